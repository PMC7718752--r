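#' Convert between recombination fraction and map distance
#'
#' Applies the Haldane (no crossover interference) or Kosambi (partial
#' interference) mapping function, forward (recombination fraction `r` to
#' additive genetic distance in centimorgans) or inverse (cM to `r`).
#'
#' Forward transforms: Haldane \eqn{d = -50 \ln(1 - 2r)}; Kosambi
#' \eqn{d = 25 \ln((1 + 2r)/(1 - 2r))}. Inverses are exact: Haldane
#' \eqn{r = (1 - e^{-d/50})/2}; Kosambi \eqn{r = \tanh(d/50)/2}.
#'
#' @param x Numeric vector: recombination fractions in `[0, 0.5)` when
#'   `inverse = FALSE`, map distances in cM (>= 0) when `inverse = TRUE`.
#' @param method `"haldane"` or `"kosambi"`.
#' @param inverse If `TRUE`, convert cM to recombination fraction.
#' @return Numeric vector of distances in cM (forward) or recombination
#'   fractions (inverse).
#' @examples
#' mapping_distance(0.25, "haldane")  # 34.657 cM
#' mapping_distance(0.25, "kosambi")  # 27.465 cM
#' mapping_distance(mapping_distance(0.3, "kosambi"), "kosambi", inverse = TRUE)
#' @export
mapping_distance <- function(x, method = c("haldane", "kosambi"),
                             inverse = FALSE) {
  method <- match.arg(method)
  stopifnot(is.numeric(x))
  if (inverse) {
    if (any(x < 0)) stop("map distances must be >= 0")
    switch(method,
      haldane = (1 - exp(-x / 50)) / 2,
      kosambi = tanh(x / 50) / 2
    )
  } else {
    if (any(x < 0) || any(x >= 0.5)) {
      stop("recombination fractions must lie in [0, 0.5)")
    }
    switch(method,
      haldane = -50 * log(1 - 2 * x),
      kosambi = 25 * log((1 + 2 * x) / (1 - 2 * x))
    )
  }
}

#' Estimate a two-locus recombination fraction
#'
#' For phase-known gametic data the estimate is the recombinant proportion.
#' For an F2 intercross with both loci codominant (both parents heterozygous,
#' coupling phase) supply the 3x3 joint genotype counts; the maximum-
#' likelihood estimate is located by bounded scalar search on `[0, 0.5)`
#' under the no-interference model in which each parental gamete is
#' independently recombinant with probability `r`.
#'
#' @param recombinants,total Phase-known counts: recombinant gametes and
#'   gametes scored.
#' @param intercross Optional 3x3 matrix of joint genotype counts; rows are
#'   locus-1 genotypes (aa, ab, bb by allele dose), columns locus-2 genotypes.
#'   When supplied, `recombinants`/`total` are ignored.
#' @return A tibble with columns `r_hat`, `n`, and `method`
#'   (`"phase_known"` or `"intercross_ml"`).
#' @examples
#' estimate_rf(recombinants = 25, total = 100)
#' @export
estimate_rf <- function(recombinants = NULL, total = NULL, intercross = NULL) {
  if (!is.null(intercross)) {
    counts <- as.matrix(intercross)
    stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
    n <- sum(counts)
    if (n == 0) stop("zero gametes scored")
    nll <- function(r) -sum(counts * log(intercross_probs(r)))
    opt <- stats::optimize(nll, interval = c(1e-8, 0.5 - 1e-8))
    # r = 0 sits on the search boundary; admit it when no recombinant
    # genotype class was observed
    r_hat <- if (nll(0) <= opt$objective) 0 else opt$minimum
    return(tibble::tibble(r_hat = r_hat, n = n, method = "intercross_ml"))
  }
  stopifnot(is.numeric(recombinants), is.numeric(total))
  if (total <= 0) stop("zero gametes scored")
  if (recombinants > total) stop("recombinants exceed gametes scored")
  tibble::tibble(r_hat = recombinants / total, n = total,
                 method = "phase_known")
}

# joint genotype probabilities for a coupling-phase F2 intercross:
# allele dose at each locus is the sum of two independent gametes, each
# recombinant with probability r
intercross_probs <- function(r) {
  g <- c(AB = (1 - r) / 2, ab = (1 - r) / 2, Ab = r / 2, aB = r / 2)
  a1 <- c(AB = 1, ab = 0, Ab = 1, aB = 0)  # locus-1 "A" allele indicator
  a2 <- c(AB = 1, ab = 0, Ab = 0, aB = 1)  # locus-2 "A" allele indicator
  p <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    d1 <- a1[i] + a1[j]
    d2 <- a2[i] + a2[j]
    p[d1 + 1, d2 + 1] <- p[d1 + 1, d2 + 1] + g[i] * g[j]
  }
  pmax(p, .Machine$double.xmin)
}

#' Cumulative map positions from adjacent recombination fractions
#'
#' Converts a vector of adjacent-interval recombination fractions, in fixed
#' marker order, into cumulative map positions starting at 0 cM.
#'
#' @param r Numeric vector of adjacent recombination fractions, each `< 0.5`.
#' @param method Mapping function passed to [mapping_distance()].
#' @return Numeric vector of length `length(r) + 1` of cumulative positions.
#' @export
positions_from_rf <- function(r, method = c("haldane", "kosambi")) {
  method <- match.arg(method)
  if (length(r) == 0) return(0)
  cumsum(c(0, mapping_distance(r, method)))
}

#' Collapse identical markers
#'
#' Groups markers whose genotype vectors are literally identical across
#' individuals — equal at every position, including an identical missingness
#' pattern — and retains the first marker (by input order) of each group as
#' its representative. Identical markers carry no extra mapping information,
#' so mapping only representatives and restoring the groups afterwards is
#' loss-free.
#'
#' @param genotypes Matrix or data frame of genotype calls, markers in rows
#'   (rownames = marker ids), individuals in columns. `NA` = missing.
#' @return A list with `representatives` (character vector of retained marker
#'   ids, in input order) and `groups` (tibble with columns `marker`,
#'   `representative`), covering every input marker.
#' @export
collapse_identicals <- function(genotypes) {
  m <- as.matrix(genotypes)
  if (is.null(rownames(m))) rownames(m) <- paste0("M", seq_len(nrow(m)))
  key <- apply(m, 1, function(x) paste(ifelse(is.na(x), "\r.NA", x),
                                       collapse = "\x1f"))
  rep_id <- rownames(m)[match(key, key)]  # first occurrence per key
  list(
    representatives = unique(rep_id),
    groups = tibble::tibble(marker = rownames(m), representative = rep_id)
  )
}

#' Restore collapsed identical markers
#'
#' Expands a table of mapped representative markers back to the full marker
#' set, giving every member of an identical group the map position of its
#' representative.
#'
#' @param mapped Data frame with columns `marker`, plus any map columns
#'   (e.g. `lg`, `pos_cm`); rows are representatives.
#' @param groups The `groups` tibble from [collapse_identicals()].
#' @return Tibble with one row per original marker.
#' @export
restore_identicals <- function(mapped, groups) {
  dplyr::inner_join(groups, dplyr::rename(mapped, representative = "marker"),
                    by = "representative") |>
    dplyr::select(-"representative")
}

#' Rank-order agreement between two maps
#'
#' Computes \eqn{r^2} for the least-squares regression of marker rank order
#' on one map against rank order on another, over their common markers —
#' the squared Pearson correlation of the two rank vectors (ties get average
#' ranks). A perfectly reversed order also gives 1: the statistic measures
#' collinearity of orders, not direction.
#'
#' @param map_a,map_b Data frames with columns `marker` and `pos_cm`
#'   (a single linkage group each).
#' @return A tibble with `r_squared` and `n_common`.
#' @export
rank_order_r2 <- function(map_a, map_b) {
  common <- intersect(map_a$marker, map_b$marker)
  if (length(common) < 3) stop("need at least 3 common markers")
  ra <- rank(map_a$pos_cm[match(common, map_a$marker)])
  rb <- rank(map_b$pos_cm[match(common, map_b$marker)])
  tibble::tibble(r_squared = stats::cor(ra, rb)^2, n_common = length(common))
}
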