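#' Chromosome-level recombination rate from distal markers
#'
#' Divides the genetic distance between the two most distal SNPs of a
#' linkage group (distal by genetic position) by the physical distance
#' between those SNPs on the assembly, in cM/Mb.
#'
#' @param map One parent's map for one linkage group: tibble `marker`,
#'   `pos_cm`.
#' @param coords Coordinate table with `marker`, `chrom_pos`.
#' @return A tibble `rr` (cM/Mb), `cm_span`, `mb_span`, `n_snps`.
#' @export
chromosome_rr <- function(map, coords) {
  hit <- dplyr::inner_join(dplyr::select(map, "marker", "pos_cm"),
                           dplyr::select(coords, "marker", "chrom_pos"),
                           by = "marker")
  if (nrow(hit) < 2) stop("need >= 2 mapped SNPs with physical positions")
  # distal SNPs by genetic position; cM ties resolved to the physical
  # extremes so a flat map still spans the chromosome
  lo_cands <- hit[hit$pos_cm == min(hit$pos_cm), ]
  hi_cands <- hit[hit$pos_cm == max(hit$pos_cm), ]
  lo <- lo_cands[which.min(lo_cands$chrom_pos), ]
  hi <- hi_cands[which.max(hi_cands$chrom_pos), ]
  mb <- abs(hi$chrom_pos - lo$chrom_pos) / 1e6
  if (mb == 0) stop("zero physical span between distal SNPs")
  tibble::tibble(rr = (hi$pos_cm - lo$pos_cm) / mb,
                 cm_span = hi$pos_cm - lo$pos_cm, mb_span = mb,
                 n_snps = nrow(hit))
}

#' Three-way ANOVA of recombination rates
#'
#' Partitions variance in chromosome-level recombination rate across
#' family, sex, and chromosome with all two-way interactions (the
#' three-way interaction is not estimable without replication of the
#' family-by-sex-by-chromosome cell and is excluded). Because each
#' family-by-chromosome mean rate is a single observation per sex, the
#' family and chromosome main effects are tested against the
#' family-by-chromosome interaction mean square; sex and the interactions
#' are tested against the residual.
#'
#' @param rr_table Tibble with columns `family`, `sex` (`"sire"`/`"dam"`),
#'   `chrom`, `rr`; exactly one row per family x sex x chromosome cell.
#' @return An `rr_anova` list: `table` (tibble `term`, `df`, `ss`, `ms`,
#'   `f`, `p_value`, `error_term`), `grand_mean`, `r_squared`,
#'   `model_f`, `model_df`, `model_p`, and `fit` (the underlying `aov`).
#' @export
rr_anova <- function(rr_table) {
  req <- c("family", "sex", "chrom", "rr")
  stopifnot(all(req %in% names(rr_table)))
  cells <- rr_table |>
    dplyr::count(.data$family, .data$sex, .data$chrom)
  n_cells <- dplyr::n_distinct(rr_table$family) * 2 *
    dplyr::n_distinct(rr_table$chrom)
  if (nrow(cells) != n_cells || any(cells$n != 1)) {
    bad <- cells[cells$n != 1, ]
    stop("design not balanced: expected one row per family x sex x ",
         "chromosome; ", nrow(bad), " cells deviate (",
         nrow(cells), "/", n_cells, " cells present)")
  }
  df <- dplyr::mutate(rr_table,
                      family = factor(.data$family),
                      sex = factor(.data$sex),
                      chrom = factor(.data$chrom))
  fit <- stats::aov(
    rr ~ family + sex + chrom + family:sex + family:chrom + sex:chrom,
    data = df)
  an <- stats::anova(fit)
  tab <- tibble::tibble(
    term = trimws(rownames(an)),
    df = an$Df, ss = an$`Sum Sq`, ms = an$`Mean Sq`
  )
  ms_resid <- tab$ms[tab$term == "Residuals"]
  df_resid <- tab$df[tab$term == "Residuals"]
  ms_fc <- tab$ms[tab$term == "family:chrom"]
  df_fc <- tab$df[tab$term == "family:chrom"]
  f_vs_fc <- if (ms_fc > 0) tab$ms / ms_fc else rep(NA_real_, nrow(tab))
  f_vs_res <- if (ms_resid > 0) tab$ms / ms_resid else
    rep(NA_real_, nrow(tab))
  tab <- tab |>
    dplyr::mutate(
      error_term = dplyr::case_when(
        term %in% c("family", "chrom") ~ "family:chrom",
        term == "Residuals" ~ NA_character_,
        TRUE ~ "Residuals"
      ),
      f = dplyr::case_when(
        term == "Residuals" ~ NA_real_,
        term %in% c("family", "chrom") ~ f_vs_fc,
        TRUE ~ f_vs_res
      ),
      p_value = dplyr::case_when(
        is.na(.data$f) ~ NA_real_,
        term %in% c("family", "chrom") ~
          stats::pf(.data$f, .data$df, df_fc, lower.tail = FALSE),
        TRUE ~ stats::pf(.data$f, .data$df, df_resid, lower.tail = FALSE)
      )
    )
  ss_model <- sum(tab$ss[tab$term != "Residuals"])
  df_model <- sum(tab$df[tab$term != "Residuals"])
  ss_resid <- tab$ss[tab$term == "Residuals"]
  model_f <- (ss_model / df_model) / ms_resid
  structure(list(
    table = tab,
    grand_mean = mean(df$rr),
    r_squared = ss_model / (ss_model + ss_resid),
    model_f = model_f,
    model_df = c(df_model, df_resid),
    model_p = stats::pf(model_f, df_model, df_resid, lower.tail = FALSE),
    fit = fit
  ), class = "rr_anova")
}

#' @export
print.rr_anova <- function(x, ...) {
  cat(sprintf(
    "Recombination-rate ANOVA: grand mean %.2f cM/Mb, F(%d/%d) = %.2f, p = %.2g, r2 = %.3f\n",
    x$grand_mean, x$model_df[1], x$model_df[2], x$model_f, x$model_p,
    x$r_squared))
  print(x$table)
  invisible(x)
}

# longest nondecreasing subsequence (indices), O(n log n); leftmost-
# maximal, deterministic
lnds_indices <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  tails <- numeric(0)     # smallest tail value of an LNDS of each length
  tails_idx <- integer(0)
  prev <- integer(n)
  for (i in seq_len(n)) {
    # first position with tail value > x[i] (nondecreasing: strict >)
    j <- findInterval(x[i], tails, left.open = FALSE) + 1L
    # findInterval gives count of tails <= x[i]; replace the next one
    prev[i] <- if (j > 1) tails_idx[j - 1] else 0L
    tails[j] <- x[i]
    tails_idx[j] <- i
  }
  out <- integer(length(tails))
  k <- tails_idx[length(tails_idx)]
  for (j in rev(seq_along(out))) {
    out[j] <- k
    k <- prev[k]
  }
  out
}

# local-linear (degree 1) fit with tricube weights over the span*n nearest
# neighbours; returns fitted value and slope at each x
local_linear_slope <- function(x, y, span) {
  n <- length(x)
  k <- max(2L, ceiling(span * n))
  fitted <- slope <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(k)]
    h <- max(d[idx])
    w <- if (h == 0) rep(1, k) else (1 - pmin(d[idx] / h, 1)^3)^3
    w[w <= 0] <- .Machine$double.eps
    xs <- x[idx] - x[i]
    sw <- sum(w)
    swx <- sum(w * xs)
    swx2 <- sum(w * xs^2)
    swy <- sum(w * y[idx])
    swxy <- sum(w * xs * y[idx])
    det <- sw * swx2 - swx^2
    if (det <= 0) {
      slope[i] <- 0
      fitted[i] <- swy / sw
    } else {
      b <- (sw * swxy - swx * swy) / det
      a <- (swy - b * swx) / sw
      fitted[i] <- a
      slope[i] <- b
    }
  }
  list(fitted = fitted, slope = slope)
}

#' Marey-map recombination-rate profile
#'
#' Estimates the local recombination rate along a chromosome as the local
#' slope of the Marey map (genetic position in cM against physical
#' position in bp). Outlier loci whose genetic position does not increase
#' monotonically with physical position are removed first, by retaining
#' the longest nondecreasing subsequence (a deterministic, maximal
#' retention). A degree-1 local regression with tricube weights over the
#' `ceiling(span * n)` nearest neighbours then yields the slope at every
#' retained locus (converted from cM/bp to cM/Mb); loci with a negative
#' rate are removed and the profile refit once on the remainder.
#'
#' @param points Tibble with columns `bp`, `cm` for one chromosome of one
#'   family/parent.
#' @param span Local-regression span (fraction of points in each
#'   neighbourhood), default 0.3.
#' @param min_points Minimum retained loci required (default 5).
#' @return An `rr_profile` tibble: `bp`, `cm`, `fitted_cm`, `rr` (cM/Mb);
#'   attributes `removed_outliers`, `removed_negative` (bp positions),
#'   `span`.
#' @export
marey_profile <- function(points, span = 0.3, min_points = 5) {
  stopifnot(all(c("bp", "cm") %in% names(points)))
  pts <- dplyr::arrange(tibble::as_tibble(points), .data$bp)
  need <- max(min_points, ceiling(span * nrow(pts)))
  if (nrow(pts) < need) {
    warning("insufficient points (", nrow(pts), "); chromosome skipped")
    return(NULL)
  }
  keep <- lnds_indices(pts$cm)
  removed_outliers <- pts$bp[-keep]
  pts <- pts[keep, ]
  if (nrow(pts) < max(min_points, 2)) {
    warning("insufficient points after outlier removal; chromosome skipped")
    return(NULL)
  }
  fit1 <- local_linear_slope(pts$bp, pts$cm, span)
  rr1 <- fit1$slope * 1e6
  neg <- rr1 < 0
  removed_negative <- pts$bp[neg]
  if (any(neg)) {
    pts <- pts[!neg, , drop = FALSE]
    if (nrow(pts) < max(min_points, 2)) {
      warning("insufficient points after negative-rate removal; skipped")
      return(NULL)
    }
    fit1 <- local_linear_slope(pts$bp, pts$cm, span)
    rr1 <- fit1$slope * 1e6
  }
  out <- tibble::tibble(bp = pts$bp, cm = pts$cm,
                        fitted_cm = fit1$fitted, rr = rr1)
  attr(out, "removed_outliers") <- removed_outliers
  attr(out, "removed_negative") <- removed_negative
  attr(out, "span") <- span
  class(out) <- c("rr_profile", class(out))
  out
}

#' Standardize recombination-rate profiles within a family
#'
#' Centers and scales the local rates of all retained loci of one family
#' (genome-wide) to mean 0 and standard deviation 1, enabling comparison
#' among families. Values above 1.28 or below -1.28 (nominal 90th/10th
#' percentiles of a standard normal) flag hotspot and coldspot candidates.
#'
#' @param profiles Tibble binding one family's profiles, with columns
#'   `chrom`, `bp`, `rr` (e.g. row-bound [marey_profile()] outputs with a
#'   `chrom` column added).
#' @param thresholds Length-2 numeric: cold and hot thresholds on the z
#'   scale.
#' @return The input with added columns `z` and `extreme`
#'   (`"hot"`, `"cold"`, or `NA`).
#' @export
standardize_rr <- function(profiles, thresholds = c(-1.28, 1.28)) {
  stopifnot(all(c("rr") %in% names(profiles)))
  if (nrow(profiles) < 2) stop("need >= 2 retained loci")
  s <- stats::sd(profiles$rr)
  if (s == 0) stop("zero variance in recombination rates")
  profiles |>
    dplyr::mutate(
      z = (.data$rr - mean(.data$rr)) / s,
      extreme = dplyr::case_when(
        z > thresholds[2] ~ "hot",
        z < thresholds[1] ~ "cold",
        TRUE ~ NA_character_
      )
    )
}

#' Quadrat test of complete spatial randomness for extreme rates
#'
#' Tests whether one chromosome's extreme standardized rates (all beyond
#' one threshold; hot and cold sets are tested separately) are uniformly
#' scattered over the rectangle tightly bounding the points in the
#' (physical position, standardized rate) plane. The rectangle is split
#' into 3 x 3 equal-area quadrats and observed counts are compared with
#' the uniform expectation `n/9` by a Pearson chi-square with 8 df. Fewer
#' than nine points (expectation below 1 per quadrat), or a degenerate
#' rectangle, leaves the set untested.
#'
#' @param points Tibble with columns `bp`, `z` (one chromosome, one
#'   extreme set).
#' @param alpha Significance threshold; the default 0.001 accounts for
#'   testing many family-by-chromosome sets.
#' @param bounds Optional list with elements `bp` and `z`, each a length-2
#'   range overriding the tight bounding rectangle (e.g. to test against
#'   the full mapped extent of a chromosome).
#' @return A tibble `n`, `tested`, `statistic`, `df`, `p_value`,
#'   `significant`, `reason` (when untested).
#' @export
csr_quadrat_test <- function(points, alpha = 0.001, bounds = NULL) {
  n <- nrow(points)
  untested <- function(reason) tibble::tibble(
    n = n, tested = FALSE, statistic = NA_real_, df = NA_integer_,
    p_value = NA_real_, significant = NA, reason = reason)
  if (n < 9) return(untested("fewer than 9 observations"))
  bp_range <- if (is.null(bounds)) range(points$bp) else bounds$bp
  z_range <- if (is.null(bounds)) range(points$z) else bounds$z
  if (diff(bp_range) == 0 || diff(z_range) == 0) {
    return(untested("degenerate bounding rectangle"))
  }
  cut3 <- function(v, rng) {
    br <- seq(rng[1], rng[2], length.out = 4)
    pmax(pmin(findInterval(v, br, rightmost.closed = TRUE), 3L), 1L)
  }
  cell <- (cut3(points$bp, bp_range) - 1L) * 3L + cut3(points$z, z_range)
  obs <- tabulate(cell, nbins = 9L)
  expd <- n / 9
  stat <- sum((obs - expd)^2 / expd)
  p <- stats::pchisq(stat, df = 8, lower.tail = FALSE)
  tibble::tibble(n = n, tested = TRUE, statistic = stat, df = 8L,
                 p_value = p, significant = p < alpha,
                 reason = NA_character_)
}

#' Minimum recombination rate in a candidate centromere region
#'
#' Reports the lowest local rate among profile loci inside a physical
#' interval (e.g. the confidence region for a centromere position),
#' together with its genome-wide quantile — a low quantile indicates
#' recombination suppression in the region.
#'
#' @param profile An `rr_profile` (or tibble with `bp`, `rr`) for the
#'   chromosome of interest.
#' @param interval Length-2 numeric, bp range (inclusive).
#' @param genome_rr Numeric vector of rates defining the reference
#'   distribution (default: the profile's own rates).
#' @return A tibble `n_in_interval`, `min_rr`, `min_bp`, `quantile`,
#'   `flagged` (`TRUE` when no locus overlaps the interval).
#' @export
centromere_min_rr <- function(profile, interval, genome_rr = profile$rr) {
  stopifnot(length(interval) == 2)
  inside <- profile$bp >= interval[1] & profile$bp <= interval[2]
  if (!any(inside)) {
    return(tibble::tibble(n_in_interval = 0L, min_rr = NA_real_,
                          min_bp = NA_real_, quantile = NA_real_,
                          flagged = TRUE))
  }
  sub <- profile[inside, ]
  i <- which.min(sub$rr)
  tibble::tibble(
    n_in_interval = sum(inside),
    min_rr = sub$rr[i],
    min_bp = sub$bp[i],
    quantile = mean(genome_rr <= sub$rr[i]),
    flagged = FALSE
  )
}
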