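#' Summarise a linkage map
#'
#' Computes per-group map lengths and the pooled average spacing between
#' unique mapping positions, the inputs of the genome-coverage formula.
#'
#' The map length of a group is the span `max(cM) - min(cM)`. The average
#' spacing `d` is pooled across groups: the sum of gaps between consecutive
#' unique positions within each group, divided by the total number of such
#' gaps. Markers mapped to the same position contribute one position. Groups
#' with a single unique position contribute no gaps and are flagged.
#'
#' @param map A linkage map: data frame with columns `marker`, `lg`,
#'   `pos_cm`.
#' @return A list of class `map_summary` with elements `groups` (tibble:
#'   `lg`, `length_cm`, `n_markers`, `n_unique_pos`), `n` (total markers),
#'   `d` (pooled average spacing, cM), `sum_lengths` (cM), `L` (extended
#'   total length, cM), `gc` (genome coverage), and `single_position_groups`.
#' @examples
#' m <- tibble::tibble(marker = paste0("s", 1:11), lg = "LG1", pos_cm = 0:10)
#' map_summary(m)$d
#' @export
map_summary <- function(map) {
  stopifnot(all(c("marker", "lg", "pos_cm") %in% names(map)))
  groups <- map |>
    dplyr::group_by(.data$lg) |>
    dplyr::summarise(
      length_cm = max(.data$pos_cm) - min(.data$pos_cm),
      n_markers = dplyr::n(),
      n_unique_pos = dplyr::n_distinct(.data$pos_cm),
      gap_sum = sum(diff(sort(unique(.data$pos_cm)))),
      .groups = "drop"
    )
  singles <- groups$lg[groups$n_unique_pos < 2]
  usable <- groups[groups$n_unique_pos >= 2, ]
  if (nrow(usable) == 0) stop("no linkage group has >= 2 unique positions")
  d <- sum(usable$gap_sum) / sum(usable$n_unique_pos - 1)
  n <- sum(groups$n_markers)
  out <- list(
    groups = dplyr::select(groups, -"gap_sum"),
    n = n,
    d = d,
    sum_lengths = sum(groups$length_cm),
    L = sum(groups$length_cm + 2 * d),
    single_position_groups = singles
  )
  out$gc <- genome_coverage(d, n, groups$length_cm)
  class(out) <- "map_summary"
  out
}

#' @export
print.map_summary <- function(x, ...) {
  cat("Linkage map summary\n")
  cat(sprintf("  groups: %d   markers: %d\n", nrow(x$groups), x$n))
  cat(sprintf("  sum of lengths: %.1f cM   average spacing d: %.3f cM\n",
              x$sum_lengths, x$d))
  cat(sprintf("  extended length L: %.1f cM   genome coverage: %.3f\n",
              x$L, x$gc))
  if (length(x$single_position_groups)) {
    cat("  single-position groups excluded from d:",
        paste(x$single_position_groups, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Expected genome coverage of a linkage map
#'
#' The expected proportion of the genome lying within `d` cM of a mapped
#' marker: \eqn{GC = 1 - e^{-2dn/L}}, where `d` is the average spacing
#' between unique mapping positions, `n` the total number of markers, and
#' `L` the sum over linkage groups of map length extended by `2d` (each
#' group's ends are assumed covered `d` cM beyond its terminal markers).
#'
#' @param d Average marker spacing, cM.
#' @param n Total number of markers across linkage groups.
#' @param lengths Numeric vector of per-group map lengths, cM.
#' @return Genome coverage in `[0, 1]`.
#' @examples
#' genome_coverage(d = 0.445, n = 1032, lengths = rep(45.46, 10))  # 0.862
#' @export
genome_coverage <- function(d, n, lengths) {
  stopifnot(d >= 0, n >= 0, length(lengths) >= 1)
  L <- sum(lengths + 2 * d)
  if (L <= 0) stop("extended total map length must be positive")
  1 - exp(-2 * d * n / L)
}

#' Paired-sample t test between two sets of per-family map statistics
#'
#' Classical paired Student's t on the per-family differences, as used to
#' compare map length, marker counts, spacing, and coverage between mapping
#' methods across the same families.
#'
#' @param x,y Numeric vectors of equal length (>= 2), one value per family.
#' @return A tibble with `mean_x`, `mean_y`, `statistic`, `df`, `p_value`
#'   (two-sided).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  diffs <- x - y
  if (all(diffs == 0)) {
    return(tibble::tibble(mean_x = mean(x), mean_y = mean(y),
                          statistic = 0, df = length(x) - 1, p_value = 1))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(
    mean_x = mean(x), mean_y = mean(y),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

#' Method-comparison table for paired map sets
#'
#' Builds a comparison table, one row per summary statistic (sum of lengths,
#' total markers, average spacing, genome coverage), giving per-method means
#' and the paired t statistic with its two-sided p-value across families.
#'
#' @param summaries_a,summaries_b Named lists of [map_summary()] objects,
#'   same family names in the same order.
#' @param labels Character vector of length 2 naming the two methods.
#' @return A tibble with columns `statistic`, `mean_<label1>`,
#'   `mean_<label2>`, `t`, `df`, `p_value`.
#' @export
compare_map_sets <- function(summaries_a, summaries_b,
                             labels = c("A", "B")) {
  stopifnot(length(summaries_a) == length(summaries_b))
  pull_stats <- function(ss) tibble::tibble(
    sum_lengths = purrr::map_dbl(ss, "sum_lengths"),
    n_markers = purrr::map_dbl(ss, "n"),
    spacing = purrr::map_dbl(ss, "d"),
    coverage = purrr::map_dbl(ss, "gc")
  )
  a <- pull_stats(summaries_a)
  b <- pull_stats(summaries_b)
  out <- purrr::map_dfr(names(a), function(stat) {
    tt <- paired_t(a[[stat]], b[[stat]])
    tibble::tibble(statistic = stat, mean_a = tt$mean_x, mean_b = tt$mean_y,
                   t = tt$statistic, df = tt$df, p_value = tt$p_value)
  })
  names(out)[2:3] <- paste0("mean_", labels)
  out
}
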