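#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a recombination-rate ANOVA
#'
#' @param x An `rr_anova`.
#' @param ... Unused.
#' @return One row per model term: `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`, `error.term`.
#' @method tidy rr_anova
#' @export
tidy.rr_anova <- function(x, ...) {
  dplyr::transmute(x$table,
                   term = .data$term, df = .data$df, sumsq = .data$ss,
                   meansq = .data$ms, statistic = .data$f,
                   p.value = .data$p_value, error.term = .data$error_term)
}

#' @rdname tidy.rr_anova
#' @method glance rr_anova
#' @export
glance.rr_anova <- function(x, ...) {
  tibble::tibble(
    grand.mean = x$grand_mean, r.squared = x$r_squared,
    statistic = x$model_f, df = x$model_df[1], df.residual = x$model_df[2],
    p.value = x$model_p
  )
}

#' Tidy a three-way loglinear analysis
#'
#' @param x A `loglinear_3way`.
#' @param ... Unused.
#' @return One row per tested term: `term`, `statistic` (G^2), `df`,
#'   `p.value`.
#' @method tidy loglinear_3way
#' @export
tidy.loglinear_3way <- function(x, ...) {
  dplyr::transmute(x$terms, term = .data$term,
                   statistic = .data$g_squared, df = .data$df,
                   p.value = .data$p_value)
}

#' @rdname tidy.loglinear_3way
#' @method glance loglinear_3way
#' @export
glance.loglinear_3way <- function(x, ...) {
  three <- x$terms[nrow(x$terms), ]
  tibble::tibble(n = sum(x$observed),
                 deviance.two.way = three$g_squared,
                 df.two.way = three$df, p.value.two.way = three$p_value)
}

#' Tidy a map summary
#'
#' @param x A `map_summary`.
#' @param ... Unused.
#' @return Per linkage group: `lg`, `length.cm`, `n.markers`,
#'   `n.unique.pos`.
#' @method tidy map_summary
#' @export
tidy.map_summary <- function(x, ...) {
  dplyr::transmute(x$groups, lg = .data$lg, length.cm = .data$length_cm,
                   n.markers = .data$n_markers,
                   n.unique.pos = .data$n_unique_pos)
}

#' @rdname tidy.map_summary
#' @method glance map_summary
#' @export
glance.map_summary <- function(x, ...) {
  tibble::tibble(n.markers = x$n, spacing.cm = x$d,
                 sum.lengths.cm = x$sum_lengths, extended.length.cm = x$L,
                 genome.coverage = x$gc)
}

#' Tidy a block-statistics summary
#'
#' @param x A `block_stats`.
#' @param ... Unused.
#' @return One row per run class with counts of runs and member SNPs.
#' @method tidy block_stats
#' @export
tidy.block_stats <- function(x, ...) {
  x$run_counts
}

#' @rdname tidy.block_stats
#' @method glance block_stats
#' @export
glance.block_stats <- function(x, ...) {
  tibble::tibble(
    n.chimeric.contigs = x$n_chimeric_contigs, n.blocks = x$n_blocks,
    mean.snps.per.block = x$mean_snps_per_block,
    median.length.bp = x$median_length_bp,
    total.length.bp = x$total_length_bp
  )
}
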