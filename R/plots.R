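#' Plot a Marey map with its fitted profile
#'
#' Genetic position against physical position for the retained loci of an
#' [marey_profile()], with the local-regression fit overlaid.
#'
#' @param object An `rr_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rr_profile
#' @export
autoplot.rr_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bp / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cm), size = 0.6,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_cm), colour = "red") +
    ggplot2::labs(x = "Physical position (Mb)",
                  y = "Genetic position (cM)", title = "Marey map")
}

#' Plot standardized recombination rates along chromosomes
#'
#' Standardized local recombination rate against physical position,
#' faceted by chromosome, with the hotspot/coldspot thresholds drawn as
#' dashed lines.
#'
#' @param profiles Output of [standardize_rr()] (columns `chrom`, `bp`,
#'   `z`).
#' @param thresholds Length-2 numeric thresholds to draw.
#' @return A ggplot object.
#' @export
plot_standardized_rr <- function(profiles, thresholds = c(-1.28, 1.28)) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$bp / 1e6, y = .data$z)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Physical position (Mb)",
                  y = "Standardized recombination rate")
}

#' Plot per-cell recombination rates from an ANOVA table
#'
#' Mean recombination rate by family, coloured by parental sex, one panel
#' per factor combination useful for inspecting the family, sex and
#' chromosome effects underlying [rr_anova()].
#'
#' @param rr_table Tibble with `family`, `sex`, `chrom`, `rr`.
#' @return A ggplot object.
#' @export
plot_rr_effects <- function(rr_table) {
  ggplot2::ggplot(rr_table,
                  ggplot2::aes(x = .data$family, y = .data$rr,
                               colour = .data$sex)) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2,
                          position = ggplot2::position_dodge(0.4)) +
    ggplot2::geom_point(alpha = 0.3,
                        position = ggplot2::position_dodge(0.4)) +
    ggplot2::labs(x = "Family", y = "Recombination rate (cM/Mb)",
                  colour = "Parent")
}

#' Plot concordance categories of a layout comparison
#'
#' @param report A `concordance_report` from [compare_layouts()].
#' @return A ggplot object.
#' @export
plot_concordance <- function(report) {
  ggplot2::ggplot(report$summary,
                  ggplot2::aes(x = stats::reorder(.data$category,
                                                  -.data$n),
                               y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Fraction of shared contigs") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
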