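#' Merge per-family linkage maps into a SNP compendium
#'
#' Joins every family's linkage-group assignments to the physical
#' coordinates of each SNP, producing one record per physical marker.
#' Markers whose linkage-group assignments conflict across families (or
#' methods) are excluded and reported separately; markers translating to a
#' duplicate physical position (same contig and position) are removed;
#' markers missing from the coordinate table are listed and skipped.
#'
#' @param maps List of linkage maps (tibbles with `marker`, `lg`, `pos_cm`;
#'   attributes `family` and optionally `parent`/method metadata). Names of
#'   the list are used as map labels; the `family` attribute (or the map
#'   name) identifies the family, and an optional `method` attribute labels
#'   the mapping method.
#' @param coords Coordinate table (`marker`, `contig`, `contig_pos`,
#'   `chrom`, `chrom_pos`).
#' @return A `snp_compendium` list: `records` (tibble, one row per retained
#'   SNP: coordinates plus `n_families`, `lg`, `families`, `methods`
#'   list-columns), `assignments` (long tibble of every retained per-map
#'   assignment), `conflicts` (tibble of excluded markers and their LGs),
#'   `duplicates` (markers removed for duplicate physical position),
#'   `missing_coords` (markers absent from `coords`).
#' @export
merge_compendium <- function(maps, coords) {
  if (is.null(names(maps)) || any(names(maps) == "")) {
    names(maps) <- paste0("map", seq_along(maps))
  }
  long <- purrr::imap_dfr(maps, function(m, nm) {
    fam <- attr(m, "family")
    if (is.null(fam)) fam <- nm
    meth <- attr(m, "method")
    if (is.null(meth)) meth <- "default"
    tibble::tibble(marker = m$marker, lg = m$lg, pos_cm = m$pos_cm,
                   map = nm, family = fam, method = meth)
  })
  missing_coords <- sort(unique(setdiff(long$marker, coords$marker)))
  long <- long[long$marker %in% coords$marker, ]
  # markers assigned to more than one linkage group are excluded
  lg_per_marker <- long |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(n_lg = dplyr::n_distinct(.data$lg),
                     lgs = paste(sort(unique(.data$lg)), collapse = ","),
                     .groups = "drop")
  conflicts <- dplyr::filter(lg_per_marker, .data$n_lg > 1) |>
    dplyr::select("marker", "lgs")
  long <- long[!long$marker %in% conflicts$marker, ]
  # markers sharing a physical position are all removed
  dup_pos <- coords |>
    dplyr::filter(.data$marker %in% long$marker) |>
    dplyr::group_by(.data$contig, .data$contig_pos) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::ungroup()
  duplicates <- sort(dup_pos$marker)
  long <- long[!long$marker %in% duplicates, ]
  records <- long |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(
      lg = .data$lg[1],
      n_families = dplyr::n_distinct(.data$family),
      families = list(sort(unique(.data$family))),
      methods = list(sort(unique(.data$method))),
      .groups = "drop"
    ) |>
    dplyr::inner_join(coords, by = "marker") |>
    dplyr::arrange(.data$chrom, .data$contig, .data$contig_pos) |>
    dplyr::select("marker", "contig", "contig_pos", "chrom", "chrom_pos",
                  "lg", "n_families", "families", "methods")
  structure(
    list(records = records, assignments = long, conflicts = conflicts,
         duplicates = duplicates, missing_coords = missing_coords),
    class = "snp_compendium"
  )
}

#' @export
print.snp_compendium <- function(x, ...) {
  cat(sprintf(
    "snp_compendium: %d SNPs (%d conflicting excluded, %d duplicate-position removed, %d without coordinates)\n",
    nrow(x$records), nrow(x$conflicts), length(x$duplicates),
    length(x$missing_coords)))
  invisible(x)
}

#' Consensus linkage group per contig
#'
#' The consensus linkage group of a contig is the group to which the
#' largest number of its SNPs is assigned. An exact tie makes the contig
#' ambiguous: it is flagged and excluded from block and chimera statistics
#' rather than resolved arbitrarily.
#'
#' @param compendium A `snp_compendium` (or its `records` tibble).
#' @return A tibble with columns `contig`, `consensus_lg` (`NA` when
#'   ambiguous), `n_snps`, `n_consensus`, `ambiguous`.
#' @export
consensus_lg <- function(compendium) {
  records <- if (inherits(compendium, "snp_compendium"))
    compendium$records else compendium
  records |>
    dplyr::group_by(.data$contig) |>
    dplyr::summarise(n_snps = dplyr::n(),
                     tab = list(sort(table(.data$lg), decreasing = TRUE)),
                     .groups = "drop") |>
    dplyr::mutate(
      ambiguous = purrr::map_lgl(.data$tab, function(tt)
        length(tt) > 1 && tt[1] == tt[2]),
      consensus_lg = ifelse(.data$ambiguous, NA_character_,
                            purrr::map_chr(.data$tab, function(tt)
                              names(tt)[1])),
      n_consensus = ifelse(.data$ambiguous, NA_integer_,
                           purrr::map_int(.data$tab, function(tt)
                             as.integer(tt[1])))
    ) |>
    dplyr::select("contig", "consensus_lg", "n_snps", "n_consensus",
                  "ambiguous")
}

#' Classify SNPs with the high-confidence decision tree
#'
#' Labels every compendium SNP by the confidence decision tree:
#' category 1 — assigned to its contig's consensus linkage group and mapped
#' in more than one family; category 2 — assigned to the consensus group,
#' mapped in one family, but located on a contig carrying category-1 SNPs;
#' category 3 — assigned to a non-consensus group in more than one family.
#' Categories 1-3 are high-confidence; all other SNPs are low-confidence.
#' SNPs on contigs with an ambiguous (tied) consensus are unclassifiable.
#'
#' @param compendium A `snp_compendium`.
#' @param consensus Optional precomputed [consensus_lg()] table.
#' @return The `records` tibble with added columns `consensus_lg`,
#'   `is_consensus`, `category` (`"1"`, `"2"`, `"3"`, `"low"`,
#'   `"unclassifiable"`), `high_confidence`.
#' @export
classify_snps <- function(compendium, consensus = consensus_lg(compendium)) {
  records <- compendium$records |>
    dplyr::left_join(dplyr::select(consensus, "contig", "consensus_lg",
                                   "ambiguous"),
                     by = "contig") |>
    dplyr::mutate(is_consensus = .data$lg == .data$consensus_lg)
  cat1_contigs <- records |>
    dplyr::filter(!.data$ambiguous, .data$is_consensus,
                  .data$n_families > 1) |>
    dplyr::pull(.data$contig) |>
    unique()
  records |>
    dplyr::mutate(
      category = dplyr::case_when(
        ambiguous ~ "unclassifiable",
        is_consensus & n_families > 1 ~ "1",
        is_consensus & n_families == 1 & contig %in% cat1_contigs ~ "2",
        !is_consensus & n_families > 1 ~ "3",
        TRUE ~ "low"
      ),
      high_confidence = .data$category %in% c("1", "2", "3")
    )
}

#' Detect runs of non-consensus SNPs on each contig
#'
#' Scans each contig's SNPs in physical order for maximal runs of
#' contiguous SNPs sharing one non-consensus linkage group. A run of one
#' SNP is a single exception; a run of two or more supported by one family
#' is a one-family block; a run of two or more supported by two or more
#' families is a multi-family (chimeric) block — evidence of contig
#' misassembly. Block support is the union of families over member SNPs
#' (switch to `support = "per_snp"` to require every member SNP itself to
#' be multi-family). Contigs with ambiguous consensus are skipped.
#'
#' @param compendium A `snp_compendium`.
#' @param consensus Optional precomputed [consensus_lg()] table.
#' @param support `"union"` (default) or `"per_snp"`.
#' @return A tibble of runs: `contig`, `lg` (the non-consensus group),
#'   `start`, `end` (bp on the contig, 1-based inclusive), `length_bp`,
#'   `n_snps`, `snps` (list), `families` (list), `n_families`, `class`
#'   (`"single_exception"`, `"one_family_block"`, `"multi_family_block"`).
#' @export
detect_blocks <- function(compendium, consensus = consensus_lg(compendium),
                          support = c("union", "per_snp")) {
  support <- match.arg(support)
  records <- compendium$records |>
    dplyr::inner_join(dplyr::select(consensus, "contig", "consensus_lg",
                                    "ambiguous"),
                      by = "contig") |>
    dplyr::filter(!.data$ambiguous) |>
    dplyr::arrange(.data$contig, .data$contig_pos)
  empty_runs <- tibble::tibble(
    contig = character(), lg = character(), start = integer(),
    end = integer(), length_bp = integer(), n_snps = integer(),
    snps = list(), families = list(), n_families = integer(),
    class = character())
  if (!any(records$lg != records$consensus_lg)) return(empty_runs)
  runs <- records |>
    dplyr::group_by(.data$contig) |>
    dplyr::mutate(
      non_consensus = .data$lg != .data$consensus_lg,
      # a run breaks wherever the assigned group changes; consensus SNPs
      # between two same-group exceptions break the run because their
      # group differs
      run_id = cumsum(.data$lg != dplyr::lag(.data$lg, default = "\x01"))
    ) |>
    dplyr::filter(.data$non_consensus) |>
    dplyr::group_by(.data$contig, .data$run_id) |>
    dplyr::summarise(
      lg = .data$lg[1],
      start = min(.data$contig_pos),
      end = max(.data$contig_pos),
      n_snps = dplyr::n(),
      snps = list(.data$marker),
      families = list(sort(unique(unlist(.data$families)))),
      all_multi = all(.data$n_families > 1),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      length_bp = .data$end - .data$start + 1L,
      n_families = lengths(.data$families),
      multi = if (support == "union") .data$n_families > 1 else
        .data$all_multi & .data$n_families > 1,
      class = dplyr::case_when(
        n_snps == 1 ~ "single_exception",
        multi ~ "multi_family_block",
        TRUE ~ "one_family_block"
      )
    ) |>
    dplyr::select("contig", "lg", "start", "end", "length_bp", "n_snps",
                  "snps", "families", "n_families", "class")
  runs
}

#' Summary statistics of chimeric blocks
#'
#' Totals over multi-family blocks only — the blocks taken as evidence of
#' chimeric contigs: number of chimeric contigs, mean SNPs per block,
#' median and total block length in bp. Also reports counts of the three
#' run classes and of their member SNPs.
#'
#' @param runs Output of [detect_blocks()].
#' @return A list of class `block_stats` with elements `n_chimeric_contigs`,
#'   `n_blocks`, `mean_snps_per_block`, `median_length_bp`,
#'   `total_length_bp`, and `run_counts` / `snp_counts` tibbles.
#' @export
block_stats <- function(runs) {
  multi <- runs[runs$class == "multi_family_block", ]
  counts <- runs |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n_runs = dplyr::n(), n_snps = sum(.data$n_snps),
                     .groups = "drop")
  structure(list(
    n_chimeric_contigs = dplyr::n_distinct(multi$contig),
    n_blocks = nrow(multi),
    mean_snps_per_block = if (nrow(multi)) mean(multi$n_snps) else NA_real_,
    median_length_bp = if (nrow(multi)) stats::median(multi$length_bp) else
      NA_real_,
    total_length_bp = if (nrow(multi)) sum(multi$length_bp) else 0L,
    run_counts = counts
  ), class = "block_stats")
}

#' @export
print.block_stats <- function(x, ...) {
  cat(sprintf(
    "chimeric contigs: %d (%d multi-family blocks; %.2f SNPs/block; median %s bp; total %s bp)\n",
    x$n_chimeric_contigs, x$n_blocks,
    ifelse(is.na(x$mean_snps_per_block), 0, x$mean_snps_per_block),
    format(x$median_length_bp), format(x$total_length_bp)))
  print(x$run_counts)
  invisible(x)
}

#' Two-by-two contingency analysis
#'
#' Odds ratio and Pearson chi-square (1 df, no continuity correction) for a
#' 2x2 table laid out `(a, b; c, d)`: the odds ratio is `a*d / (b*c)`, the
#' product of the main diagonal over the product of the off-diagonal.
#'
#' @param a,b,c,d Cell counts (row-wise).
#' @return A tibble with `odds_ratio`, `statistic`, `df`, `p_value`, and a
#'   `degenerate` flag (zero cell: odds ratio 0 or infinite).
#' @examples
#' contingency_2x2(256, 16919, 5, 846)  # odds ratio 2.560
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0))
  m <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal total")
  }
  or <- (a * d) / (b * c)
  ct <- stats::chisq.test(m, correct = FALSE)
  tibble::tibble(
    odds_ratio = or,
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    degenerate = any(counts == 0)
  )
}

#' Three-way loglinear analysis of a 2x2x2 table
#'
#' Fits the hierarchy of loglinear models to a 2x2x2 contingency table by
#' iterative proportional fitting and reports likelihood-ratio G^2 tests
#' (1 df each) for dropping each two-way interaction from the
#' all-two-way-interaction model, and for the three-way interaction itself
#' (the all-two-way model's deviance against the saturated model).
#'
#' @param counts A 2x2x2 array (or a data frame with three two-level factor
#'   columns and a `n` count column).
#' @param dimension_names Optional names for the three dimensions.
#' @return A `loglinear_3way` list: `terms` (tibble `term`, `g_squared`,
#'   `df`, `p_value`), `fit_all_two_way` (fitted expected counts), and
#'   `observed`.
#' @export
loglinear_3way <- function(counts, dimension_names = NULL) {
  if (is.data.frame(counts)) {
    stopifnot("n" %in% names(counts))
    fac <- setdiff(names(counts), "n")
    stopifnot(length(fac) == 3)
    counts <- stats::xtabs(stats::reformulate(fac, "n"), data = counts)
  }
  counts <- as.array(counts)
  stopifnot(all(dim(counts) == 2), length(dim(counts)) == 3)
  if (!is.null(dimension_names)) {
    names(dimnames(counts)) <- dimension_names
  } else if (is.null(names(dimnames(counts))) ||
             any(!nzchar(names(dimnames(counts))))) {
    dimnames(counts) <- stats::setNames(
      dimnames(counts) %||% rep(list(c("1", "2")), 3), c("A", "B", "C"))
  }
  if (any(counts == 0)) {
    warning("structural/sampling zeros present; G^2 may be unstable")
  }
  dn <- names(dimnames(counts))
  all2 <- list(c(1, 2), c(1, 3), c(2, 3))
  fit <- function(margins) {
    stats::loglin(counts, margin = margins, fit = TRUE, print = FALSE)
  }
  full <- fit(all2)
  drop_one <- purrr::map_dfr(1:3, function(i) {
    reduced <- fit(all2[-i])
    tibble::tibble(
      term = paste(dn[all2[[i]]], collapse = " x "),
      g_squared = reduced$lrt - full$lrt,
      df = 1,
      p_value = stats::pchisq(reduced$lrt - full$lrt, 1, lower.tail = FALSE)
    )
  })
  three <- tibble::tibble(
    term = paste(dn, collapse = " x "),
    g_squared = full$lrt, df = full$df,
    p_value = stats::pchisq(full$lrt, full$df, lower.tail = FALSE)
  )
  structure(list(terms = dplyr::bind_rows(drop_one, three),
                 fit_all_two_way = full$fit, observed = counts),
            class = "loglinear_3way")
}

#' @export
print.loglinear_3way <- function(x, ...) {
  cat("Three-way loglinear analysis (G^2 likelihood-ratio tests)\n")
  print(x$terms)
  invisible(x)
}

#' Grouping-accuracy cross-classification of a compendium
#'
#' Builds the 2x2x2 table of SNP counts over grouping accuracy (consensus
#' vs non-consensus linkage group), mapping method, and level of family
#' support (mapped in one vs more than one family), the input to
#' [loglinear_3way()] and to layer-wise [contingency_2x2()] analyses.
#'
#' @param classified Output of [classify_snps()].
#' @param method_of Function mapping the `methods` list-column entries of a
#'   record to a single method label (default: first method).
#' @return A tibble with columns `accuracy`, `method`, `support`, `n`.
#' @export
grouping_table <- function(classified,
                           method_of = function(m) m[[1]]) {
  classified |>
    dplyr::filter(.data$category != "unclassifiable") |>
    dplyr::mutate(
      accuracy = ifelse(.data$is_consensus, "conLG", "non-conLG"),
      method = purrr::map_chr(.data$methods, method_of),
      support = ifelse(.data$n_families > 1, ">1 family", "1 family")
    ) |>
    dplyr::count(.data$accuracy, .data$method, .data$support, name = "n")
}
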