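#' Assign contigs to chromosomes from linkage evidence
#'
#' Each contig carrying at least one high-confidence SNP is assigned to the
#' chromosome corresponding to its consensus linkage group; contigs without
#' high-confidence SNPs stay unplaced.
#'
#' @param classified Output of [classify_snps()].
#' @param lg_to_chrom Named character vector: linkage group -> chromosome.
#' @return A tibble `contig`, `consensus_lg`, `chrom` (`NA` = unplaced),
#'   `n_high_confidence`.
#' @export
assign_chromosomes <- function(classified, lg_to_chrom) {
  per_contig <- classified |>
    dplyr::group_by(.data$contig) |>
    dplyr::summarise(
      consensus_lg = .data$consensus_lg[1],
      n_high_confidence = sum(.data$high_confidence),
      .groups = "drop"
    )
  placeable <- !is.na(per_contig$consensus_lg) &
    per_contig$n_high_confidence > 0
  unknown <- setdiff(per_contig$consensus_lg[placeable], names(lg_to_chrom))
  if (length(unknown)) {
    stop("linkage group(s) missing from correspondence: ",
         paste(unknown, collapse = ", "))
  }
  per_contig$chrom <- ifelse(placeable,
                             unname(lg_to_chrom[per_contig$consensus_lg]),
                             NA_character_)
  per_contig
}

# build a contig_layout tibble from ordered contigs per object
layout_from_order <- function(contig, object, orientation, length_bp,
                              gap = 100) {
  out <- list()
  part_rows <- split(seq_along(contig), factor(object, unique(object)))
  for (obj in names(part_rows)) {
    idx <- part_rows[[obj]]
    pos <- 1L
    part <- 1L
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (j > 1 && gap > 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          object = obj, object_start = pos, object_end = pos + gap - 1L,
          part = part, type = "U", contig = NA_character_,
          contig_start = NA_integer_, contig_end = NA_integer_,
          orientation = NA_character_, gap_length = as.integer(gap))
        pos <- pos + as.integer(gap)
        part <- part + 1L
      }
      out[[length(out) + 1]] <- tibble::tibble(
        object = obj, object_start = pos,
        object_end = pos + length_bp[i] - 1L, part = part, type = "W",
        contig = contig[i], contig_start = 1L,
        contig_end = as.integer(length_bp[i]),
        orientation = orientation[i], gap_length = NA_integer_)
      pos <- pos + as.integer(length_bp[i])
      part <- part + 1L
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("contig_layout", class(res))
  res
}

#' Order and orient contigs from multi-map linkage evidence
#'
#' Within each chromosome, contigs are ordered by their weight-averaged
#' mean genetic position: each map contributes the mean cM of the contig's
#' SNPs on that map, min-max scaled to `[0, 1]` per map and chromosome
#' before averaging (making the order invariant to per-map affine
#' rescaling of cM). Orientation is the sign of the weighted mean rank
#' correlation between contig position (bp) and genetic position (cM) over
#' maps with at least two distinct genetic positions on the contig; a
#' contig with no such map, or with mean absolute correlation below 0.1,
#' gets orientation `"?"`. Ties in mean position are broken by more
#' supporting SNPs, then by contig id.
#'
#' @param classified Output of [classify_snps()] (high-confidence SNPs are
#'   used).
#' @param maps Named list of linkage maps (tibbles `marker`, `lg`,
#'   `pos_cm`).
#' @param assignment Output of [assign_chromosomes()].
#' @param contig_lengths Named vector of contig lengths in bp.
#' @param weights Optional named numeric vector of per-map weights
#'   (default: every map weighs 1).
#' @param gap Gap length between consecutive contigs (bp, default 100).
#' @return A list of class `anchoring`: `layout` (a `contig_layout` with
#'   `U` gap rows; unplaced contigs in object `"unplaced"`), `placements`
#'   (tibble `contig`, `chrom`, `mean_pos`, `orientation`, `rho`,
#'   `n_snps`).
#' @export
order_and_orient <- function(classified, maps, assignment, contig_lengths,
                             weights = NULL, gap = 100) {
  if (length(maps) < 1) stop("need at least one map")
  if (is.null(names(maps)) || any(names(maps) == "")) {
    names(maps) <- paste0("map", seq_along(maps))
  }
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(maps)), names(maps))
  }
  # positional evidence comes from high-confidence SNPs assigned to their
  # contig's consensus group; replicated non-consensus SNPs (category 3)
  # flag misassembly but carry another chromosome's cM scale
  hc <- classified[classified$high_confidence & classified$is_consensus, ]
  if (nrow(hc) == 0) stop("no high-confidence SNPs to anchor with")
  placed <- assignment[!is.na(assignment$chrom), ]
  evidence <- purrr::imap_dfr(maps, function(m, nm) {
    hit <- dplyr::inner_join(
      dplyr::select(hc, "marker", "contig", "contig_pos"),
      dplyr::select(m, "marker", "pos_cm"), by = "marker")
    if (nrow(hit) == 0) return(NULL)
    hit$map <- nm
    hit
  }) |>
    dplyr::inner_join(dplyr::select(placed, "contig", "chrom"),
                      by = "contig")
  if (nrow(evidence) == 0) stop("no positioned high-confidence SNPs in maps")
  # per map x chromosome: contig mean cM, then min-max scale across contigs
  contig_map <- evidence |>
    dplyr::group_by(.data$map, .data$chrom, .data$contig) |>
    dplyr::summarise(
      mean_cm = mean(.data$pos_cm),
      n_snps = dplyr::n(),
      rho = if (dplyr::n_distinct(.data$pos_cm) >= 2)
        suppressWarnings(stats::cor(.data$contig_pos, .data$pos_cm,
                                    method = "spearman")) else NA_real_,
      .groups = "drop_last"
    ) |>
    dplyr::mutate(
      scaled = if (dplyr::n() > 1 && diff(range(.data$mean_cm)) > 0)
        (.data$mean_cm - min(.data$mean_cm)) / diff(range(.data$mean_cm))
      else 0.5,
      w = unname(weights[.data$map[1]])
    ) |>
    dplyr::ungroup()
  placements <- contig_map |>
    dplyr::group_by(.data$chrom, .data$contig) |>
    dplyr::summarise(
      mean_pos = stats::weighted.mean(.data$scaled, .data$w),
      n_snps = sum(.data$n_snps),
      rho = if (all(is.na(.data$rho))) NA_real_ else
        stats::weighted.mean(.data$rho, .data$w, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      orientation = dplyr::case_when(
        is.na(rho) ~ "?",
        abs(rho) < 0.1 ~ "?",
        rho > 0 ~ "+",
        TRUE ~ "-"
      )
    ) |>
    dplyr::arrange(.data$chrom, .data$mean_pos,
                   dplyr::desc(.data$n_snps), .data$contig)
  missing_len <- setdiff(placements$contig, names(contig_lengths))
  if (length(missing_len)) {
    stop("no length for contig(s): ", paste(missing_len, collapse = ", "))
  }
  unplaced <- setdiff(names(contig_lengths), placements$contig)
  layout <- layout_from_order(
    c(placements$contig, unplaced),
    c(placements$chrom, rep("unplaced", length(unplaced))),
    c(placements$orientation, rep("?", length(unplaced))),
    unname(contig_lengths[c(placements$contig, unplaced)]),
    gap = gap
  )
  structure(list(layout = layout, placements = placements),
            class = "anchoring")
}

#' @export
print.anchoring <- function(x, ...) {
  cat(sprintf("anchoring: %d contigs on %d chromosomes\n",
              nrow(x$placements), dplyr::n_distinct(x$placements$chrom)))
  invisible(x)
}

#' Build pseudomolecule sequences from a layout
#'
#' Concatenates contig sequences in layout order, reverse-complementing
#' contigs with orientation `"-"` and inserting `N` runs for gap rows, and
#' returns the FASTA-ready sequences together with the layout. Orientation
#' `"?"` is treated as `"+"` in sequence (the layout retains the `?`).
#'
#' @param layout A `contig_layout` (e.g. from [order_and_orient()]).
#' @param seqs A [Biostrings::DNAStringSet] of contig sequences.
#' @return A [Biostrings::DNAStringSet], one sequence per layout object.
#' @export
build_pseudomolecules <- function(layout, seqs) {
  comp <- layout[layout$type == "W", ]
  missing_seq <- setdiff(comp$contig, names(seqs))
  if (length(missing_seq)) {
    stop("missing sequence for contig(s): ",
         paste(missing_seq, collapse = ", "))
  }
  lens <- Biostrings::width(seqs)[match(comp$contig, names(seqs))]
  bad <- comp$contig[lens != comp$contig_end - comp$contig_start + 1L]
  if (length(bad)) {
    stop("sequence length disagrees with layout for: ",
         paste(bad, collapse = ", "))
  }
  objs <- unique(layout$object)
  out <- Biostrings::DNAStringSet(vapply(objs, function(obj) {
    rows <- layout[layout$object == obj, ]
    rows <- rows[order(rows$part), ]
    pieces <- vapply(seq_len(nrow(rows)), function(i) {
      if (rows$type[i] %in% c("N", "U")) {
        strrep("N", rows$gap_length[i])
      } else {
        s <- seqs[[rows$contig[i]]]
        if (identical(rows$orientation[i], "-")) {
          s <- Biostrings::reverseComplement(s)
        }
        as.character(s)
      }
    }, character(1))
    paste(pieces, collapse = "")
  }, character(1)))
  names(out) <- objs
  out
}

#' Total object lengths of a layout
#'
#' @param layout A `contig_layout`.
#' @return Tibble `object`, `length` (bp, components plus gaps).
#' @export
layout_lengths <- function(layout) {
  layout |>
    dplyr::group_by(object = .data$object) |>
    dplyr::summarise(length = max(.data$object_end), .groups = "drop")
}

#' Compare two contig layouts
#'
#' Classifies every shared contig into one of five exhaustive, mutually
#' exclusive concordance categories: `identical` (same chromosome, same
#' relative order, same orientation), `different_order` (same chromosome,
#' different relative order, with the offset in rank positions),
#' `reversed_orientation` (same chromosome and order, opposite
#' orientation), `orientation_unknown` (orientation `?` in the test
#' layout), and `different_chromosome`. Relative order is compared over
#' the contigs shared by both layouts on the reference chromosome.
#'
#' @param test,reference `contig_layout` tibbles.
#' @return A list of class `concordance_report`: `contigs` (tibble
#'   `contig`, `chrom_test`, `chrom_ref`, `category`, `order_offset`),
#'   `summary` (tibble `category`, `n`, `fraction`), `excluded` (contigs
#'   absent from the reference).
#' @export
compare_layouts <- function(test, reference) {
  comp <- function(l) {
    l[l$type == "W" & l$object != "unplaced", ] |>
      dplyr::group_by(.data$object) |>
      dplyr::arrange(.data$object_start, .by_group = TRUE) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::select("contig", chrom = "object", "orientation", "rank")
  }
  t <- comp(test)
  r <- comp(reference)
  excluded <- setdiff(t$contig, r$contig)
  shared <- dplyr::inner_join(t, r, by = "contig",
                              suffix = c("_test", "_ref"))
  # relative order is compared over contigs shared by both layouts AND on
  # the same chromosome in both, so one relocated contig does not shift
  # every rank around it
  shared <- shared |>
    dplyr::mutate(same_chrom = .data$chrom_test == .data$chrom_ref) |>
    dplyr::group_by(.data$chrom_ref, .data$same_chrom) |>
    dplyr::mutate(
      rank_ref2 = ifelse(.data$same_chrom, rank(.data$rank_ref), NA_real_),
      rank_test2 = ifelse(.data$same_chrom, rank(.data$rank_test), NA_real_)
    ) |>
    dplyr::ungroup()
  shared <- shared |>
    dplyr::mutate(
      same_order = .data$same_chrom & .data$rank_test2 == .data$rank_ref2,
      order_offset = ifelse(.data$same_chrom,
                            abs(.data$rank_test2 - .data$rank_ref2),
                            NA_real_),
      category = dplyr::case_when(
        !same_chrom ~ "different_chromosome",
        !same_order ~ "different_order",
        orientation_test == "?" ~ "orientation_unknown",
        orientation_test == orientation_ref ~ "identical",
        TRUE ~ "reversed_orientation"
      )
    )
  summary <- shared |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  structure(list(
    contigs = dplyr::select(shared, "contig", "chrom_test", "chrom_ref",
                            "category", "order_offset"),
    summary = summary,
    excluded = excluded
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Layout concordance\n")
  print(x$summary)
  if (length(x$excluded)) {
    cat("excluded (absent from reference):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
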