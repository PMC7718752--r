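#' Read a linkage map from TSV
#'
#' Expects a tab-separated file with columns `marker`, `lg`, `pos_cm` and
#' optionally `mating_type`. Lines starting with `#` are metadata of the
#' form `# key: value` (e.g. `# family: 23x31`, `# parent: dam`) and are
#' attached as attributes. Missing values are written `NA`; files are UTF-8.
#'
#' @param path File path.
#' @return A tibble with the map columns; attributes `family` and `parent`
#'   if present in the metadata header.
#' @export
read_linkage_map <- function(path) {
  header <- read_hash_metadata(path)
  map <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         na = "NA", progress = FALSE)
  required <- c("marker", "lg", "pos_cm")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols)) {
    stop("linkage map ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(map$pos_cm)) {
    bad <- which(is.na(suppressWarnings(as.numeric(map$pos_cm))))
    stop("non-numeric cM position in ", path, " at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  dup <- map$marker[duplicated(map$marker)]
  if (length(dup)) {
    row <- which(map$marker == dup[1])[2]
    stop("duplicate marker id '", dup[1], "' in ", path, " (data row ", row, ")")
  }
  map <- dplyr::arrange(map, .data$lg, .data$pos_cm)
  attr(map, "family") <- header[["family"]]
  attr(map, "parent") <- header[["parent"]]
  map
}

#' Write a linkage map to TSV
#'
#' @param map Data frame with columns `marker`, `lg`, `pos_cm` (and any
#'   extras). Attributes or arguments `family`/`parent` become `#` metadata
#'   header lines.
#' @param path Output path.
#' @param family,parent Optional metadata; default to the map's attributes.
#' @return `path`, invisibly.
#' @export
write_linkage_map <- function(map, path, family = attr(map, "family"),
                              parent = attr(map, "parent")) {
  lines <- character(0)
  if (!is.null(family)) lines <- c(lines, paste0("# family: ", family))
  if (!is.null(parent)) lines <- c(lines, paste0("# parent: ", parent))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  utils::write.table(map, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_hash_metadata <- function(path) {
  lines <- readLines(path, n = 50L, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in meta) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

#' Read a SNP coordinate table
#'
#' Tab-separated with columns `marker`, `contig`, `contig_pos`, `chrom`,
#' `chrom_pos` (1-based positions). One row per marker.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_coordinates <- function(path) {
  coords <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                            na = "NA", progress = FALSE)
  required <- c("marker", "contig", "contig_pos", "chrom", "chrom_pos")
  missing_cols <- setdiff(required, names(coords))
  if (length(missing_cols)) {
    stop("coordinate table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(coords$marker)) {
    stop("duplicate marker id '",
         coords$marker[duplicated(coords$marker)][1], "' in ", path)
  }
  if (any(coords$contig_pos < 1) || any(coords$chrom_pos < 1)) {
    stop("positions must be >= 1 (1-based) in ", path)
  }
  coords
}

#' Write a SNP coordinate table
#' @param coords Tibble as returned by [read_coordinates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(coords, path) {
  utils::write.table(coords, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a contig layout from AGP v2
#'
#' Parses an AGP v2.0 file describing ordered, oriented components within
#' assembled objects. Component rows (type `W`) and gap rows (`N`/`U`) are
#' supported; comment lines start with `#`.
#'
#' @param path File path.
#' @return A `contig_layout`: tibble with columns `object`, `object_start`,
#'   `object_end`, `part`, `type`, `contig`, `contig_start`, `contig_end`,
#'   `orientation`, `gap_length`.
#' @export
read_layout <- function(path) {
  cols <- c("object", "object_start", "object_end", "part", "type",
            "c6", "c7", "c8", "c9")
  agp <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = cols, stringsAsFactors = FALSE,
                           fill = TRUE)
  agp$object_start <- as.integer(agp$object_start)
  agp$object_end <- as.integer(agp$object_end)
  is_gap <- agp$type %in% c("N", "U")
  out <- tibble::tibble(
    object = agp$object,
    object_start = agp$object_start,
    object_end = agp$object_end,
    part = as.integer(agp$part),
    type = agp$type,
    contig = ifelse(is_gap, NA_character_, agp$c6),
    contig_start = ifelse(is_gap, NA_integer_, suppressWarnings(as.integer(agp$c7))),
    contig_end = ifelse(is_gap, NA_integer_, suppressWarnings(as.integer(agp$c8))),
    orientation = ifelse(is_gap, NA_character_, agp$c9),
    gap_length = ifelse(is_gap, suppressWarnings(as.integer(agp$c6)), NA_integer_)
  )
  # coordinates within an object must tile without overlap
  by_obj <- split(out, out$object)
  for (obj in by_obj) {
    obj <- obj[order(obj$part), ]
    if (any(obj$object_start[-1] <= obj$object_end[-nrow(obj)]) && nrow(obj) > 1) {
      stop("overlapping object coordinates in AGP object ", obj$object[1])
    }
  }
  class(out) <- c("contig_layout", class(out))
  out
}

#' Write a contig layout to AGP v2
#'
#' @param layout A `contig_layout` tibble (see [read_layout()] or
#'   [order_and_orient()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  is_gap <- layout$type %in% c("N", "U")
  fields <- ifelse(
    is_gap,
    paste(layout$object, layout$object_start, layout$object_end, layout$part,
          layout$type, layout$gap_length, "scaffold", "yes", "map",
          sep = "\t"),
    paste(layout$object, layout$object_start, layout$object_end, layout$part,
          layout$type, layout$contig, layout$contig_start, layout$contig_end,
          layout$orientation, sep = "\t")
  )
  writeLines(fields, con)
  invisible(path)
}

#' Write intervals to BED
#'
#' Writes half-open, 0-based BED3+ records. Input positions are 1-based
#' inclusive (as carried in package tables) and are converted.
#'
#' @param intervals Data frame with columns `seqname`, `start`, `end`
#'   (1-based inclusive) and optional `name`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  bed <- data.frame(
    seqname = intervals$seqname,
    start = intervals$start - 1L,
    end = intervals$end,
    stringsAsFactors = FALSE
  )
  if ("name" %in% names(intervals)) bed$name <- intervals$name
  if ("score" %in% names(intervals)) bed$score <- intervals$score
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read contig sequences from FASTA
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_contig_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write contig sequences to FASTA
#' @param seqs A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contig_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
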