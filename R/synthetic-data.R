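# Deterministic child RNG streams: one root seed, one stream per
# family/parent/gamete, so adding progeny never perturbs earlier draws.
# Constants chosen so all intermediates stay below 2^53 (exact doubles).
child_seed <- function(root, ...) {
  s <- as.double(root) %% 2147483647
  for (k in as.double(c(...))) {
    s <- (s * 48271 + k * 65537 + 11) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(expr)
}

#' Build a synthetic genome model
#'
#' Generates chromosomes tiled by contigs and populated with SNPs, with
#' known coordinates on both contig and chromosome scales. Defaults emulate
#' a bivalve-sized genome: 10 chromosomes of 56 Mb (560 Mb total) split
#' into 300 contigs.
#'
#' Contigs tile each chromosome without gaps or overlap; SNP chromosome
#' position equals contig start + contig position - 1 (positions 1-based
#' inclusive).
#'
#' @param chrom_lengths Named or unnamed numeric vector of chromosome
#'   lengths in bp. Default `rep(56e6, 10)`.
#' @param n_contigs Total contig count, apportioned to chromosomes in
#'   proportion to length (at least one each).
#' @param snp_density SNPs per Mb per chromosome. The default, 12.5/Mb
#'   (about 7,000 genome-wide), matches the per-family marker yield of a
#'   genotyping-by-sequencing experiment on a genome of this size.
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   genome exactly.
#' @return A `genome_model`: list with tibbles `chromosomes` (`chrom`,
#'   `length`), `contigs` (`contig`, `chrom`, `start`, `end`), and `snps`
#'   (`snp`, `contig`, `contig_pos`, `chrom`, `chrom_pos`).
#' @examples
#' g <- build_genome(chrom_lengths = c(5e6, 5e6), n_contigs = 6,
#'                   snp_density = 4, seed = 1)
#' g$chromosomes
#' @export
build_genome <- function(chrom_lengths = rep(56e6, 10), n_contigs = 300,
                         snp_density = 12.5, seed = 1) {
  if (length(chrom_lengths) < 1) stop("need at least one chromosome")
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome")
  if (n_contigs < length(chrom_lengths)) {
    stop("contig count must be at least the chromosome count")
  }
  if (snp_density <= 0) stop("SNP density must be positive")
  n_chrom <- length(chrom_lengths)
  chrom_ids <- if (!is.null(names(chrom_lengths))) names(chrom_lengths) else
    paste0("chr", seq_len(n_chrom))
  with_seed(child_seed(seed, 101), {
    # apportion contigs to chromosomes proportionally (>= 1 each)
    share <- chrom_lengths / sum(chrom_lengths)
    k <- pmax(1L, round(share * n_contigs))
    while (sum(k) != n_contigs) {
      i <- if (sum(k) > n_contigs) which.max(k) else which.min(k / share)
      k[i] <- k[i] + sign(n_contigs - sum(k))
    }
    contigs <- purrr::map_dfr(seq_len(n_chrom), function(ci) {
      len <- chrom_lengths[ci]
      nc <- k[ci]
      cuts <- if (nc > 1) sort(sample(seq_len(len - 1), nc - 1)) else integer(0)
      starts <- c(1, cuts + 1)
      ends <- c(cuts, len)
      tibble::tibble(chrom = chrom_ids[ci], start = starts, end = ends)
    })
    contigs <- contigs |>
      dplyr::mutate(contig = sprintf("ctg%03d", dplyr::row_number()),
                    .before = 1)
    snps <- purrr::map_dfr(seq_len(n_chrom), function(ci) {
      len <- chrom_lengths[ci]
      n_snp <- max(2L, round(snp_density * len / 1e6))
      pos <- sort(sample(seq_len(len), n_snp))
      tibble::tibble(chrom = chrom_ids[ci], chrom_pos = pos)
    })
  })
  snps <- snps |>
    dplyr::left_join(contigs, by = "chrom",
                     relationship = "many-to-many") |>
    dplyr::filter(.data$chrom_pos >= .data$start,
                  .data$chrom_pos <= .data$end) |>
    dplyr::transmute(
      snp = paste0(.data$chrom, "_", .data$chrom_pos),
      contig = .data$contig,
      contig_pos = .data$chrom_pos - .data$start + 1L,
      chrom = .data$chrom,
      chrom_pos = .data$chrom_pos
    )
  structure(
    list(
      chromosomes = tibble::tibble(chrom = chrom_ids,
                                   length = unname(chrom_lengths)),
      contigs = contigs[, c("contig", "chrom", "start", "end")],
      snps = snps
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes (%.1f Mb), %d contigs, %d SNPs\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              nrow(x$contigs), nrow(x$snps)))
  invisible(x)
}

#' SNP coordinate table of a genome model
#'
#' @param genome A `genome_model`.
#' @return A tibble with columns `marker`, `contig`, `contig_pos`, `chrom`,
#'   `chrom_pos`, the coordinate-table layout consumed by
#'   [merge_compendium()].
#' @export
coordinate_table <- function(genome) {
  dplyr::rename(genome$snps, marker = "snp")
}

#' Reference contig layout of a genome model
#'
#' @param genome A `genome_model`.
#' @param gap Gap length recorded between consecutive contigs (bp).
#' @return A `contig_layout` tibble (component rows only when `gap = 0`).
#' @export
genome_layout <- function(genome, gap = 0) {
  lens <- genome$contigs$end - genome$contigs$start + 1L
  layout_from_order(
    genome$contigs$contig, genome$contigs$chrom,
    rep("+", nrow(genome$contigs)), lens, gap = gap
  )
}

#' Define a recombination landscape
#'
#' A piecewise-constant crossover-rate landscape (cM/Mb) per chromosome,
#' optionally modulated by hotspot/coldspot intervals with multiplicative
#' factors. The cumulative genetic map of a chromosome is the integral of
#' the rate, and is nondecreasing.
#'
#' @param genome A `genome_model`.
#' @param base_rate Baseline rate in cM/Mb; a single value or a vector, one
#'   per chromosome. The default gives every chromosome a 60 cM map,
#'   emulating 1.1-1.2 chiasmata per bivalent.
#' @param modifiers Optional tibble `chrom`, `start`, `end` (bp, 1-based
#'   inclusive), `factor` of multiplicative hotspot (>1) or coldspot (<1)
#'   intervals.
#' @return A `recomb_landscape`: list with `segments` (tibble `chrom`,
#'   `start`, `end` half-open 0-based, `rate` cM/Mb) and `modifiers`.
#' @export
recomb_landscape <- function(genome, base_rate = NULL, modifiers = NULL) {
  chroms <- genome$chromosomes
  if (is.null(base_rate)) base_rate <- 60 / (chroms$length / 1e6)
  base_rate <- rep_len(base_rate, nrow(chroms))
  if (any(base_rate < 0)) stop("rates must be >= 0")
  segments <- purrr::map_dfr(seq_len(nrow(chroms)), function(i) {
    breaks <- c(0, chroms$length[i])
    mods <- NULL
    if (!is.null(modifiers)) {
      mods <- modifiers[modifiers$chrom == chroms$chrom[i], , drop = FALSE]
      breaks <- sort(unique(c(breaks, mods$start - 1, mods$end)))
      breaks <- breaks[breaks >= 0 & breaks <= chroms$length[i]]
    }
    seg <- tibble::tibble(
      chrom = chroms$chrom[i],
      start = breaks[-length(breaks)],
      end = breaks[-1],
      rate = base_rate[i]
    )
    if (!is.null(mods) && nrow(mods)) {
      for (j in seq_len(nrow(mods))) {
        hit <- seg$start >= mods$start[j] - 1 & seg$end <= mods$end[j]
        seg$rate[hit] <- seg$rate[hit] * mods$factor[j]
      }
    }
    seg
  })
  if (any(segments$rate < 0)) stop("rates must be >= 0")
  structure(list(segments = segments, modifiers = modifiers),
            class = "recomb_landscape")
}

# piecewise-linear cumulative map knots for one chromosome:
# bp (0-based) -> cumulative cM
landscape_knots <- function(landscape, chrom) {
  seg <- landscape$segments[landscape$segments$chrom == chrom, , drop = FALSE]
  if (nrow(seg) == 0) stop("unknown chromosome: ", chrom)
  seg <- seg[order(seg$start), ]
  cm <- cumsum(seg$rate * (seg$end - seg$start) / 1e6)
  list(bp = c(seg$start[1], seg$end), cm = c(0, cm))
}

#' Genetic length of a chromosome under a landscape
#'
#' @param landscape A `recomb_landscape`.
#' @param chrom Chromosome id.
#' @param multiplier Per-parent rate multiplier.
#' @return Genetic length in cM.
#' @export
genetic_length <- function(landscape, chrom, multiplier = 1) {
  k <- landscape_knots(landscape, chrom)
  utils::tail(k$cm, 1) * multiplier
}

#' Cumulative genetic position of physical positions
#'
#' @param landscape A `recomb_landscape`.
#' @param chrom Chromosome id.
#' @param bp Physical positions (1-based).
#' @param multiplier Per-parent rate multiplier.
#' @return Genetic positions in cM (nondecreasing in `bp`).
#' @export
genetic_position <- function(landscape, chrom, bp, multiplier = 1) {
  k <- landscape_knots(landscape, chrom)
  stats::approx(k$bp, k$cm, xout = bp - 0.5, rule = 2)$y * multiplier
}

# inverse cumulative map: cM -> bp; requires strictly positive rates
invert_genetic <- function(landscape, chrom, cm) {
  k <- landscape_knots(landscape, chrom)
  if (any(duplicated(k$cm))) {
    keep <- !duplicated(k$cm)
    k$bp <- k$bp[keep]
    k$cm <- k$cm[keep]
  }
  stats::approx(k$cm, k$bp, xout = cm, rule = 2)$y
}

#' Simulate crossover positions for one gamete
#'
#' The crossover count is Poisson with mean `L/100` (map length `L` in cM:
#' one crossover per morgan, no interference, consistent with Haldane map
#' units); positions are uniform on the genetic map and carried back to
#' physical coordinates by inverting the cumulative map. With
#' `obligate = TRUE`, bivalent crossovers are drawn zero-truncated-Poisson
#' with mean `2L/100` and thinned by 1/2 into the gamete, enforcing at
#' least one crossover per bivalent.
#'
#' @param landscape A `recomb_landscape`.
#' @param chrom Chromosome id.
#' @param multiplier Per-parent rate multiplier (sex-by-family effect).
#' @param seed Integer seed for this gamete's stream.
#' @param obligate Enforce an obligate chiasma per bivalent (default off).
#' @return Sorted numeric vector of crossover positions in bp (possibly
#'   empty), strictly inside the chromosome.
#' @export
simulate_crossovers <- function(landscape, chrom, multiplier = 1, seed = 1,
                                obligate = FALSE) {
  lg <- genetic_length(landscape, chrom, multiplier)
  with_seed(seed, {
    if (lg <= 0) return(numeric(0))
    if (obligate) {
      lam <- 2 * lg / 100
      kb <- stats::qpois(stats::runif(1, stats::dpois(0, lam), 1), lam)
      n <- stats::rbinom(1, kb, 0.5)
    } else {
      n <- stats::rpois(1, lg / 100)
    }
    if (n == 0) return(numeric(0))
    u <- sort(stats::runif(n, 0, lg))
    sort(invert_genetic(landscape, chrom, u / multiplier))
  })
}

#' Describe a mapping family design
#'
#' @param family Family id.
#' @param sire,dam Parent ids.
#' @param n_progeny Number of F2 progeny (>= 1).
#' @param sire_mult,dam_mult Per-parent landscape multipliers. The defaults,
#'   1.0 and 1.25, emulate the higher recombination rate of maternal
#'   parents.
#' @param mating_props Proportions of the three cross-pollinated mating
#'   types among markers: `hkxhk` (bi-parental), `lmxll` (dam-informative),
#'   `nnxnp` (sire-informative).
#' @param error_rate,missing_rate Genotyping error and missing-data rates
#'   in `[0, 1]`. Defaults emulate an observed 2-3% error rate.
#' @param seed Family-level RNG seed.
#' @return A `family_design` list.
#' @export
family_design <- function(family, sire = paste0(family, "_sire"),
                          dam = paste0(family, "_dam"), n_progeny = 100,
                          sire_mult = 1, dam_mult = 1.25,
                          mating_props = c(hkxhk = 1 / 3, lmxll = 1 / 3,
                                           nnxnp = 1 / 3),
                          error_rate = 0.025, missing_rate = 0.05,
                          seed = 1) {
  stopifnot(n_progeny >= 1,
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!all(names(mating_props) %in% c("hkxhk", "lmxll", "nnxnp"))) {
    stop("unknown mating type in mating_props")
  }
  structure(list(family = family, sire = sire, dam = dam,
                 n_progeny = as.integer(n_progeny),
                 sire_mult = sire_mult, dam_mult = dam_mult,
                 mating_props = mating_props / sum(mating_props),
                 error_rate = error_rate, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "family_design")
}

# allele letters per parental haplotype for each mating type;
# row = haplotype 0/1
mating_alleles <- list(
  hkxhk = list(sire = c("h", "k"), dam = c("h", "k")),
  lmxll = list(sire = c("l", "l"), dam = c("l", "m")),
  nnxnp = list(sire = c("n", "p"), dam = c("n", "n"))
)

legal_genotypes <- list(
  hkxhk = c("hh", "hk", "kk"),
  lmxll = c("ll", "lm"),
  nnxnp = c("nn", "np")
)

#' Simulate an F2 mapping family
#'
#' Simulates meioses for both parents of one family over a genome and
#' recombination landscape, and emits progeny genotypes under the
#' cross-pollinated mating-type coding: `hkxhk` markers segregate from both
#' parents, `lmxll` only from the dam, `nnxnp` only from the sire. Parental
#' phase is fixed (coupling), so gametic haplotypes are recorded alongside
#' genotypes and the per-parent true genetic positions of every SNP are
#' returned.
#'
#' @param genome A `genome_model`.
#' @param landscape A `recomb_landscape`.
#' @param design A [family_design()].
#' @param obligate Passed to [simulate_crossovers()].
#' @return A `family_sim` list: `genotypes` (character matrix, SNP x
#'   progeny, no error/missingness), `mating_type` (per SNP),
#'   `truth` (tibble `snp`, `chrom`, `chrom_pos`, `cm_sire`, `cm_dam`),
#'   `gametes` (list of two 0/1 integer matrices `sire`, `dam`),
#'   `crossovers` (tibble `progeny`, `parent`, `chrom`, `pos`),
#'   and `design`.
#' @export
simulate_family <- function(genome, landscape, design, obligate = FALSE) {
  stopifnot(inherits(design, "family_design"))
  snps <- genome$snps
  n_snp <- nrow(snps)
  n_prog <- design$n_progeny
  types <- with_seed(child_seed(design$seed, 7), {
    sample(names(design$mating_props), n_snp, replace = TRUE,
           prob = design$mating_props)
  })
  unknown <- setdiff(unique(types), names(mating_alleles))
  if (length(unknown)) stop("unknown mating type: ", unknown[1])
  chrom_ids <- genome$chromosomes$chrom
  snp_by_chrom <- split(seq_len(n_snp), factor(snps$chrom, levels = chrom_ids))
  parents <- c(sire = design$sire_mult, dam = design$dam_mult)
  gametes <- list(
    sire = matrix(0L, n_snp, n_prog),
    dam = matrix(0L, n_snp, n_prog)
  )
  xo_list <- list()
  for (p in c("sire", "dam")) {
    pmult <- parents[[p]]
    pidx <- match(p, c("sire", "dam"))
    for (ci in seq_along(chrom_ids)) {
      idx <- snp_by_chrom[[ci]]
      pos <- snps$chrom_pos[idx]
      for (i in seq_len(n_prog)) {
        s <- child_seed(design$seed, pidx, ci, i)
        xo <- simulate_crossovers(landscape, chrom_ids[ci], pmult, s,
                                  obligate = obligate)
        h0 <- with_seed(child_seed(s, 2), stats::rbinom(1, 1, 0.5))
        hap <- (h0 + findInterval(pos, xo)) %% 2L
        gametes[[p]][idx, i] <- hap
        if (length(xo)) {
          xo_list[[length(xo_list) + 1]] <- tibble::tibble(
            progeny = i, parent = p, chrom = chrom_ids[ci], pos = xo)
        }
      }
    }
  }
  geno <- matrix(NA_character_, n_snp, n_prog,
                 dimnames = list(snps$snp,
                                 sprintf("%s_p%03d", design$family,
                                         seq_len(n_prog))))
  for (tp in unique(types)) {
    rows <- which(types == tp)
    al <- mating_alleles[[tp]]
    a_sire <- al$sire[gametes$sire[rows, , drop = FALSE] + 1L]
    a_dam <- al$dam[gametes$dam[rows, , drop = FALSE] + 1L]
    g <- ifelse(a_sire <= a_dam, paste0(a_sire, a_dam), paste0(a_dam, a_sire))
    geno[rows, ] <- g
  }
  truth <- tibble::tibble(
    snp = snps$snp, chrom = snps$chrom, chrom_pos = snps$chrom_pos,
    cm_sire = unlist(purrr::map(seq_along(chrom_ids), function(ci) {
      genetic_position(landscape, chrom_ids[ci],
                       snps$chrom_pos[snp_by_chrom[[ci]]],
                       design$sire_mult)
    })),
    cm_dam = unlist(purrr::map(seq_along(chrom_ids), function(ci) {
      genetic_position(landscape, chrom_ids[ci],
                       snps$chrom_pos[snp_by_chrom[[ci]]],
                       design$dam_mult)
    }))
  )
  structure(
    list(genotypes = geno, mating_type = stats::setNames(types, snps$snp),
         truth = truth, gametes = gametes,
         crossovers = if (length(xo_list)) dplyr::bind_rows(xo_list) else
           tibble::tibble(progeny = integer(), parent = character(),
                          chrom = character(), pos = numeric()),
         design = design),
    class = "family_sim"
  )
}

#' @export
print.family_sim <- function(x, ...) {
  cat(sprintf("family_sim %s: %d SNPs x %d progeny, %d crossovers\n",
              x$design$family, nrow(x$genotypes), ncol(x$genotypes),
              nrow(x$crossovers)))
  invisible(x)
}

#' Apply genotyping error and missingness
#'
#' Each called genotype is independently replaced by a different legal
#' genotype of its mating type with probability `error_rate`, then set
#' missing with probability `missing_rate`. The input is untouched, so
#' truth is retained by keeping the original matrix.
#'
#' @param genotypes Character matrix (SNP x progeny) from
#'   [simulate_family()].
#' @param mating_type Named character vector of mating types per SNP.
#' @param error_rate,missing_rate Rates in `[0, 1]`.
#' @param seed Integer seed.
#' @return Degraded genotype matrix of the same shape (`NA` = missing).
#' @export
degrade_genotypes <- function(genotypes, mating_type, error_rate,
                              missing_rate, seed = 1) {
  stopifnot(error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  out <- genotypes
  with_seed(child_seed(seed, 3), {
    if (error_rate > 0) {
      flip <- matrix(stats::runif(length(out)) < error_rate, nrow(out))
      for (tp in unique(mating_type)) {
        legal <- legal_genotypes[[tp]]
        cells <- which(flip & matrix(mating_type == tp, nrow(out),
                                     ncol(out)))
        if (length(cells)) {
          cur <- out[cells]
          pick <- vapply(cur, function(g) {
            sample(setdiff(legal, g), 1)
          }, character(1))
          out[cells] <- pick
        }
      }
    }
    if (missing_rate > 0) {
      out[matrix(stats::runif(length(out)) < missing_rate, nrow(out))] <-
        NA_character_
    }
  })
  out
}

#' Plan assembly corruptions
#'
#' @param chimeric Tibble with one row per chimeric block to inject:
#'   columns `host_contig`, `donor_contig`, `n_snps` (block size in SNPs),
#'   and optionally `spacing` (bp between block SNPs, default 15). The
#'   donor must lie on a different chromosome than the host.
#' @param flips Character vector of contig ids whose orientation to
#'   reverse.
#' @param moves Tibble with columns `contig`, `new_index` (target rank of
#'   the contig within its chromosome's contig order).
#' @return A `corruption_plan` list.
#' @export
corruption_plan <- function(chimeric = NULL, flips = character(0),
                            moves = NULL) {
  structure(list(chimeric = chimeric, flips = flips, moves = moves),
            class = "corruption_plan")
}

#' Corrupt a genome assembly with known truth
#'
#' Splices blocks of SNPs from donor contigs into host contigs on other
#' chromosomes (chimeric blocks), reverses contig orientations, and moves
#' contigs within their chromosome's order, recording every corruption in
#' a truth record. The corrupted model represents the *claimed* assembly
#' coordinates; meiosis simulated on the original genome combined with the
#' corrupted coordinates reproduces the signal of a misassembled contig.
#'
#' @param genome A `genome_model` (the true genome).
#' @param plan A [corruption_plan()].
#' @param seed Integer seed (placement of spliced blocks).
#' @return A list: `genome` (corrupted `genome_model`), `truth` (list with
#'   `chimeric_blocks` tibble, `flips`, `moves`).
#' @export
corrupt_assembly <- function(genome, plan, seed = 1) {
  stopifnot(inherits(plan, "corruption_plan"))
  snps <- genome$snps
  contigs <- genome$contigs
  blocks <- list()
  if (!is.null(plan$chimeric) && nrow(plan$chimeric)) {
    for (b in seq_len(nrow(plan$chimeric))) {
      row <- plan$chimeric[b, ]
      spacing <- if ("spacing" %in% names(row)) row$spacing else 15L
      host <- contigs[contigs$contig == row$host_contig, ]
      donor <- contigs[contigs$contig == row$donor_contig, ]
      if (nrow(host) == 0 || nrow(donor) == 0) stop("unknown contig in plan")
      if (host$chrom == donor$chrom) {
        stop("chimeric donor must lie on a different chromosome than host")
      }
      didx <- which(snps$contig == row$donor_contig)
      if (length(didx) < row$n_snps) {
        stop("donor contig ", row$donor_contig, " has fewer than ",
             row$n_snps, " SNPs")
      }
      span <- (row$n_snps - 1) * spacing + 1
      host_len <- host$end - host$start + 1
      if (span > host_len) stop("block longer than host contig")
      didx <- didx[order(snps$contig_pos[didx])]
      start_d <- with_seed(child_seed(seed, 11, b),
                           sample(length(didx) - row$n_snps + 1, 1))
      take <- didx[start_d:(start_d + row$n_snps - 1)]
      # place the block in a free window of the host contig
      hpos <- sort(snps$contig_pos[snps$contig == row$host_contig])
      anchor <- with_seed(child_seed(seed, 13, b), {
        free <- setdiff(seq_len(host_len - span + 1),
                        unlist(lapply(hpos, function(p)
                          max(1, p - span):(p))))
        if (!length(free)) stop("no room in host contig for block")
        sample(free, 1)
      })
      new_cpos <- anchor + spacing * (seq_len(row$n_snps) - 1L)
      snps$contig[take] <- row$host_contig
      snps$contig_pos[take] <- new_cpos
      snps$chrom[take] <- host$chrom
      snps$chrom_pos[take] <- host$start + new_cpos - 1L
      blocks[[b]] <- tibble::tibble(
        host_contig = row$host_contig,
        donor_contig = row$donor_contig,
        true_chrom = donor$chrom,
        snp = list(snps$snp[take]),
        start = min(new_cpos), end = max(new_cpos),
        length_bp = max(new_cpos) - min(new_cpos) + 1L
      )
    }
  }
  for (f in plan$flips) {
    ctg <- contigs[contigs$contig == f, ]
    if (nrow(ctg) == 0) stop("unknown contig in flips: ", f)
    len <- ctg$end - ctg$start + 1L
    idx <- which(snps$contig == f)
    snps$contig_pos[idx] <- len - snps$contig_pos[idx] + 1L
    snps$chrom_pos[idx] <- ctg$start + snps$contig_pos[idx] - 1L
  }
  moves <- NULL
  if (!is.null(plan$moves) && nrow(plan$moves)) {
    for (mvi in seq_len(nrow(plan$moves))) {
      mv <- plan$moves[mvi, ]
      chrom <- contigs$chrom[contigs$contig == mv$contig]
      if (length(chrom) == 0) stop("unknown contig in moves: ", mv$contig)
      ord <- contigs$contig[contigs$chrom == chrom]
      ord <- append(setdiff(ord, mv$contig),
                    mv$contig, after = mv$new_index - 1L)
      lens <- vapply(ord, function(cc) {
        r <- contigs[contigs$contig == cc, ]
        as.integer(r$end - r$start + 1L)
      }, integer(1))
      starts <- cumsum(c(1L, utils::head(lens, -1)))
      off_chrom <- min(contigs$start[contigs$chrom == chrom])
      for (j in seq_along(ord)) {
        sel <- contigs$contig == ord[j]
        old_start <- contigs$start[sel]
        contigs$start[sel] <- off_chrom + starts[j] - 1L
        contigs$end[sel] <- contigs$start[sel] + lens[j] - 1L
        sidx <- which(snps$contig == ord[j])
        snps$chrom_pos[sidx] <- contigs$start[sel] + snps$contig_pos[sidx] - 1L
      }
    }
    moves <- plan$moves
  }
  corrupted <- structure(
    list(chromosomes = genome$chromosomes,
         contigs = contigs[order(contigs$chrom, contigs$start), ],
         snps = snps),
    class = "genome_model"
  )
  truth <- list(
    chimeric_blocks = if (length(blocks)) dplyr::bind_rows(blocks) else
      tibble::tibble(host_contig = character(), donor_contig = character(),
                     true_chrom = character(), snp = list(),
                     start = integer(), end = integer(),
                     length_bp = integer()),
    flips = plan$flips,
    moves = moves
  )
  list(genome = corrupted, truth = truth)
}

#' True linkage maps from a family simulation
#'
#' Converts the known genetic positions of a simulated family into the
#' per-parent linkage-map tables the mapping pipeline consumes, with one
#' linkage group per chromosome.
#'
#' @param sim A `family_sim`.
#' @param lg_of_chrom Optional named vector mapping chromosome id to
#'   linkage-group label; defaults to `LG<i>` in chromosome order.
#' @return Named list of two tibbles (`sire`, `dam`) with columns `marker`,
#'   `lg`, `pos_cm`, restricted to the markers informative through that
#'   parent; attributes `family` and `parent` set.
#' @export
true_linkage_maps <- function(sim, lg_of_chrom = NULL) {
  chroms <- unique(sim$truth$chrom)
  if (is.null(lg_of_chrom)) {
    lg_of_chrom <- stats::setNames(paste0("LG", seq_along(chroms)), chroms)
  }
  informative <- list(
    sire = names(sim$mating_type)[sim$mating_type %in% c("hkxhk", "nnxnp")],
    dam = names(sim$mating_type)[sim$mating_type %in% c("hkxhk", "lmxll")]
  )
  out <- purrr::imap(informative, function(markers, parent) {
    cm <- if (parent == "sire") sim$truth$cm_sire else sim$truth$cm_dam
    m <- tibble::tibble(
      marker = sim$truth$snp,
      lg = unname(lg_of_chrom[sim$truth$chrom]),
      pos_cm = cm
    )[sim$truth$snp %in% markers, ]
    m <- dplyr::arrange(m, .data$lg, .data$pos_cm)
    attr(m, "family") <- sim$design$family
    attr(m, "parent") <- parent
    m
  })
  out
}

#' Estimated linkage maps from simulated gametes
#'
#' Builds per-parent linkage maps from a simulated family by estimating
#' adjacent recombination fractions on the true marker order (parental
#' phase is known in simulation, so the recombinant proportion between
#' adjacent informative markers is observed directly) and accumulating
#' them with a mapping function. This is the minimal end-to-end mapping
#' path: it exercises estimation noise without re-implementing a full
#' ordering algorithm.
#'
#' @param sim A `family_sim`.
#' @param method Mapping function for [positions_from_rf()] (default
#'   `"haldane"`, matching the no-interference crossover process).
#' @param lg_of_chrom Optional named vector chromosome -> linkage group.
#' @return Named list of tibbles (`sire`, `dam`) with `marker`, `lg`,
#'   `pos_cm`; attributes `family` and `parent` set.
#' @export
estimated_linkage_maps <- function(sim, method = "haldane",
                                   lg_of_chrom = NULL) {
  chroms <- unique(sim$truth$chrom)
  if (is.null(lg_of_chrom)) {
    lg_of_chrom <- stats::setNames(paste0("LG", seq_along(chroms)), chroms)
  }
  informative <- list(
    sire = c("hkxhk", "nnxnp"),
    dam = c("hkxhk", "lmxll")
  )
  purrr::imap(informative, function(types, parent) {
    gam <- sim$gametes[[parent]]
    keep <- sim$mating_type[sim$truth$snp] %in% types
    out <- purrr::map_dfr(chroms, function(ch) {
      idx <- which(keep & sim$truth$chrom == ch)
      idx <- idx[order(sim$truth$chrom_pos[idx])]
      if (length(idx) < 2) return(NULL)
      h <- gam[idx, , drop = FALSE]
      rf <- rowMeans(h[-1, , drop = FALSE] != h[-nrow(h), , drop = FALSE])
      rf <- pmin(rf, 0.5 - 1e-9)
      tibble::tibble(
        marker = sim$truth$snp[idx],
        lg = unname(lg_of_chrom[ch]),
        pos_cm = positions_from_rf(rf, method)
      )
    })
    attr(out, "family") <- sim$design$family
    attr(out, "parent") <- parent
    out
  })
}

#' Write simulated genotypes to TSV
#'
#' @param sim A `family_sim` (or degraded genotype matrix via `genotypes`).
#' @param path Output path.
#' @param genotypes Optional matrix overriding `sim$genotypes`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(sim, path, genotypes = sim$genotypes) {
  df <- data.frame(marker = rownames(genotypes),
                   mating_type = unname(sim$mating_type[rownames(genotypes)]),
                   genotypes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a corruption truth record to JSON
#'
#' @param truth Truth list from [corrupt_assembly()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(
      chimeric_blocks = truth$chimeric_blocks,
      flips = truth$flips,
      moves = truth$moves
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Synthetic contig sequences for a genome model
#'
#' Random uniform-composition DNA of the correct contig lengths, for
#' exercising pseudomolecule construction. Lengths, not content, carry the
#' information used downstream.
#'
#' @param genome A `genome_model`.
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet], one sequence per contig.
#' @export
synthetic_contig_seqs <- function(genome, seed = 1) {
  lens <- genome$contigs$end - genome$contigs$start + 1
  with_seed(child_seed(seed, 17), {
    seqs <- vapply(lens, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1))
  })
  stats::setNames(Biostrings::DNAStringSet(seqs), genome$contigs$contig)
}
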