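# Shared fixtures: a small three-chromosome genome with two mapping
# families, built fresh in code. Sizes are kept small so the whole suite
# runs quickly; truth-recovery tests that need more signal build their own.

small_genome <- function(seed = 42, n_chrom = 3, chrom_mb = 5,
                         n_contigs = 9, snp_density = 20) {
  build_genome(chrom_lengths = rep(chrom_mb * 1e6, n_chrom),
               n_contigs = n_contigs, snp_density = snp_density,
               seed = seed)
}

lg_map_for <- function(genome) {
  chroms <- genome$chromosomes$chrom
  stats::setNames(chroms, paste0("LG", seq_along(chroms)))
}

chrom_to_lg <- function(genome) {
  chroms <- genome$chromosomes$chrom
  stats::setNames(paste0("LG", seq_along(chroms)), chroms)
}

# per-parent true maps for k families; returns flat named list of maps
family_true_maps <- function(genome, landscape, n_families = 2,
                             n_progeny = 50, seed = 5) {
  maps <- list()
  for (i in seq_len(n_families)) {
    d <- family_design(paste0("fam", i), n_progeny = n_progeny,
                       seed = seed + i)
    sim <- simulate_family(genome, landscape, d)
    tm <- true_linkage_maps(sim)
    maps[[paste0("fam", i, "_sire")]] <- tm$sire
    maps[[paste0("fam", i, "_dam")]] <- tm$dam
  }
  maps
}

# contigs with at least n SNPs, by chromosome
contigs_with_snps <- function(genome, min_snps = 6) {
  counts <- table(genome$snps$contig)
  ids <- names(counts)[counts >= min_snps]
  genome$contigs[genome$contigs$contig %in% ids, ]
}

# brute-force run scan used as the oracle for detect_blocks: quadratic,
# written independently of the package's grouped-dplyr implementation
brute_force_runs <- function(lg, pos, consensus) {
  runs <- list()
  i <- 1
  n <- length(lg)
  while (i <= n) {
    if (lg[i] != consensus) {
      j <- i
      while (j < n && lg[j + 1] == lg[i]) j <- j + 1
      runs[[length(runs) + 1]] <- list(lg = lg[i], start = pos[i],
                                       end = pos[j], n = j - i + 1)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}
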