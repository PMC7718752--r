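# mapanchor

Validate chromosome-level genome assemblies with dense genetic linkage
maps, and profile recombination rates along chromosomes.

Dense linkage maps are an independent witness to an assembly's structure:
markers that co-segregate belong to one chromosome, so a block of adjacent
SNPs on a contig that maps — in more than one family — to a different
linkage group than the rest of its contig is evidence of a chimeric
(misassembled) contig. The same maps, joined to physical coordinates,
measure recombination: the local slope of the Marey map (genetic position
in cM against physical position in bp) is the recombination rate in cM/Mb.

`mapanchor` is a tidyverse-style R package for multi-family F2 designs
with cross-pollinated marker coding (`hkxhk` bi-parental, `lmxll`
dam-informative, `nnxnp` sire-informative). It provides:

* **Compendium construction** — `merge_compendium()` joins per-family
  linkage maps to SNP physical coordinates, excluding markers with
  conflicting linkage-group assignments and duplicate physical positions.
* **Consensus and confidence** — `consensus_lg()` (plurality linkage
  group per contig, ties flagged ambiguous), `classify_snps()` (the
  high-confidence decision tree: consensus + multi-family; consensus +
  single-family on a corroborated contig; replicated non-consensus).
* **Chimeric-block detection** — `detect_blocks()` finds maximal runs of
  contiguous non-consensus SNPs and classifies them as single exceptions,
  one-family blocks, or multi-family (chimeric) blocks; `block_stats()`
  summarises them.
* **Grouping-accuracy statistics** — `contingency_2x2()` (odds ratio
  `a·d/(b·c)` with uncorrected Pearson chi-square) and `loglinear_3way()`
  (hierarchical loglinear fits by iterative proportional fitting, G²
  likelihood-ratio tests).
* **Anchoring** — `assign_chromosomes()`, `order_and_orient()` (mean
  genetic position across equally-weighted maps, scaled per map;
  orientation from the sign of the bp–cM rank correlation),
  `build_pseudomolecules()` (100-bp gaps, reverse-complementing `−`
  contigs), AGP v2 in/out, and `compare_layouts()` (five concordance
  categories: identical / different order / reversed / orientation
  unknown / different chromosome).
* **Recombination rates** — `chromosome_rr()` (distal-SNP rate),
  `rr_anova()` (family × sex × chromosome partitioning with the
  family×chromosome error stratum for the family and chromosome tests),
  `marey_profile()` (monotonicity-outlier removal, local-linear tricube
  slope at span 0.3, negative-rate refit), `standardize_rr()` (±1.28
  hotspot/coldspot thresholds), `csr_quadrat_test()` (3×3 quadrat
  chi-square test of complete spatial randomness at α = 0.001), and
  `centromere_min_rr()`.
* **A meiosis simulator with truth** — `build_genome()`,
  `recomb_landscape()`, `simulate_family()`, `degrade_genotypes()`,
  `corrupt_assembly()`: Poisson (no-interference) crossovers placed by
  inverting the cumulative genetic map, per-parent rate multipliers,
  2–3% genotyping error, injected chimeric blocks and contig shuffles
  with complete truth records, so every pipeline stage is testable by
  recovery.

Fitted objects come with broom-style `tidy()`/`glance()` methods and
ggplot2 helpers (`autoplot()` for Marey profiles, `plot_standardized_rr()`,
`plot_rr_effects()`, `plot_concordance()`).

## A worked example

Simulate a small genome, corrupt its assembly with one chimeric block,
and recover the corruption from two families' maps:

```r
library(mapanchor)

g    <- build_genome(chrom_lengths = rep(5e6, 3), n_contigs = 9,
                     snp_density = 20, seed = 42)
land <- recomb_landscape(g)   # 60 cM per chromosome by default
maps <- unlist(lapply(1:2, function(i) {
  sim <- simulate_family(g, land,
                         family_design(paste0("fam", i), n_progeny = 50,
                                       seed = i))
  true_linkage_maps(sim)
}), recursive = FALSE)

plan <- corruption_plan(chimeric = tibble::tibble(
  host_contig = "ctg002", donor_contig = "ctg006", n_snps = 3))
corrupted <- corrupt_assembly(g, plan, seed = 3)

comp <- merge_compendium(maps, coordinate_table(corrupted$genome))
runs <- detect_blocks(comp)
glance(block_stats(runs))
#> # A tibble: 1 × 5
#>   n.chimeric.contigs n.blocks mean.snps.per.block median.length.bp total.length.bp
#>                <int>    <int>               <dbl>            <dbl>           <dbl>
#> 1                  1        1                   3               31              31
```

The three donor SNPs spliced into `ctg002` are found as exactly one
multi-family block of 3 SNPs spanning 31 bp — the injected block, with
exact bp bounds. `classify_snps()` labels them category 3 (replicated
non-consensus: evidence against the assembly, not the maps), and
`order_and_orient()` + `compare_layouts()` would flag flipped or moved
contigs the same way.

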