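---
title: "Validating genome assemblies with linkage maps and profiling recombination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating genome assemblies with linkage maps and profiling recombination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapanchor)
library(dplyr)
```

## The problem

A dense genetic linkage map is an independent witness to the structure of a
genome assembly. Markers that co-segregate in meiosis belong to one
chromosome; if a block of adjacent SNPs on an assembled contig maps to a
*different* linkage group than the rest of the contig, and does so in more
than one mapping family, the most parsimonious explanation is a
misassembly — a chimeric contig. Conversely, when contigs ordered purely by
genetic position agree with the assembly's order, the assembly is
corroborated at chromosome scale. The same maps, joined to physical
coordinates, measure recombination: the local slope of the Marey map
(genetic position against physical position) is the recombination rate in
cM/Mb, and chromosome-level rates can be partitioned across families,
sexes, and chromosomes.

`mapanchor` implements this whole workflow for multi-family F2 designs
with cross-pollinated marker coding (`hkxhk` bi-parental, `lmxll`
dam-informative, `nnxnp` sire-informative), together with a meiosis and
genotyping simulator so every stage can be validated by recovering known
truth.

## The compendium and the confidence decision tree

Per-family maps are merged with a SNP coordinate table into a compendium
(`merge_compendium()`): one record per physical SNP, carrying every
family's linkage-group assignment. Two filters apply at merge time, both
reported rather than silent: markers assigned to two or more different
linkage groups across maps are excluded as irreconcilable, and markers
translating to the same physical position are removed.

The consensus linkage group of a contig (`consensus_lg()`) is the group
holding the plurality of its SNPs. An exact tie makes the contig
*ambiguous*; we deliberately refuse to break ties (by input order or
otherwise) because misassignment statistics must not depend on row order.

SNPs are then classified (`classify_snps()`) by the decision tree:

1. assigned to the consensus group and mapped in more than one family;
2. assigned to the consensus group, mapped in one family, but on a contig
   that carries category-1 SNPs;
3. assigned to a non-consensus group in more than one family.

Categories 1–3 are high-confidence. Category 3 deserves emphasis: a
*replicated* disagreement is evidence about the assembly, not about the
map, so it is retained with high confidence — it is exactly the signal
`detect_blocks()` turns into chimeric-block calls. Runs of contiguous
same-group non-consensus SNPs of length one are single exceptions
(most plausibly mapping noise); longer runs supported by one family are
one-family blocks; longer runs supported by two or more families are
chimeric blocks. Block support is the union of families over member SNPs;
a stricter per-SNP rule is available (`support = "per_snp"`). Block length
in bp is `last − first + 1` over member SNP positions.

Grouping accuracy is analysed as a 2×2×2 table (accuracy × mapping
method × family support) by layer-wise odds ratios
(`contingency_2x2()`; Pearson chi-square without continuity correction)
and a hierarchical loglinear analysis (`loglinear_3way()`, iterative
proportional fitting via `stats::loglin`). We report likelihood-ratio G²
statistics for dropping each two-way interaction from the all-two-way
model, not Wald chi-squares, whose values depend on a particular
package's parameterization and coding.

## Anchoring contigs into pseudomolecules

Contigs with high-confidence SNPs are assigned to the chromosome of their
consensus linkage group (`assign_chromosomes()`); contigs without
high-confidence SNPs remain unplaced and are carried in an explicit
"unplaced" bin rather than dropped. Within a chromosome, contigs are
ordered by their weight-averaged mean genetic position across maps
(`order_and_orient()`, all maps weighted 1 by default). Each map's
contribution is min–max scaled to [0, 1] per chromosome before averaging,
which makes the order invariant to per-map affine rescaling of cM — maps
in different units or with different baseline rates vote equally.
Orientation is the sign of the mean Spearman correlation between contig
position and genetic position over maps with at least two distinct
genetic positions on the contig; contigs with no such map, or mean |ρ|
below 0.1, get orientation `?`. Positional evidence uses only
high-confidence SNPs assigned to the contig's consensus group: replicated
non-consensus SNPs flag misassembly but carry another chromosome's cM
scale and would corrupt the estimate.

`build_pseudomolecules()` concatenates contig sequences in layout order
with fixed 100-bp `N` gaps, reverse-complementing `−` contigs, and
`write_layout()` emits AGP v2. `compare_layouts()` classifies each shared
contig against a reference layout into five exhaustive categories:
identical, different order (with the rank offset), reversed orientation,
orientation unknown, different chromosome. Relative order is compared
over contigs shared by both layouts *and on the same chromosome in both*,
so a single relocated contig does not cascade into spurious order
differences for its neighbours.

## Recombination rates

`chromosome_rr()` divides the genetic span between the two most distal
SNPs (distal by genetic position; cM ties resolved to the physical
extremes) by their physical distance. `rr_anova()` fits family + sex +
chromosome with all two-way interactions to a balanced one-observation-
per-cell table; the three-way interaction is not estimable without
replication and is excluded. Because family×chromosome means are single
observations per sex, the family and chromosome main effects are tested
against the family×chromosome mean square, while sex and the interactions
use the residual. With 6 families, 2 sexes and 10 chromosomes this yields
the 74/45 model/residual degrees of freedom characteristic of the design.

`marey_profile()` estimates local rates in three steps. First,
monotonicity outliers are removed by keeping the longest nondecreasing
subsequence of cM ordered by bp — a deterministic rule that retains the
maximal consistent set (the originating program's exact rule is not
published; this choice is ours). Second, a degree-1 local regression with
tricube weights over the `ceiling(span × n)` nearest neighbours
(span 0.3 by default) is fit at every retained locus, and the local slope
— not the fitted value — is the quantity of interest, converted from
cM/bp to cM/Mb. This local-linear machinery is written in the package
because `stats::loess` does not expose the local slope; `loess` serves as
an independent cross-check on fitted values in the tests. Third, loci
with negative rates are removed and the profile refit once on the
remainder.

`standardize_rr()` centres and scales one family's retained rates
genome-wide (the per-family unit makes families comparable; a
per-chromosome alternative is a trivial variation the caller can apply by
grouping). Values beyond ±1.28 — the nominal 10th and 90th percentiles of
a standard normal — are coldspot and hotspot candidates.
`csr_quadrat_test()` then asks whether one chromosome's extreme points
are uniformly scattered over the rectangle tightly bounding them in the
(bp, z) plane: 3×3 equal-area quadrats, Pearson chi-square against n/9,
8 df, significance at 0.001 to account for the many family-by-chromosome
tests. Sets of fewer than nine points (expectation below 1 per quadrat)
or with a degenerate rectangle are left untested and say so.
`centromere_min_rr()` reports the minimum rate inside a candidate
centromere interval together with its genome-wide quantile.

## The simulator: what it emulates and what it does not

The generator is first-class, tested code, and its defaults are the study
conditions the rest of the package is validated under:

* `build_genome()`: 10 chromosomes × 56 Mb (560 Mb) tiled by 300 contigs;
  SNP density defaults to 12.5/Mb, the per-family marker yield of a
  genotyping-by-sequencing experiment at this genome size (the mapped
  compendium of a real study is denser; tests scale density to the
  question at hand).
* `recomb_landscape()`: piecewise-constant rates; the default gives every
  chromosome a 60 cM map, consistent with 1.1–1.2 chiasmata per bivalent.
  Hotspots/coldspots are multiplicative interval modifiers.
* `simulate_crossovers()`: crossover counts are Poisson in map length
  (no interference — consistent with Haldane map units); positions are
  uniform on the genetic map and carried to bp by inverting the
  cumulative map. An obligate-chiasma option (zero-truncated Poisson at
  the bivalent level, thinned 1/2 into the gamete) is off by default.
* `family_design()`: mating types drawn in equal thirds by default (their
  real proportions vary by cross and are not published); genotyping error
  2.5% (the middle of an observed 2–3% range) applied as a flip to a
  different legal genotype; missing rate 5%; dam multiplier 1.25 against
  sire 1.0, emulating the higher maternal map length (2.20 vs 1.74 cM/Mb
  scale).
* RNG: one root seed with derived child streams per family, parent,
  chromosome and gamete, so enlarging a family never perturbs existing
  progeny. Coordinates in emitted tables are 1-based inclusive; internal
  interval arithmetic is half-open.

`corrupt_assembly()` manufactures the assembly errors the pipeline must
find — spliced chimeric blocks (donor SNPs from another chromosome
claimed at tens-of-bp spacing inside a host contig), orientation flips,
and within-chromosome moves — and records every corruption in a truth
object.

What the simulator does *not* model: read-level data (depth, allele
balance), segregation distortion (widespread in real oyster families, but
its quantitative form is not published, so we decline to guess a
selection model), crossover interference, and sex-specific landscape
*shape* differences (only multiplicative level differences). Passing
truth-recovery tests therefore demonstrates correctness of the
algorithms under clean Mendelian segregation, not robustness to every
pathology of real data.

## Numerical choices and degenerate inputs

* Consensus ties → ambiguous, never broken arbitrarily; affected SNPs are
  "unclassifiable" and excluded from block statistics.
* `estimate_rf()` for intercross 3×3 counts maximizes the multinomial
  likelihood by bounded scalar search on [0, 0.5), admitting the r = 0
  boundary when no recombinant class is observed.
* Identical-marker collapsing treats two markers as identical only when
  they agree at every individual *and* share the missingness pattern —
  literal record identity, the conservative reading.
* Rank ties in map-order comparison get average ranks.
* Zero-variance profiles are rejected by `standardize_rr()`; empty
  centromere overlaps and sub-minimum quadrat sets are flagged, not
  silently dropped.
* Anchoring ties in mean position break by supporting-SNP count, then
  contig id, so output is deterministic.

## Problem sizes used in the tests

The test-suite fixtures use 3–10 chromosomes of 5–56 Mb, 40–80 progeny
per family, and SNP densities of 1–25/Mb, chosen so each statistical
check has the power it needs: e.g. recombination-fraction recovery uses
5,000 progeny on a 2-marker contrast, the ANOVA sex-multiplier recovery
uses 6 families × 80 progeny × 10 chromosomes, and the quadrat test's
type-I rate is calibrated on 10,000 uniform replicates.

## A worked example

```{r example}
g <- build_genome(chrom_lengths = rep(5e6, 3), n_contigs = 9,
                  snp_density = 20, seed = 42)
land <- recomb_landscape(g)
maps <- unlist(lapply(1:2, function(i) {
  sim <- simulate_family(g, land,
                         family_design(paste0("fam", i), n_progeny = 50,
                                       seed = i))
  true_linkage_maps(sim)
}), recursive = FALSE)

# corrupt the assembly with one chimeric block, then recover it
plan <- corruption_plan(chimeric = tibble::tibble(
  host_contig = "ctg002", donor_contig = "ctg006", n_snps = 3))
corrupted <- corrupt_assembly(g, plan, seed = 3)

comp <- merge_compendium(maps, coordinate_table(corrupted$genome))
runs <- detect_blocks(comp)
glance(block_stats(runs))
```

```{r marey}
sim <- simulate_family(g, land, family_design("famA", n_progeny = 60,
                                              seed = 5))
pts <- with(subset(sim$truth, chrom == "chr1"),
            tibble::tibble(bp = chrom_pos, cm = cm_dam))
prof <- marey_profile(pts)
autoplot(prof)
```

## Known limitations

* Marker grouping and ordering (the job of dedicated mapping software)
  are out of scope; maps enter the package already ordered, and the
  simulator's `estimated_linkage_maps()` assumes the true order.
* The anchoring objective is mean-position ordering with rank-correlation
  orientation — a documented simplification of full colinearity
  maximization, validated here by exact truth recovery on simulated
  shuffles rather than against any external tool's output.
* The loglinear G² statistics are likelihood-ratio tests; they are not
  comparable to Wald chi-squares from other software.
* Chimeric contigs are reported, not broken: editing the assembly is a
  decision for the assembler, not the validator.
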