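coords_for <- function(markers, contig = "ctgA", chrom = "chr1") {
  tibble::tibble(marker = markers, contig = contig,
                 contig_pos = seq(10L, by = 100L,
                                  length.out = length(markers)),
                 chrom = chrom,
                 chrom_pos = seq(10L, by = 100L,
                                 length.out = length(markers)))
}

one_map <- function(markers, lg = "LG1", family = "famA",
                    method = "default") {
  m <- tibble::tibble(marker = markers, lg = lg,
                      pos_cm = seq_along(markers) - 1)
  attr(m, "family") <- family
  attr(m, "method") <- method
  m
}

test_that("a single map yields one single-family record per marker", {
  mk <- paste0("m", 1:5)
  comp <- merge_compendium(list(a = one_map(mk)), coords_for(mk))
  expect_equal(nrow(comp$records), 5)
  expect_true(all(comp$records$n_families == 1))
  expect_equal(nrow(comp$conflicts), 0)
})

test_that("conflicting and duplicate-position markers are excluded", {
  mk <- paste0("m", 1:4)
  mA <- one_map(mk, "LG1", family = "famA")
  mB <- one_map(mk, "LG1", family = "famB")
  mB$lg[2] <- "LG7"  # m2 conflicts between families
  co <- coords_for(mk)
  co$contig_pos[4] <- co$contig_pos[3]  # m3/m4 share a physical position
  co$chrom_pos[4] <- co$chrom_pos[3]
  comp <- merge_compendium(list(A = mA, B = mB), co)
  expect_equal(comp$conflicts$marker, "m2")
  expect_equal(comp$duplicates, c("m3", "m4"))
  expect_equal(comp$records$marker, "m1")
  expect_equal(comp$records$n_families, 2)
})

test_that("markers without coordinates are listed and skipped", {
  mk <- paste0("m", 1:3)
  comp <- merge_compendium(list(a = one_map(mk)), coords_for(mk[1:2]))
  expect_equal(comp$missing_coords, "m3")
  expect_equal(nrow(comp$records), 2)
})

test_that("consensus is the plurality group and exact ties are ambiguous", {
  mk <- paste0("m", 1:26)
  co <- coords_for(mk)
  m <- one_map(mk)
  m$lg <- c(rep("LG2", 14), rep("LG10", 12))
  comp <- merge_compendium(list(a = m), co)
  cons <- consensus_lg(comp)
  expect_equal(cons$consensus_lg, "LG2")
  expect_equal(cons$n_consensus, 14)
  expect_false(cons$ambiguous)
  m$lg <- c(rep("LG2", 13), rep("LG10", 13))
  cons_tie <- consensus_lg(merge_compendium(list(a = m), co))
  expect_true(cons_tie$ambiguous)
  expect_true(is.na(cons_tie$consensus_lg))
})

test_that("the decision tree labels each confidence category correctly", {
  mk <- paste0("m", 1:6)
  co <- coords_for(mk)
  # m1-m4 consensus LG1; m5, m6 non-consensus LG9
  mkA <- mk[c(1, 2, 3, 5, 6)]
  mA <- one_map(mkA, c("LG1", "LG1", "LG1", "LG9", "LG9"), family = "famA")
  mB <- one_map(mk[c(1, 4, 5, 6)], c("LG1", "LG1", "LG9", "LG9"),
                family = "famB")
  comp <- merge_compendium(list(A = mA, B = mB), co)
  cl <- classify_snps(comp)
  got <- stats::setNames(cl$category, cl$marker)
  expect_equal(got[["m1"]], "1")      # consensus, two families
  expect_equal(got[["m2"]], "2")      # consensus, one family, corroborated
  expect_equal(got[["m5"]], "3")      # non-consensus, two families
  expect_equal(got[["m6"]], "3")
  expect_true(all(cl$high_confidence[cl$marker %in% c("m1", "m2", "m5")]))
})

test_that("category 2 needs a corroborated contig and tied contigs are unclassifiable", {
  mk <- paste0("m", 1:4)
  co <- coords_for(mk)
  # only famA maps the contig: no category-1 SNP to corroborate
  cl_single <- classify_snps(merge_compendium(list(A = one_map(mk)), co))
  expect_true(all(cl_single$category == "low"))
  # 2 vs 2 tie -> unclassifiable
  m <- one_map(mk, c("LG1", "LG1", "LG2", "LG2"))
  cl_tie <- classify_snps(merge_compendium(list(A = m), co))
  expect_true(all(cl_tie$category == "unclassifiable"))
})

test_that("runs are segmented exactly as a brute-force scan", {
  # pattern C C X C X X C on one contig (X = one non-consensus group)
  lg <- c("LG1", "LG1", "LG9", "LG1", "LG9", "LG9", "LG1")
  mk <- paste0("m", seq_along(lg))
  comp <- merge_compendium(list(A = one_map(mk, lg)), coords_for(mk))
  runs <- detect_blocks(comp)
  expect_equal(nrow(runs), 2)
  expect_equal(sort(runs$class),
               c("one_family_block", "single_exception"))
  blk <- runs[runs$class == "one_family_block", ]
  expect_equal(blk$n_snps, 2)
  expect_equal(blk$start, 410)
  expect_equal(blk$end, 510)
  expect_equal(blk$length_bp, 101)
})

test_that("run detection equals the brute-force oracle on random contigs", {
  set.seed(99)
  for (trial in 1:1000) {
    n <- sample(3:12, 1)
    lg <- sample(c("LG1", "LG1", "LG1", "LG2", "LG3"), n, replace = TRUE)
    # force LG1 to be the strict plurality, else skip (ambiguous excluded)
    if (sum(lg == "LG1") <= max(table(lg[lg != "LG1"]), 0)) next
    mk <- paste0("t", trial, "_m", 1:n)
    comp <- merge_compendium(list(A = one_map(mk, lg)), coords_for(mk))
    runs <- detect_blocks(comp)
    pos <- seq(10L, by = 100L, length.out = n)
    oracle <- brute_force_runs(lg, pos, "LG1")
    expect_equal(nrow(runs), length(oracle))
    if (length(oracle)) {
      o <- dplyr::bind_rows(lapply(oracle, tibble::as_tibble))
      runs <- dplyr::arrange(runs, start)
      o <- dplyr::arrange(o, start)
      expect_equal(runs$start, o$start)
      expect_equal(runs$end, o$end)
      expect_equal(runs$n_snps, o$n)
      expect_equal(runs$lg, o$lg)
    }
  }
})

test_that("multi-family support separates chimeric from one-family blocks", {
  mk <- paste0("m", 1:6)
  co <- coords_for(mk)
  lgs <- c("LG1", "LG1", "LG1", "LG1", "LG9", "LG9")
  mA <- one_map(mk, lgs, family = "famA")
  mB <- one_map(mk[1:5], lgs[1:5], family = "famB")
  comp <- merge_compendium(list(A = mA, B = mB), co)
  runs_union <- detect_blocks(comp)
  expect_equal(runs_union$class, "multi_family_block")
  # per-SNP strictness: m6 is single-family, so the block is not
  runs_strict <- detect_blocks(comp, support = "per_snp")
  expect_equal(runs_strict$class, "one_family_block")
})

test_that("block statistics summarise multi-family blocks only", {
  runs <- tibble::tibble(
    contig = c("c1", "c1", "c2", "c3"),
    lg = "LG9", start = 1L, end = c(10L, 50L, 60L, 5L),
    length_bp = c(10L, 50L, 60L, 5L), n_snps = c(3L, 5L, 2L, 1L),
    snps = list("a", "b", "c", "d"), families = list("f", "f", "f", "f"),
    n_families = 2L,
    class = c("multi_family_block", "multi_family_block",
              "one_family_block", "single_exception"))
  bs <- block_stats(runs)
  expect_equal(bs$n_chimeric_contigs, 1)
  expect_equal(bs$n_blocks, 2)
  expect_equal(bs$mean_snps_per_block, 4)
  expect_equal(bs$median_length_bp, 30)
  expect_equal(bs$total_length_bp, 60)
  empty <- block_stats(runs[0, ])
  expect_equal(empty$n_blocks, 0)
  expect_true(is.na(empty$mean_snps_per_block))
})

test_that("injected chimeric blocks are recovered with exact bounds", {
  g <- small_genome(snp_density = 25, seed = 50)
  ok <- contigs_with_snps(g, 10)
  hosts <- c(ok$contig[ok$chrom == "chr1"][1], ok$contig[ok$chrom == "chr2"][1])
  donors <- c(ok$contig[ok$chrom == "chr3"][1], ok$contig[ok$chrom == "chr3"][2])
  plan <- corruption_plan(chimeric = tibble::tibble(
    host_contig = hosts, donor_contig = donors, n_snps = 3))
  cor <- corrupt_assembly(g, plan, seed = 4)
  ls <- recomb_landscape(g)
  maps <- family_true_maps(g, ls, n_families = 2, n_progeny = 40)
  comp <- merge_compendium(maps, coordinate_table(cor$genome))
  runs <- detect_blocks(comp)
  multi <- runs[runs$class == "multi_family_block", ]
  truth <- dplyr::arrange(cor$truth$chimeric_blocks, host_contig)
  multi <- dplyr::arrange(multi, contig)
  expect_equal(multi$contig, truth$host_contig)
  expect_equal(multi$start, truth$start)
  expect_equal(multi$end, truth$end)
  expect_equal(multi$n_snps, lengths(truth$snp))
})

test_that("2x2 analyses reproduce the published odds ratios", {
  expect_equal(round(contingency_2x2(256, 16919, 5, 846)$odds_ratio, 3),
               2.560)
  expect_equal(round(contingency_2x2(44, 1607, 5, 846)$odds_ratio, 3),
               4.633)
  expect_equal(round(contingency_2x2(846, 16919, 1607, 45795)$odds_ratio, 3),
               1.425)
  expect_equal(round(contingency_2x2(2163, 45795, 44, 1607)$odds_ratio, 3),
               1.725)
  expect_equal(round(contingency_2x2(2163, 256, 45795, 16919)$odds_ratio, 3),
               3.122)
  expect_equal(round(contingency_2x2(5, 256, 44, 2163)$odds_ratio, 3),
               0.960)
  # tiny tables trip the usual small-expected-count caution
  even <- suppressWarnings(contingency_2x2(1, 1, 1, 1))
  expect_equal(even$odds_ratio, 1)
  expect_equal(even$statistic, 0)
  expect_error(contingency_2x2(0, 0, 3, 4), "zero marginal")
  expect_true(suppressWarnings(contingency_2x2(0, 5, 3, 4))$degenerate)
})

test_that("2x2 chi-square matches the uncorrected Pearson statistic", {
  res <- contingency_2x2(30, 70, 55, 45)
  m <- matrix(c(30, 70, 55, 45), 2, 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(res$statistic, sum((m - e)^2 / e), tolerance = 1e-12)
  expect_equal(res$df, 1)
})

test_that("loglinear interactions vanish on an independence table", {
  p <- c(0.3, 0.7)
  q <- c(0.4, 0.6)
  s <- c(0.25, 0.75)
  counts <- 10000 * outer(outer(p, q), s)
  dim(counts) <- c(2, 2, 2)
  fit <- loglinear_3way(counts)
  two_way <- fit$terms[1:3, ]
  expect_true(all(two_way$g_squared < 1e-8))
})

test_that("loglinear G2 matches a Poisson-regression oracle", {
  counts <- array(c(2163, 44, 45795, 1607, 256, 5, 16919, 846), c(2, 2, 2),
                  dimnames = list(accuracy = c("non", "con"),
                                  method = c("LM3", "JM"),
                                  support = c("one", "multi")))
  fit <- loglinear_3way(counts)
  df <- as.data.frame.table(counts, responseName = "n")
  full <- stats::glm(n ~ (accuracy + method + support)^2, poisson, df)
  for (drop in c("accuracy:method", "accuracy:support", "method:support")) {
    reduced <- stats::update(full, stats::as.formula(paste("~ . -", drop)))
    g2_oracle <- reduced$deviance - full$deviance
    term <- fit$terms$g_squared[fit$terms$term ==
                                  sub(":", " x ", drop, fixed = TRUE)]
    expect_equal(term, g2_oracle, tolerance = 1e-4)
  }
  # three-way term: deviance of the all-two-way model
  expect_equal(fit$terms$g_squared[4], full$deviance, tolerance = 1e-4)
})

test_that("IPF fitted margins reproduce observed margins of retained terms", {
  counts <- array(c(2163, 44, 45795, 1607, 256, 5, 16919, 846), c(2, 2, 2))
  fit <- loglinear_3way(counts)
  for (mar in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_equal(apply(fit$fit_all_two_way, mar, sum),
                 apply(fit$observed, mar, sum), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("the grouping table cross-classifies accuracy, method, support", {
  mk <- paste0("m", 1:6)
  co <- coords_for(mk)
  mA <- one_map(mk, c(rep("LG1", 5), "LG9"), family = "famA", method = "JM")
  mB <- one_map(mk[1:3], rep("LG1", 3), family = "famB", method = "JM")
  cl <- classify_snps(merge_compendium(list(A = mA, B = mB), co))
  gt <- grouping_table(cl)
  expect_equal(sum(gt$n), 6)
  expect_equal(gt$n[gt$accuracy == "conLG" & gt$support == ">1 family"], 3)
  expect_equal(gt$n[gt$accuracy == "non-conLG"], 1)
})
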