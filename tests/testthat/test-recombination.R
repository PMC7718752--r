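test_that("chromosome-level rate divides distal genetic by physical span", {
  map <- tibble::tibble(marker = c("a", "b"), pos_cm = c(0, 30))
  co <- tibble::tibble(marker = c("a", "b"), chrom_pos = c(1, 15e6 + 1))
  expect_equal(chromosome_rr(map, co)$rr, 2, tolerance = 1e-6)
  flat <- tibble::tibble(marker = c("a", "b"), pos_cm = c(5, 5))
  expect_equal(chromosome_rr(flat, co)$rr, 0)
  same_bp <- tibble::tibble(marker = c("a", "b"), chrom_pos = c(10, 10))
  expect_error(chromosome_rr(map, same_bp), "zero physical span")
  expect_error(chromosome_rr(map[1, ], co), ">= 2 mapped SNPs")
})

test_that("distal SNPs are chosen by genetic, not physical, position", {
  map <- tibble::tibble(marker = c("a", "b", "c"), pos_cm = c(10, 0, 40))
  co <- tibble::tibble(marker = c("a", "b", "c"),
                       chrom_pos = c(1e6, 3e6, 11e6))
  # span runs from b (0 cM @ 3 Mb) to c (40 cM @ 11 Mb): 40 cM / 8 Mb
  expect_equal(chromosome_rr(map, co)$rr, 5)
})

test_that("a dense noise-free map recovers the landscape rate", {
  g <- build_genome(chrom_lengths = 56e6, n_contigs = 3, snp_density = 5,
                    seed = 31)
  ls <- recomb_landscape(g)  # 60 cM over 56 Mb = 1.0714 cM/Mb
  cm <- genetic_position(ls, "chr1", g$snps$chrom_pos)
  map <- tibble::tibble(marker = g$snps$snp, pos_cm = cm)
  co <- dplyr::rename(g$snps, marker = snp)
  rr <- chromosome_rr(map, co)$rr
  expect_lt(abs(rr - 60 / 56) / (60 / 56), 0.05)
})

test_that("the rate ANOVA uses the printed error strata and df", {
  set.seed(5)
  tab <- tidyr::expand_grid(family = paste0("f", 1:6),
                            sex = c("sire", "dam"),
                            chrom = paste0("chr", 1:10))
  tab$rr <- 2 + (tab$sex == "dam") * 0.5 + stats::rnorm(120, 0, 0.2)
  fit <- rr_anova(tab)
  expect_equal(fit$model_df, c(74, 45))
  t <- fit$table
  expect_equal(t$error_term[t$term == "family"], "family:chrom")
  expect_equal(t$error_term[t$term == "chrom"], "family:chrom")
  expect_equal(t$error_term[t$term == "sex"], "Residuals")
  expect_equal(t$df[t$term == "family"], 5)
  expect_equal(t$df[t$term == "family:chrom"], 45)
  # F for family must equal MS_family / MS_family:chrom
  expect_equal(t$f[t$term == "family"],
               t$ms[t$term == "family"] / t$ms[t$term == "family:chrom"])
  expect_error(rr_anova(tab[-1, ]), "not balanced")
})

test_that("a constant table has zero effect sums of squares", {
  tab <- tidyr::expand_grid(family = paste0("f", 1:3),
                            sex = c("sire", "dam"),
                            chrom = paste0("chr", 1:4))
  tab$rr <- 1.5
  # a perfectly constant response makes the underlying F machinery warn
  fit <- suppressWarnings(rr_anova(tab))
  expect_true(all(fit$table$ss < 1e-20))
  expect_equal(fit$grand_mean, 1.5)
})

test_that("sums of squares match a cell-mean decomposition oracle", {
  set.seed(8)
  for (rep in 1:5) {
    tab <- tidyr::expand_grid(family = paste0("f", 1:4),
                              sex = c("sire", "dam"),
                              chrom = paste0("chr", 1:5))
    tab$rr <- stats::rnorm(nrow(tab), 2, 0.5)
    fit <- rr_anova(tab)
    t <- fit$table
    # brute-force balanced decomposition from cell means
    gm <- mean(tab$rr)
    eff <- function(fac) {
      mns <- tapply(tab$rr, tab[[fac]], mean)
      sum((mns - gm)^2) * nrow(tab) / length(mns)
    }
    expect_equal(t$ss[t$term == "family"], eff("family"), tolerance = 1e-8)
    expect_equal(t$ss[t$term == "sex"], eff("sex"), tolerance = 1e-8)
    expect_equal(t$ss[t$term == "chrom"], eff("chrom"), tolerance = 1e-8)
    ab <- tapply(tab$rr, list(tab$family, tab$chrom), mean)
    a <- tapply(tab$rr, tab$family, mean)
    b <- tapply(tab$rr, tab$chrom, mean)
    ss_ab <- sum((ab - outer(a - gm, b - gm, "+") - gm)^2) * 2
    expect_equal(t$ss[t$term == "family:chrom"], ss_ab, tolerance = 1e-8)
  }
})

test_that("tidy and glance expose the ANOVA in broom shape", {
  tab <- tidyr::expand_grid(family = paste0("f", 1:3),
                            sex = c("sire", "dam"),
                            chrom = paste0("chr", 1:4))
  set.seed(2)
  tab$rr <- stats::rnorm(24, 2)
  fit <- rr_anova(tab)
  td <- tidy(fit)
  expect_true(all(c("term", "statistic", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$grand.mean, mean(tab$rr))
  expect_true(gl$r.squared >= 0 && gl$r.squared <= 1)
})

test_that("a linear Marey map yields a constant profile at the true rate", {
  pts <- tibble::tibble(bp = seq(1e5, 2e7, by = 1e5))
  pts$cm <- 2e-6 * pts$bp
  prof <- marey_profile(pts)
  expect_equal(prof$rr, rep(2, nrow(prof)), tolerance = 1e-6)
  expect_length(attr(prof, "removed_outliers"), 0)
})

test_that("non-monotone loci are removed as outliers before fitting", {
  pts <- tibble::tibble(bp = seq(1e6, 20e6, by = 1e6))
  pts$cm <- pts$bp * 1.5e-6
  pts$cm[8] <- pts$cm[3]  # a locus whose cM fell back
  prof <- marey_profile(pts)
  expect_equal(attr(prof, "removed_outliers"), pts$bp[8])
  expect_equal(nrow(prof), 19)
})

test_that("the local slope matches a finite-difference oracle on a line", {
  set.seed(1)
  pts <- tibble::tibble(bp = sort(stats::runif(120, 0, 3e7)))
  pts$cm <- 1.2e-6 * pts$bp + 3
  prof <- marey_profile(pts)
  fd <- diff(pts$cm) / diff(pts$bp) * 1e6
  expect_lt(max(abs(prof$rr - mean(fd))) / mean(fd), 0.1)
})

test_that("a piecewise landscape is recovered away from the breakpoint", {
  g <- build_genome(chrom_lengths = 3e7, n_contigs = 1, snp_density = 10,
                    seed = 12)
  ls <- recomb_landscape(
    g, base_rate = 1,
    modifiers = tibble::tibble(chrom = "chr1", start = 15e6 + 1, end = 3e7,
                               factor = 3))
  pts <- tibble::tibble(bp = g$snps$chrom_pos,
                        cm = genetic_position(ls, "chr1",
                                              g$snps$chrom_pos))
  prof <- marey_profile(pts)
  away_low <- prof$bp < 10e6
  away_high <- prof$bp > 20e6 & prof$bp < 28e6
  expect_true(all(abs(prof$rr[away_low] - 1) / 1 < 0.15))
  expect_true(all(abs(prof$rr[away_high] - 3) / 3 < 0.15))
})

test_that("standardization centres, scales, and flags the extreme tails", {
  set.seed(4)
  prof <- tibble::tibble(chrom = "chr1", bp = seq_len(10000),
                         rr = stats::rnorm(10000, 2, 0.5))
  z <- standardize_rr(prof)
  expect_equal(mean(z$z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$z), 1, tolerance = 1e-12)
  frac_hot <- mean(z$z > 1.28)
  frac_cold <- mean(z$z < -1.28)
  expect_lt(abs(frac_hot - 0.1), 0.015)
  expect_lt(abs(frac_cold - 0.1), 0.015)
  expect_equal(unique(z$extreme[z$z > 1.28]), "hot")
  expect_error(standardize_rr(dplyr::mutate(prof, rr = 1)),
               "zero variance")
})

test_that("quadrat counts drive the spatial-randomness chi-square", {
  # nine points, one per quadrat -> statistic 0
  grid <- tidyr::expand_grid(i = 1:3, j = 1:3)
  pts <- tibble::tibble(bp = c(0, 5e6, 1e7)[grid$i] ,
                        z = c(1.5, 2, 2.5)[grid$j])
  res <- csr_quadrat_test(pts)
  expect_true(res$tested)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # nine points clustered into one quadrat of a supplied rectangle:
  # (9-1)^2/1 + 8*1 = 72
  pts2 <- tibble::tibble(bp = stats::runif(9, 0, 3e6),
                         z = stats::runif(9, 1.3, 1.5))
  res2 <- csr_quadrat_test(pts2, bounds = list(bp = c(0, 9e6),
                                               z = c(1.3, 1.9)))
  expect_equal(res2$statistic, 72)
  expect_true(res2$significant)
})

test_that("small or degenerate extreme sets are left untested", {
  few <- tibble::tibble(bp = seq_len(8) * 1e6, z = seq_len(8) / 2 + 1.3)
  expect_false(csr_quadrat_test(few)$tested)
  flat <- tibble::tibble(bp = rep(1e6, 9), z = seq(1.3, 2.1, 0.1))
  res <- csr_quadrat_test(flat)
  expect_false(res$tested)
  expect_match(res$reason, "degenerate")
})

test_that("injected hotspots are detected as clustered extremes", {
  hits <- 0
  n_rep <- 10
  for (k in seq_len(n_rep)) {
    g <- build_genome(chrom_lengths = 5e7, n_contigs = 2,
                      snp_density = 10, seed = 300 + k)
    ls <- recomb_landscape(
      g, base_rate = 1,
      modifiers = tibble::tibble(chrom = "chr1", start = 20e6 + 1,
                                 end = 24e6, factor = 5))
    pts <- tibble::tibble(chrom = "chr1", bp = g$snps$chrom_pos,
                          cm = genetic_position(ls, "chr1",
                                                g$snps$chrom_pos))
    prof <- marey_profile(pts[, c("bp", "cm")])
    z <- standardize_rr(dplyr::mutate(prof, chrom = "chr1"))
    hot <- z[!is.na(z$extreme) & z$extreme == "hot", ]
    # detection: the hot cluster centres on the injected interval (the
    # local-regression window smears its edges) and CSR is rejected
    centred <- stats::median(hot$bp) > 19e6 & stats::median(hot$bp) < 25e6
    res <- csr_quadrat_test(hot[, c("bp", "z")])
    if (centred && isTRUE(res$significant)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("the centromere check finds the interval minimum and quantile", {
  prof <- tibble::tibble(bp = seq(1e6, 20e6, by = 1e6),
                         rr = c(2, 2, 2, 1.5, 0.2, 0.4, 2, 2, 2, 2,
                                2, 2, 2, 2, 2, 2, 2, 2, 2, 2))
  res <- centromere_min_rr(prof, c(4e6, 7e6))
  expect_equal(res$min_rr, 0.2)
  expect_equal(res$min_bp, 5e6)
  expect_equal(res$quantile, 1 / 20)
  whole <- centromere_min_rr(prof, c(0, 3e7))
  expect_equal(whole$min_rr, min(prof$rr))
  empty <- centromere_min_rr(prof, c(25e6, 26e6))
  expect_true(empty$flagged)
})

test_that("simulated sex effects are recovered by the ANOVA", {
  # 6 families x 2 parents x 10 chromosomes; dam rate 1.25x sire;
  # chromosome-level rates estimated end-to-end from simulated meioses
  g <- build_genome(chrom_lengths = rep(25e6, 10), n_contigs = 20,
                    snp_density = 1.2, seed = 77)
  ls <- recomb_landscape(g, base_rate = 1.6)  # 40 cM per chromosome
  co <- coordinate_table(g)
  rows <- list()
  for (i in 1:6) {
    d <- family_design(paste0("f", i), n_progeny = 80, seed = 900 + i)
    sim <- simulate_family(g, ls, d)
    est <- estimated_linkage_maps(sim)
    for (p in c("sire", "dam")) {
      m <- est[[p]]
      for (lg in unique(m$lg)) {
        sub <- m[m$lg == lg, ]
        ch <- g$snps$chrom[match(sub$marker, g$snps$snp)][1]
        rr <- chromosome_rr(sub, co)
        rows[[length(rows) + 1]] <- tibble::tibble(
          family = paste0("f", i), sex = p, chrom = ch, rr = rr$rr)
      }
    }
  }
  tab <- dplyr::bind_rows(rows)
  fit <- rr_anova(tab)
  t <- fit$table
  expect_lt(t$p_value[t$term == "sex"], 0.001)
  diff_obs <- mean(tab$rr[tab$sex == "dam"]) -
    mean(tab$rr[tab$sex == "sire"])
  # truth: (1.25 - 1) * 1.6 cM/Mb, up to edge effects of distal SNPs
  se <- stats::sd(tab$rr) / sqrt(60)
  expect_lt(abs(diff_obs - 0.25 * 1.6), 3 * se * sqrt(2))
  expect_lt(abs(fit$grand_mean - 1.6 * 1.125) / (1.6 * 1.125), 0.05)
})
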