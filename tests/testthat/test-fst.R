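test_that("wc_fst behaves at the no-differentiation and fixation limits", {
  # equal frequencies, no hets: between-group variance term is 0 and the
  # estimator is slightly negative (finite-sample noise around 0)
  th_eq <- wc_fst(n = c(50, 50), p = c(0.3, 0.3), h = c(0, 0))
  expect_lte(th_eq, 0)
  # reciprocal fixation with large equal samples: theta -> 1
  th_fix <- wc_fst(n = c(1000, 1000), p = c(1, 0), h = c(0, 0))
  expect_equal(th_fix, 1, tolerance = 1e-3)
  # fewer than two usable groups -> undefined
  expect_true(is.na(wc_fst(n = c(10, 0), p = c(0.5, NA), h = c(0, 0))))
})

test_that("wc_fst matches the independent transcription on a worked case", {
  th <- wc_fst(n = c(10, 10), p = c(0.9, 0.1), h = c(0, 0))
  expect_equal(th, oracle_wc_theta(c(10, 10), c(0.9, 0.1), c(0, 0)),
               tolerance = 1e-12)
  # permutation sanity check: shuffling group labels of a structured panel
  # collapses theta toward 0
  sim <- simulate_panel(sim_config(seed = 4, n_per_group = 50,
                                   n_linkage_groups = 2,
                                   markers_per_lg = 150,
                                   outlier_loci = NULL))
  G <- filter_snps(sim$genotypes)
  perm <- sim$groups
  set.seed(1)
  perm$group <- sample(perm$group)
  cnt <- group_allele_counts(G, perm)
  theta_perm <- wc_fst(cnt$n, cnt$p, cnt$h)
  expect_lt(abs(mean(theta_perm, na.rm = TRUE)), 0.02)
})

test_that("nei_gst and jost_d follow their closed forms", {
  expect_equal(nei_gst(n = c(100, 100), p = c(1, 0)), 1)
  expect_equal(nei_gst(n = c(100, 100), p = c(0.4, 0.4)), 0)
  expect_equal(nei_gst(n = c(100, 100), p = c(0.9, 0.1)), 0.64,
               tolerance = 1e-12)
  expect_equal(jost_d(n = c(100, 100), p = c(1, 0)), 1)
  expect_equal(jost_d(n = c(100, 100), p = c(0.4, 0.4)), 0)
  expect_equal(jost_d(n = c(100, 100), p = c(0.9, 0.1)),
               (0.5 - 0.18) / (1 - 0.18) * 2, tolerance = 1e-12)
})

test_that("scan values equal marker-by-marker estimator calls", {
  sim <- simulate_panel(sim_config(seed = 6, n_per_group = 40,
                                   n_linkage_groups = 2,
                                   markers_per_lg = 60,
                                   outlier_loci = NULL))
  G <- filter_snps(sim$genotypes)
  scan <- fst_scan(G, sim$groups, sim$map,
                   groups_used = c("winter", "spring"))
  cnt <- group_allele_counts(G, sim$groups, c("winter", "spring"))
  for (m in sample(scan$marker, 10)) {
    j <- match(m, colnames(G))
    expect_equal(scan$fst[scan$marker == m],
                 wc_fst(cnt$n[j, ], cnt$p[j, ], cnt$h[j, ]))
    expect_equal(scan$jost_d[scan$marker == m],
                 jost_d(cnt$n[j, ], cnt$p[j, ]))
  }
  expect_false(is.unsorted(scan$cum_pos))  # Manhattan ordering
})

test_that("fst and jost_d are strongly rank-correlated on biallelic scans", {
  sim <- simulate_panel(sim_config(seed = 10))
  G <- filter_snps(sim$genotypes)
  scan <- fst_scan(G, sim$groups, sim$map,
                   groups_used = c("winter", "spring"))
  ok <- !is.na(scan$fst) & !is.na(scan$jost_d)
  rho <- cor(scan$fst[ok], scan$jost_d[ok], method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("multilocus F_ST reduces to the single-marker estimator", {
  G <- toy_geno(c(rep(0L, 10), rep(2L, 10)), n_acc = 20)
  groups <- data.frame(accession = rownames(G),
                       group = rep(c("A", "B"), each = 10))
  mf <- mean_multilocus_fst(G, groups)
  cnt <- group_allele_counts(G, groups)
  expect_equal(mf$multilocus, wc_fst(cnt$n, cnt$p, cnt$h))
  expect_equal(mf$n_markers, 1L)
})

test_that("identical groups give near-zero multilocus F_ST", {
  G <- random_geno(30, 200, missing_rate = 0, seed = 20)
  G2 <- rbind(G, G)
  rownames(G2) <- c(paste0("x", rownames(G)), paste0("y", rownames(G)))
  groups <- data.frame(accession = rownames(G2),
                       group = rep(c("A", "B"), each = nrow(G)))
  mf <- mean_multilocus_fst(G2, groups)
  expect_lt(abs(mf$multilocus), 0.02)
})

test_that("anova_fst_by_lg reproduces the hand-computed table", {
  scan <- data.frame(fst = c(0.1, 0.2, 0.5, 0.6),
                     linkage_group = c(1, 1, 2, 2))
  av <- anova_fst_by_lg(scan)
  expect_equal(av$F, 32, tolerance = 1e-10)
  expect_equal(av$df, c(1, 2))
  expect_equal(av$p_value, stats::pf(32, 1, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(anova_fst_by_lg(data.frame(fst = 1:2, linkage_group = 1)),
               ">= 2 linkage groups")
})

test_that("a linkage group with elevated F_ST is detected by the ANOVA", {
  elevated <- data.frame(lg = 2L, cM = seq(5, 95, length.out = 25),
                         fst = 0.8, group_a = "winter", group_b = "spring")
  sim <- simulate_panel(sim_config(seed = 22, n_linkage_groups = 3,
                                   markers_per_lg = 120, lg_length_cM = 100,
                                   outlier_loci = elevated))
  G <- filter_snps(sim$genotypes)
  scan <- fst_scan(G, sim$groups, sim$map,
                   groups_used = c("winter", "spring"))
  av <- anova_fst_by_lg(scan)
  expect_lt(av$p_value, 0.05)
  lg_means <- tapply(scan$fst, scan$linkage_group, mean, na.rm = TRUE)
  expect_equal(unname(which.max(lg_means)), 2L)
})

test_that("empirical_outliers flags by quantile and labels the method", {
  scan <- data.frame(marker = sprintf("m%d", 1:100), fst = seq(0, 0.99, 0.01),
                     linkage_group = 1)
  all_f <- empirical_outliers(scan, top_quantile = 0)
  expect_equal(nrow(all_f), 100)
  top <- empirical_outliers(scan, top_quantile = 0.95)
  expect_equal(nrow(top), 5)          # quantile-sized flag set
  expect_equal(top$marker[1], "m100") # rank 1 = highest F_ST
  expect_match(attr(top, "method"), "empirical")
})

test_that("permuted group labels center the scan near zero", {
  sim <- simulate_panel(sim_config(seed = 24, n_per_group = 50))
  G <- filter_snps(sim$genotypes)
  perm <- sim$groups
  set.seed(2)
  perm$group <- sample(perm$group)
  scan <- fst_scan(G, perm, sim$map, groups_used = c("winter", "spring"))
  expect_lt(abs(mean(scan$fst, na.rm = TRUE)), 0.02)
})
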