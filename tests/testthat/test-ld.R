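test_that("pairwise_r2 handles perfect, flipped and orthogonal pairs", {
  g <- c(0L, 0L, 2L, 2L)
  expect_equal(pairwise_r2(g, g), 1)
  expect_equal(pairwise_r2(g, 2L - g), 1)          # sign-invariance
  expect_equal(pairwise_r2(g, c(0L, 2L, 0L, 2L)), 0)
  expect_true(is.na(pairwise_r2(g, rep(2L, 4))))   # zero variance flagged
  expect_true(is.na(pairwise_r2(c(0L, NA, NA, NA), c(0L, NA, NA, NA))))
})

test_that("intra_lg_ld enumerates within-LG pairs only", {
  G <- random_geno(30, 10, missing_rate = 0, seed = 2)
  map1 <- data.frame(marker = colnames(G)[1:4], linkage_group = 1,
                     cM = c(0, 1, 2, 3))
  pairs <- intra_lg_ld(G[, 1:4], map1)
  expect_equal(nrow(pairs), 6)
  map2 <- data.frame(marker = colnames(G)[1:6],
                     linkage_group = rep(1:2, each = 3),
                     cM = rep(c(0, 5, 10), 2))
  pairs2 <- intra_lg_ld(G[, 1:6], map2)
  expect_equal(nrow(pairs2), 6)    # 3 per LG, no inter-LG pairs
  expect_equal(pairs2$dist_cM, rep(c(5, 10, 5), 2))
  expect_warning(intra_lg_ld(G, map2), "absent from map")
})

test_that("ld_decay_profile keeps quantiles ordered and handles degeneracy", {
  pairs <- data.frame(marker_a = "a", marker_b = "b", linkage_group = 1,
                      dist_cM = runif(100, 0, 0.4), r2 = 0.3)
  prof <- ld_decay_profile(pairs)
  expect_equal(nrow(prof), 1)
  expect_equal(unname(unlist(prof[, grep("^q", names(prof))])),
               rep(0.3, 19))      # degenerate distribution: all quantiles equal

  panel <- small_mapped_panel(seed = 10, n_acc = 50, per_lg = 40)
  lp <- intra_lg_ld(panel$G, panel$map)
  prof2 <- ld_decay_profile(lp, bin_width = 5, min_pairs = 5)
  qcols <- grep("^q", names(prof2), value = TRUE)
  for (i in seq_len(nrow(prof2)))
    expect_false(is.unsorted(unlist(prof2[i, qcols])))
  expect_true(all(prof2$n_pairs >= 5))
})

test_that("r2v equals r2 under identity kinship and respects bounds", {
  set.seed(3)
  n <- 40
  g_a <- as.integer(rbinom(n, 2, 0.4))
  g_b <- as.integer(rbinom(n, 2, 0.6))
  K <- diag(n)
  expect_equal(r2v(g_a, g_b, K), pairwise_r2(g_a, g_b), tolerance = 1e-10)
  expect_equal(r2v(g_a, g_a, K), 1, tolerance = 1e-10)
  # arbitrary valid kinship: perfect correlation stays 1, result in [0,1]
  X <- matrix(rnorm(n * 10), n)
  Kr <- tcrossprod(X) / 10 + diag(0.5, n)
  expect_equal(r2v(g_a, g_a, Kr), 1, tolerance = 1e-8)
  v <- r2v(g_a, g_b, Kr)
  expect_gte(v, 0); expect_lte(v, 1)
})

test_that("r2v removes structure-induced LD between unlinked markers", {
  # two diverged subpopulations create LD between unlinked markers;
  # whitening by the kinship should remove most of it on average
  sim <- simulate_panel(sim_config(seed = 12, n_groups = 2,
                                   n_per_group = 60, drift_F = 0.4,
                                   n_linkage_groups = 2,
                                   markers_per_lg = 120,
                                   outlier_loci = NULL,
                                   group_names = c("A", "B")))
  G <- filter_snps(sim$genotypes, min_maf = 0.05)
  K <- kinship_matrix(G)
  m1 <- intersect(sim$map$marker[sim$map$linkage_group == 1], colnames(G))
  m2 <- intersect(sim$map$marker[sim$map$linkage_group == 2], colnames(G))
  set.seed(1)
  m1 <- sample(m1, 25); m2 <- sample(m2, 25)
  raw <- mapply(function(a, b) pairwise_r2(G[, a], G[, b]), m1, m2)
  cor <- mapply(function(a, b) r2v(G[, a], G[, b], K), m1, m2)
  expect_gt(mean(raw, na.rm = TRUE), mean(cor, na.rm = TRUE))
})

test_that("r2v_matrix agrees with per-pair r2v on complete data", {
  set.seed(6)
  n <- 30
  G <- matrix(as.integer(rbinom(n * 6, 2, 0.5)), n,
              dimnames = list(sprintf("a%d", 1:n), sprintf("m%d", 1:6)))
  X <- matrix(rnorm(n * 20), n)
  K <- tcrossprod(X) / 20 + diag(0.3, n)
  R <- r2v_matrix(G, K)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(R[i, j], r2v(G[, i], G[, j], K), tolerance = 1e-8)
})

test_that("physical_ld pairs only markers sharing a scaffold", {
  G <- random_geno(30, 5, missing_rate = 0, seed = 14)
  map <- data.frame(marker = colnames(G), linkage_group = 1,
                    cM = c(0, 0.1, 0.2, 5, 9),
                    scaffold = c("s1", "s1", "s2", "s2", NA),
                    bp = c(100L, 1100L, 50L, 900L, NA))
  ph <- physical_ld(G, map)
  expect_equal(nrow(ph), 2)   # (m1,m2) on s1 and (m3,m4) on s2
  expect_equal(ph$dist_bp[ph$marker_a == "m001"], 1000)
  # brute-force enumeration oracle
  brute <- sum(sapply(unique(na.omit(map$scaffold)), function(s)
    choose(sum(!is.na(map$scaffold) & map$scaffold == s), 2)))
  expect_equal(nrow(ph), brute)
})

test_that("simulated physical pair count matches combinatorial enumeration", {
  sim <- simulate_panel(sim_config(seed = 16, n_per_group = 30,
                                   n_linkage_groups = 2, markers_per_lg = 80,
                                   outlier_loci = NULL))
  ph <- physical_ld(sim$genotypes, sim$map)
  brute <- sum(sapply(split(sim$map$marker, sim$map$scaffold),
                      function(m) choose(length(m), 2)))
  expect_equal(nrow(ph), brute)
})

test_that("LD heatmap matrices are symmetric with unit diagonal", {
  panel <- small_mapped_panel(seed = 18, n_acc = 40, per_lg = 20)
  R <- ld_matrix(panel$G, panel$map, lg = 1)
  expect_equal(R, t(R), tolerance = 1e-12)
  expect_equal(unname(diag(R)), rep(1, nrow(R)))
  K <- kinship_matrix(panel$G)
  Rv <- ld_matrix(panel$G, panel$map, lg = 1, kinship = K)
  expect_equal(Rv, t(Rv), tolerance = 1e-10)
  expect_equal(unname(diag(Rv)), rep(1, nrow(Rv)))
})
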