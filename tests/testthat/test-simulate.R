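test_that("the generator is deterministic given seed and config", {
  cfg <- sim_config(seed = 42, n_per_group = 20, markers_per_lg = 40,
                    n_linkage_groups = 2, outlier_loci = NULL)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$map, s2$map)
  expect_identical(s1$truth$markers, s2$truth$markers)
})

test_that("forced homozygosity yields only dosages 0 and 2", {
  sim <- simulate_panel(sim_config(seed = 1, n_per_group = 20,
                                   markers_per_lg = 50,
                                   n_linkage_groups = 2,
                                   outlier_loci = NULL,
                                   inbreeding_prob = 1,
                                   het_residual_rate = 0,
                                   missing_rate = 0))
  expect_true(all(sim$genotypes %in% c(0L, 2L)))
})

test_that("truth records match the emitted matrices exactly", {
  sim <- simulate_panel(sim_config(seed = 2, n_per_group = 15,
                                   markers_per_lg = 30,
                                   n_linkage_groups = 2,
                                   outlier_loci = NULL))
  expect_identical(sim$truth$markers$marker, colnames(sim$genotypes))
  expect_identical(sim$truth$accessions$accession, rownames(sim$genotypes))
  expect_identical(sim$map$marker, colnames(sim$genotypes))
  expect_equal(dim(sim$truth$mosaic$hap1), dim(sim$genotypes))
})

test_that("near-zero drift with a large founder pool gives F_ST near 0", {
  sim <- simulate_panel(sim_config(seed = 3, drift_F = 1e-4,
                                   n_founders = 200, n_per_group = 50,
                                   markers_per_lg = 150,
                                   n_linkage_groups = 3,
                                   outlier_loci = NULL))
  # per-group frequencies track the ancestral frequency
  tm <- sim$truth$markers
  expect_lt(max(abs(tm$p_wild - tm$ancestral_p)), 0.05)
  G <- filter_snps(sim$genotypes)
  mf <- mean_multilocus_fst(G, sim$groups)
  expect_lt(abs(mf$multilocus), 0.02)
})

test_that("drawn group frequencies have Balding-Nichols moments", {
  sim <- simulate_panel(sim_config(seed = 5, markers_per_lg = 300,
                                   outlier_loci = NULL))
  tm <- sim$truth$markers
  for (g in c("wild", "winter", "spring")) {
    dev <- tm[[paste0("p_", g)]] - tm$ancestral_p
    expect_lt(abs(mean(dev)), 0.02)                 # mean ~ ancestral p
    ratio <- mean(dev^2) / mean(0.3 * tm$ancestral_p * (1 - tm$ancestral_p))
    expect_lt(abs(ratio - 1), 0.15)                 # var ~ F p (1 - p)
  }
})

test_that("missing data appear at the configured rate", {
  sim <- simulate_panel(sim_config(seed = 7, n_per_group = 50,
                                   markers_per_lg = 100,
                                   n_linkage_groups = 2,
                                   outlier_loci = NULL,
                                   missing_rate = 0.1))
  rate <- mean(is.na(sim$genotypes))
  expect_lt(abs(rate - 0.1), 0.01)
})

test_that("ascertainment biases the wild group toward rare alleles", {
  sim <- simulate_panel(sim_config(seed = 9, ascertainment_min_maf = 0.05))
  G <- filter_snps(sim$genotypes)
  low_frac <- function(g) {
    h <- maf_histogram(G, sim$groups$accession[sim$groups$group == g])
    sum(h$count[h$bin_hi <= 0.1]) / sum(h$count)
  }
  expect_gt(low_frac("wild"), low_frac("spring"))
  expect_gt(low_frac("wild"), low_frac("winter"))
  he <- group_he(G, sim$groups)
  expect_lt(he$mean_He[he$group == "wild"],
            min(he$mean_He[he$group != "wild"]))
})

test_that("fewer founders produce stronger short-range LD", {
  short_r2 <- function(nf) {
    sim <- simulate_panel(sim_config(seed = 11, n_groups = 1,
                                     n_per_group = 60, n_founders = nf,
                                     n_linkage_groups = 2,
                                     markers_per_lg = 120,
                                     outlier_loci = NULL,
                                     group_names = "pop"))
    chk <- ld_expectation_check(sim, bin_width = 2)
    chk$profile$mean_r2[1]
  }
  expect_gt(short_r2(2), short_r2(50))
})

test_that("free recombination flattens the decay profile", {
  sim <- simulate_panel(sim_config(seed = 13, n_groups = 1,
                                   n_per_group = 60,
                                   switch_rate_per_cM = 100,
                                   n_linkage_groups = 2,
                                   markers_per_lg = 120,
                                   outlier_loci = NULL,
                                   group_names = "pop"))
  chk <- ld_expectation_check(sim, bin_width = 5)
  prof <- chk$profile
  expect_lt(max(prof$mean_r2) - min(prof$mean_r2), 0.02)
})

test_that("default panel LD decays with genetic distance", {
  sim <- simulate_panel(sim_config(seed = 15))
  chk <- ld_expectation_check(sim, group = "winter")
  expect_true(chk$decays)
  expect_gt(nrow(chk$profile), 10)
})

test_that("planted outliers carry the designated group divergence in truth", {
  sim <- simulate_panel(sim_config(seed = 17))
  tm <- sim$truth$markers
  out <- tm[tm$outlier, ]
  expect_equal(nrow(out), 10)
  expect_true(all(abs(out$p_winter - out$p_spring) > 0.8))
  expect_true(all(out$linkage_group %in% c(5, 6)))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_per_group = 0), "empty group")
  expect_error(sim_config(n_founders = 0), "founder")
  expect_error(sim_config(drift_F = 1.2), "drift_F")
  expect_error(sim_config(missing_rate = 2), "probabilities")
  expect_error(sim_config(n_groups = 2, group_names = c("A", "B")),
               "group names")  # default outliers reference winter/spring
})
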