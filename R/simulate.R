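#' Simulation configuration for a structured panel of inbred lines
#'
#' Defaults describe a desk-scale analogue of a diverse germplasm
#' collection genotyped on a mapped SNP array: three strongly diverged
#' groups (wild-like, winter-like, spring-like) of near-homozygous lines,
#' markers on 7 linkage groups, steep distance-decaying LD from a
#' founder-mosaic copying process, a drift coefficient F = 0.3 per group
#' (Balding-Nichols), and ten planted outlier loci strongly differentiated
#' between the winter- and spring-like groups in two clusters on linkage
#' groups 5 (37-87 cM) and 6 (46-50 cM).
#'
#' @param seed master RNG seed; all randomness derives from it.
#' @param n_groups number of groups.
#' @param n_per_group accessions per group (recycled to `n_groups`).
#' @param drift_F Balding-Nichols drift coefficient per group in (0, 1)
#'   (recycled).
#' @param n_linkage_groups,markers_per_lg,lg_length_cM map geometry.
#' @param n_founders founder haplotypes per group. Pools are allocated by
#'   stratified rounding (`round(n_founders * p)` ALT copies on random
#'   founders), so group frequencies are quantised to multiples of
#'   `1/n_founders` but the realized group divergence matches `drift_F`
#'   without a second founder-bottleneck term.
#' @param switch_rate_per_cM Poisson intensity of founder switches along
#'   the cM axis (lower = longer shared segments = stronger LD).
#' @param inbreeding_prob probability an individual's second haplotype is
#'   a copy of the first (selfing-derived line).
#' @param het_residual_rate rate of residual heterozygous calls injected
#'   into the final dosages.
#' @param missing_rate uniform missing-call rate.
#' @param ancestral_freq_range range of the uniform ancestral allele
#'   frequency.
#' @param outlier_loci data.frame of planted outliers: `lg`, `cM`, `fst`
#'   (target between-pair differentiation), and the designated group pair
#'   in `group_a`, `group_b`; `NULL` for none.
#' @param ascertainment_min_maf when non-`NULL`, loci with pooled MAF
#'   below this in `ascertainment_groups` are dropped, emulating an
#'   array discovery-panel bias against alleles rare in cultivated
#'   material.
#' @param ascertainment_groups groups forming the ascertainment pool
#'   (default: all but the first, i.e. the cultivated-like groups).
#' @param scaffold_span_cM genetic span of one physical scaffold.
#' @param bp_per_cM physical bp per cM (default 5.6e6, genome-scale
#'   arithmetic for a ~4.45 Gb genome over a ~800 cM map).
#' @param group_names labels for the groups.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_groups = 3, n_per_group = 100,
                       drift_F = 0.3, n_linkage_groups = 7,
                       markers_per_lg = 286, lg_length_cM = 113,
                       n_founders = 8, switch_rate_per_cM = 0.1,
                       inbreeding_prob = 0.98, het_residual_rate = 0.002,
                       missing_rate = 0.03,
                       ancestral_freq_range = c(0.05, 0.95),
                       outlier_loci = default_outlier_loci(),
                       ascertainment_min_maf = NULL,
                       ascertainment_groups = NULL,
                       scaffold_span_cM = 1, bp_per_cM = 5.6e6,
                       group_names = NULL) {
  if (is.null(group_names))
    group_names <- if (n_groups == 3) c("wild", "winter", "spring")
      else paste0("group", seq_len(n_groups))
  cfg <- list(seed = seed, n_groups = n_groups,
              n_per_group = rep_len(n_per_group, n_groups),
              drift_F = rep_len(drift_F, n_groups),
              n_linkage_groups = n_linkage_groups,
              markers_per_lg = markers_per_lg,
              lg_length_cM = lg_length_cM, n_founders = n_founders,
              switch_rate_per_cM = switch_rate_per_cM,
              inbreeding_prob = inbreeding_prob,
              het_residual_rate = het_residual_rate,
              missing_rate = missing_rate,
              ancestral_freq_range = ancestral_freq_range,
              outlier_loci = outlier_loci,
              ascertainment_min_maf = ascertainment_min_maf,
              ascertainment_groups = ascertainment_groups,
              scaffold_span_cM = scaffold_span_cM, bp_per_cM = bp_per_cM,
              group_names = group_names)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param config configuration list to validate.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    if (any(n_per_group < 1)) stop("empty group in config")
    if (n_founders < 1) stop("need at least one founder")
    if (markers_per_lg < 2) stop("markers_per_lg must be >= 2")
    if (any(drift_F <= 0 | drift_F >= 1)) stop("drift_F must be in (0,1)")
    probs <- c(inbreeding_prob, het_residual_rate, missing_rate)
    if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]")
    if (!is.null(outlier_loci)) {
      need <- c("lg", "cM", "fst", "group_a", "group_b")
      if (!all(need %in% names(outlier_loci)))
        stop("outlier_loci needs columns: ", paste(need, collapse = ", "))
      if (!all(outlier_loci$group_a %in% group_names) ||
          !all(outlier_loci$group_b %in% group_names))
        stop("outlier group pair must use configured group names")
      if (any(outlier_loci$lg > n_linkage_groups) ||
          any(outlier_loci$cM > lg_length_cM))
        stop("outlier loci placed outside the configured map")
    }
  })
  invisible(config)
}

#' @rdname sim_config
#' @export
default_outlier_loci <- function() {
  data.frame(
    lg = c(rep(5L, 6), rep(6L, 4)),
    cM = c(37.8, 45.0, 53.6, 61.0, 67.3, 86.2, 46.9, 47.4, 49.1, 49.8),
    fst = 0.8,
    group_a = "winter", group_b = "spring",
    stringsAsFactors = FALSE
  )
}

# Stratified founder-pool allocation: each locus gets round(K * p) ALT
# copies placed on random founders. An iid Bernoulli pool would add
# ~p(1-p)/K of extra frequency variance (a second bottleneck on top of
# the Balding-Nichols drift) and an atom of chance fixations; stratified
# allocation keeps the realized group divergence equal to the drawn
# drift, at the cost of quantising group frequencies to multiples of 1/K.
founder_pool <- function(p, n_founders) {
  m <- length(p)
  n_alt <- round(n_founders * p)
  ranks <- apply(matrix(stats::runif(n_founders * m), n_founders, m), 2, rank)
  matrix(as.integer(t(t(ranks) <= n_alt)), n_founders, m)
}

# founder-mosaic path along one linkage group: founder index per marker
mosaic_path <- function(pos, lg_len, n_founders, switch_rate) {
  n_sw <- stats::rpois(1, switch_rate * lg_len)
  sw <- sort(stats::runif(n_sw, 0, lg_len))
  founders <- sample.int(n_founders, n_sw + 1, replace = TRUE)
  founders[findInterval(pos, sw) + 1L]
}

#' Simulate a structured genotype panel with truth records
#'
#' Generates a genotype matrix, marker map and group assignment with the
#' statistical structure a diversity/LD/differentiation analysis assumes,
#' plus the ground truth needed for recovery tests. All randomness derives
#' from `config$seed`; draws occur in a fixed documented order (map,
#' ancestral frequencies, group frequencies, outlier placement, founder
#' haplotypes, per-accession mosaics, residual heterozygosity, missing
#' mask), so identical configs reproduce identical panels.
#'
#' Procedure: ancestral frequencies are uniform on
#' `ancestral_freq_range`; per-group frequencies follow the
#' Balding-Nichols Beta distribution with the group's drift F; planted
#' outlier loci instead displace the designated group pair symmetrically
#' by `sqrt(fst * p * (1 - p))` around a mid-range ancestral frequency
#' (sign randomised), which realises the target between-pair
#' differentiation; founder haplotypes are drawn site-independently from
#' the group frequencies; each sample haplotype copies founders in a
#' mosaic along each linkage group with Poisson(switch rate) breakpoints;
#' selfed lines duplicate their first haplotype with probability
#' `inbreeding_prob`; residual heterozygous calls and missing entries are
#' injected at the configured rates; optional ascertainment drops loci
#' rare in the cultivated-like pool; physical coordinates place
#' consecutive markers on scaffolds of `scaffold_span_cM` at
#' `bp_per_cM`.
#'
#' @param config a [sim_config()].
#' @return list: `genotypes` (matrix), `map`, `groups`, `truth` (list with
#'   `markers` data.frame incl. ancestral and per-group frequencies and
#'   outlier flags, `accessions`, and founder `mosaic` index matrices),
#'   and `config`.
#' @export
simulate_panel <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  K <- config$n_groups
  gn <- config$group_names

  # --- map (neutral markers + planted outliers inserted at their positions)
  maps <- lapply(seq_len(config$n_linkage_groups), function(l) {
    pos <- sort(stats::runif(config$markers_per_lg, 0, config$lg_length_cM))
    data.frame(marker = sprintf("M%d_%03d", l, seq_along(pos)),
               linkage_group = l, cM = round(pos, 3), outlier = FALSE,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  ol <- config$outlier_loci
  if (!is.null(ol) && nrow(ol)) {
    out_rows <- data.frame(marker = sprintf("OUT%d_%04.1f", ol$lg, ol$cM),
                           linkage_group = ol$lg, cM = ol$cM, outlier = TRUE,
                           stringsAsFactors = FALSE)
    map <- rbind(map, out_rows)
  }
  map <- map[order(map$linkage_group, map$cM), ]
  rownames(map) <- NULL
  m <- nrow(map)

  # --- ancestral and per-group allele frequencies
  p_anc <- stats::runif(m, config$ancestral_freq_range[1],
                        config$ancestral_freq_range[2])
  p_anc[map$outlier] <- 0.5
  p_grp <- matrix(NA_real_, m, K, dimnames = list(map$marker, gn))
  for (k in seq_len(K)) {
    f <- config$drift_F[k]
    p_grp[, k] <- stats::rbeta(m, p_anc * (1 - f) / f,
                               (1 - p_anc) * (1 - f) / f)
  }
  if (!is.null(ol) && nrow(ol)) {
    out_idx <- match(sprintf("OUT%d_%04.1f", ol$lg, ol$cM), map$marker)
    delta <- sqrt(ol$fst * p_anc[out_idx] * (1 - p_anc[out_idx]))
    s <- sample(c(-1, 1), nrow(ol), replace = TRUE)
    pa <- pmin(pmax(p_anc[out_idx] + s * delta, 0.005), 0.995)
    pb <- pmin(pmax(p_anc[out_idx] - s * delta, 0.005), 0.995)
    p_grp[cbind(out_idx, match(ol$group_a, gn))] <- pa
    p_grp[cbind(out_idx, match(ol$group_b, gn))] <- pb
  }

  # --- founder haplotypes per group (site-independent given p_grp,
  #     stratified so the pool frequency tracks p_grp)
  founders <- lapply(seq_len(K), function(k) {
    founder_pool(p_grp[, k], config$n_founders)
  })

  # --- accession mosaics
  n_total <- sum(config$n_per_group)
  G <- matrix(NA_integer_, n_total, m)
  hap1_id <- hap2_id <- matrix(NA_integer_, n_total, m)
  acc_names <- character(n_total)
  acc_group <- character(n_total)
  lg_of <- map$linkage_group
  pos_of <- map$cM
  row <- 0L
  for (k in seq_len(K)) {
    Fk <- founders[[k]]
    for (i in seq_len(config$n_per_group[k])) {
      row <- row + 1L
      acc_names[row] <- sprintf("%s_%03d", gn[k], i)
      acc_group[row] <- gn[k]
      draw_hap <- function() {
        fid <- integer(m)
        for (l in seq_len(config$n_linkage_groups)) {
          sel <- lg_of == l
          fid[sel] <- mosaic_path(pos_of[sel], config$lg_length_cM,
                                  config$n_founders,
                                  config$switch_rate_per_cM)
        }
        fid
      }
      f1 <- draw_hap()
      selfed <- stats::runif(1) < config$inbreeding_prob
      f2 <- if (selfed) f1 else draw_hap()
      hap1_id[row, ] <- f1
      hap2_id[row, ] <- f2
      G[row, ] <- Fk[cbind(f1, seq_len(m))] + Fk[cbind(f2, seq_len(m))]
    }
  }
  dimnames(G) <- list(acc_names, map$marker)

  # --- residual heterozygosity, then missing mask
  if (config$het_residual_rate > 0) {
    flip <- matrix(stats::runif(n_total * m) < config$het_residual_rate,
                   n_total, m)
    G[flip] <- 1L
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n_total * m) < config$missing_rate,
                   n_total, m)
    G[miss] <- NA_integer_
  }

  groups <- data.frame(accession = acc_names, group = acc_group,
                       stringsAsFactors = FALSE)

  # --- ascertainment: drop loci rare in the cultivated-like pool
  keep <- rep(TRUE, m)
  if (!is.null(config$ascertainment_min_maf)) {
    asc_groups <- config$ascertainment_groups
    if (is.null(asc_groups)) asc_groups <- gn[-1]
    pool <- groups$accession[groups$group %in% asc_groups]
    p_pool <- allele_freq(G, pool)
    maf_pool <- pmin(p_pool, 1 - p_pool)
    keep <- !is.na(maf_pool) & maf_pool >= config$ascertainment_min_maf
  }

  # --- physical coordinates: scaffolds of fixed genetic span
  sc_idx <- floor(map$cM / config$scaffold_span_cM)
  map$scaffold <- sprintf("scf_%d_%d", map$linkage_group, sc_idx)
  map$bp <- as.integer(round((map$cM - sc_idx * config$scaffold_span_cM) *
                               config$bp_per_cM)) + 1L

  truth_markers <- data.frame(map[, c("marker", "linkage_group", "cM")],
                              ancestral_p = p_anc, outlier = map$outlier,
                              stringsAsFactors = FALSE)
  for (k in seq_len(K)) truth_markers[[paste0("p_", gn[k])]] <- p_grp[, k]

  G <- G[, keep, drop = FALSE]
  map_out <- map[keep, c("marker", "linkage_group", "cM", "scaffold", "bp")]
  rownames(map_out) <- NULL
  truth_markers <- truth_markers[keep, , drop = FALSE]
  rownames(truth_markers) <- NULL

  list(genotypes = G, map = map_out, groups = groups,
       truth = list(markers = truth_markers, accessions = groups,
                    mosaic = list(hap1 = hap1_id[, keep, drop = FALSE],
                                  hap2 = hap2_id[, keep, drop = FALSE])),
       config = config)
}

#' Check the generator's LD decay against expectation
#'
#' Computes the within-group mean r2 per genetic-distance bin (after the
#' usual MAF >= 0.05 filter) and summarises whether mean r2 decays from
#' the shortest to the longest distance bin — the signature the
#' founder-mosaic process must produce.
#'
#' @param sim output of [simulate_panel()].
#' @param group group label to compute LD within (default: first group).
#' @param bin_width distance bin width in cM (default 1).
#' @param min_pairs minimum pairs per bin (default 10).
#' @return list: `profile` (data.frame bin_mid, mean_r2, n_pairs),
#'   `decays` (logical: first-bin mean exceeds last-bin mean).
#' @export
ld_expectation_check <- function(sim, group = NULL, bin_width = 1,
                                 min_pairs = 10) {
  if (is.null(group)) group <- sim$groups$group[1]
  acc <- sim$groups$accession[sim$groups$group == group]
  Gg <- filter_snps(sim$genotypes[acc, , drop = FALSE],
                    max_missing = 1, max_het = 1, min_maf = 0.05)
  pairs <- intra_lg_ld(Gg, sim$map)
  pairs <- pairs[!is.na(pairs$r2), ]
  bin <- floor(pairs$dist_cM / bin_width)
  agg <- stats::aggregate(pairs$r2, by = list(bin = bin),
                          FUN = function(x) c(mean(x), length(x)))
  profile <- data.frame(bin_mid = (agg$bin + 0.5) * bin_width,
                        mean_r2 = agg$x[, 1], n_pairs = agg$x[, 2])
  profile <- profile[profile$n_pairs >= min_pairs, ]
  list(profile = profile,
       decays = profile$mean_r2[1] > profile$mean_r2[nrow(profile)])
}
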