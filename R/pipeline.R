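#' Build a pipeline run configuration
#'
#' Exactly one of `inputs` (paths to genotype / map / group files) or
#' `sim` (a [sim_config()]) must be given. Two filtered views of the
#' input are maintained throughout: a structure/diversity view
#' (MAF >= `maf_structure`, default 0.02) and an LD view
#' (MAF >= `maf_ld`, default 0.05), both behind the same missing-rate and
#' heterozygosity filters.
#'
#' @param inputs list with `genotypes`, `map`, `groups` paths (and
#'   optional `format` = "table"/"vcf").
#' @param sim a [sim_config()].
#' @param max_missing,max_het,maf_structure,maf_ld marker filters.
#' @param stages named logical list toggling `qc`, `diversity`,
#'   `relatedness`, `ld`, `ld_kinship`, `fstscan`.
#' @param contrast group labels for the differentiation scan (default:
#'   all groups).
#' @param exclude_groups groups omitted from the scan and mean F_ST.
#' @param ibs_threshold IBS network threshold.
#' @param he_reps resampling replicates for size-equalised He.
#' @param seed RNG seed for the run.
#' @return a `run_config` list.
#' @export
run_config <- function(inputs = NULL, sim = NULL, max_missing = 0.2,
                       max_het = 0.05, maf_structure = 0.02, maf_ld = 0.05,
                       stages = list(), contrast = NULL,
                       exclude_groups = NULL, ibs_threshold = 0.8,
                       he_reps = 50, seed = 1) {
  if (is.null(inputs) == is.null(sim))
    stop("exactly one of 'inputs' or 'sim' must be given")
  defaults <- list(qc = TRUE, diversity = TRUE, relatedness = TRUE,
                   ld = TRUE, ld_kinship = TRUE, fstscan = TRUE)
  defaults[names(stages)] <- stages
  structure(list(inputs = inputs, sim = sim, max_missing = max_missing,
                 max_het = max_het, maf_structure = maf_structure,
                 maf_ld = maf_ld, stages = defaults, contrast = contrast,
                 exclude_groups = exclude_groups,
                 ibs_threshold = ibs_threshold, he_reps = he_reps,
                 seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `sim` block is
#' passed to [sim_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(run_config, y)
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the stages in dependency order — load or simulate, marker QC,
#' per-group diversity (He, resampled He, MAF spectra, joint spectra),
#' relatedness (distance / IBS / kinship, Ward tree, IBS network), LD
#' (decay profile, physical-distance pairs, per-LG heatmap matrices raw
#' and kinship-corrected) and the differentiation scan (F_ST / G_ST /
#' Jost's D, ANOVA across linkage groups, empirical outliers) — writing
#' every output under `out_dir` and a `manifest.json` listing each file
#' with its MD5 checksum together with the thresholds, seed and marker /
#' accession counts after every filter.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  files <- character()
  add <- function(path) files <<- c(files, path)
  log_counts <- list()

  # --- stage: load / simulate -------------------------------------------
  if (!is.null(config$sim)) {
    sim <- simulate_panel(config$sim)
    G <- sim$genotypes; map <- sim$map; groups <- sim$groups
    add(write_genotypes(G, file.path(out_dir, "genotypes.tsv")))
    add(write_map(map, file.path(out_dir, "map.tsv")))
    add(write_groups(groups, file.path(out_dir, "groups.tsv")))
    add(write_table(sim$truth$markers, file.path(out_dir, "truth_markers.tsv")))
  } else {
    fmt <- if (is.null(config$inputs$format)) "table" else config$inputs$format
    G <- read_genotypes(config$inputs$genotypes, format = fmt)
    map <- read_map(config$inputs$map)
    groups <- read_groups(config$inputs$groups, G)
  }
  log_counts$input <- c(accessions = nrow(G), markers = ncol(G))

  # --- stage: qc ---------------------------------------------------------
  if (config$stages$qc) {
    summ <- snp_summary(G)
    add(write_table(summ, file.path(out_dir, "snp_summary.tsv")))
  }
  G_struct <- filter_snps(G, config$max_missing, config$max_het,
                          config$maf_structure)
  G_ld <- filter_snps(G, config$max_missing, config$max_het, config$maf_ld)
  log_counts$structure_view <- c(accessions = nrow(G_struct),
                                 markers = ncol(G_struct))
  log_counts$ld_view <- c(accessions = nrow(G_ld), markers = ncol(G_ld))

  # --- stage: diversity --------------------------------------------------
  if (config$stages$diversity) {
    he <- group_he(G_struct, groups)
    sizes <- table(groups$group)
    ref_n <- min(sizes)
    he$resampled_mean_He <- NA_real_
    he$n_reps <- NA_integer_
    for (i in seq_len(nrow(he))) {
      rs <- resampled_group_he(G_struct, groups, he$group[i], ref_n,
                               n_reps = config$he_reps,
                               seed = config$seed + i)
      he$resampled_mean_He[i] <- rs$resampled_mean_He
      he$n_reps[i] <- rs$n_reps
    }
    add(write_table(he, file.path(out_dir, "group_he.tsv")))
    hist_all <- maf_histogram(G_struct)
    hist_all$group <- "total"
    hists <- list(hist_all)
    for (g in unique(groups$group)) {
      hg <- maf_histogram(G_struct, groups$accession[groups$group == g])
      hg$group <- g
      hists[[length(hists) + 1L]] <- hg
    }
    add(write_table(do.call(rbind, hists),
                    file.path(out_dir, "maf_histograms.tsv")))
    labs <- unique(groups$group)
    if (length(labs) >= 2) {
      joint <- utils::combn(labs, 2, simplify = FALSE)
      jrows <- lapply(joint, function(pr) {
        jh <- joint_maf_histogram(G_struct, groups, pr[1], pr[2])
        data.frame(group_a = pr[1], group_b = pr[2],
                   bin_a = rep(seq_len(nrow(jh$counts)), ncol(jh$counts)),
                   bin_b = rep(seq_len(ncol(jh$counts)),
                               each = nrow(jh$counts)),
                   count = as.vector(jh$counts), stringsAsFactors = FALSE)
      })
      add(write_table(do.call(rbind, jrows),
                      file.path(out_dir, "joint_maf_histograms.tsv")))
    }
  }

  # --- stage: relatedness ------------------------------------------------
  K <- NULL
  if (config$stages$relatedness || config$stages$ld_kinship) {
    K <- kinship_matrix(G_struct)
  }
  if (config$stages$relatedness) {
    D <- allele_sharing_distance(G_struct)
    add(write_matrix_tsv(D, file.path(out_dir, "distance.tsv")))
    add(write_matrix_tsv(1 - D, file.path(out_dir, "ibs.tsv")))
    add(write_matrix_tsv(K, file.path(out_dir, "kinship.tsv")))
    add(write_newick(ward_tree(D), file.path(out_dir, "ward_tree.nwk")))
    net <- ibs_network(G_struct, threshold = config$ibs_threshold,
                       groups = groups, ibs = 1 - D)
    add(write_network(net, file.path(out_dir, "ibs_network_edges.tsv"),
                      file.path(out_dir, "ibs_network.graphml")))
  }

  # --- stage: LD ---------------------------------------------------------
  if (config$stages$ld) {
    pairs <- intra_lg_ld(G_ld, map)
    profile <- ld_decay_profile(pairs)
    add(write_table(profile, file.path(out_dir, "ld_decay_profile.tsv")))
    phys <- physical_ld(G_ld, map)
    if (nrow(phys))
      add(write_table(phys, file.path(out_dir, "ld_physical_pairs.tsv")))
    lg1 <- map$linkage_group[1]
    R <- ld_matrix(G_ld, map, lg1)
    add(write_matrix_tsv(R, file.path(out_dir,
                                      paste0("ld_heatmap_lg", lg1, ".tsv"))))
    if (config$stages$ld_kinship) {
      Rv <- ld_matrix(G_ld, map, lg1, kinship = K)
      add(write_matrix_tsv(Rv,
        file.path(out_dir, paste0("ld_heatmap_lg", lg1, "_corrected.tsv"))))
    }
  }

  # --- stage: differentiation scan --------------------------------------
  if (config$stages$fstscan) {
    scan <- fst_scan(G_struct, groups, map, groups_used = config$contrast,
                     exclude_groups = config$exclude_groups)
    add(write_table(scan, file.path(out_dir, "fst_scan.tsv")))
    outl <- empirical_outliers(scan)
    if (nrow(outl)) {
      outl$flag <- attr(outl, "method")
      add(write_table(outl, file.path(out_dir, "fst_outliers.tsv")))
    }
    av <- anova_fst_by_lg(scan)
    mf <- mean_multilocus_fst(G_struct, groups,
                              exclude_groups = config$exclude_groups)
    summary_stats <- list(
      mean_fst_multilocus = mf$multilocus,
      mean_fst_per_marker = mf$mean_per_marker,
      n_markers_fst = mf$n_markers,
      anova_F = av$F, anova_df = av$df, anova_p = av$p_value,
      n_monomorphic_excluded = attr(scan, "n_monomorphic"),
      outlier_threshold = attr(outl, "threshold"),
      outlier_flagging = "empirical, not model-based")
    sp <- file.path(out_dir, "fst_summary.json")
    jsonlite::write_json(summary_stats, sp, auto_unbox = TRUE, digits = NA)
    add(sp)
  }

  manifest <- list(
    seed = config$seed,
    thresholds = list(max_missing = config$max_missing,
                      max_het = config$max_het,
                      maf_structure = config$maf_structure,
                      maf_ld = config$maf_ld),
    counts = log_counts,
    package_version = as.character(utils::packageVersion("germscan")),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
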