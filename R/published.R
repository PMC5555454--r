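#' Recompute headline summaries from a genotyped-collection directory
#'
#' Given the real genotype matrix, consensus map and group labels of a
#' genotyped germplasm collection, recomputes the summaries that a
#' diversity / LD / differentiation study reports: per-taxon polymorphic
#' marker counts, per-group mean He with size-equalised resampling, the
#' multilocus mean F_ST across clusters (optionally omitting clusters),
#' the per-SNP F_ST / Jost's D for a winter-vs-spring style contrast, and
#' the median r2 at a given genetic distance.
#'
#' Expected files under `dir` (tab-separated, standard package layouts):
#' `genotypes.tsv` ([read_genotypes()]), `map.tsv` ([read_map()]),
#' `groups.tsv` (accession to wild/winter/spring-style label),
#' optionally `clusters.tsv` (accession to fine cluster label) and
#' `taxa.tsv` (accession to taxon, e.g. species assignments).
#'
#' @param dir directory containing the files above.
#' @param contrast two group labels for the per-SNP scan (default
#'   `c("winter", "spring")`).
#' @param exclude_clusters cluster labels omitted from the multilocus
#'   F_ST across clusters.
#' @param snp_ids optional marker ids whose scan rows are returned
#'   individually.
#' @param ld_dist_cM genetic distance (cM) at which the median r2 is
#'   reported (default 5; the bin containing this distance).
#' @param he_reps resampling replicates (default 50).
#' @param seed RNG seed for the resampling.
#' @return list with `polymorphic_counts` (per taxon, when `taxa.tsv`
#'   present), `group_he`, `mean_fst_clusters` (when `clusters.tsv`
#'   present), `scan_snps` (rows for `snp_ids`), `median_r2_at_dist`.
#' @export
recompute_published_summaries <- function(dir,
                                          contrast = c("winter", "spring"),
                                          exclude_clusters = NULL,
                                          snp_ids = NULL, ld_dist_cM = 5,
                                          he_reps = 50, seed = 1) {
  paths <- file.path(dir, c("genotypes.tsv", "map.tsv", "groups.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("genotyped-collection files not found: ",
         paste(missing, collapse = ", "))
  G <- read_genotypes(paths[1])
  map <- read_map(paths[2])
  groups <- read_groups(paths[3], G)

  G_struct <- filter_snps(G, 0.2, 0.05, 0.02)
  G_ld <- filter_snps(G, 0.2, 0.05, 0.05)

  res <- list()

  taxa_path <- file.path(dir, "taxa.tsv")
  if (file.exists(taxa_path)) {
    taxa <- utils::read.table(taxa_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    res$polymorphic_counts <- vapply(unique(taxa$taxon), function(tx) {
      polymorphic_count(G_struct, taxa$accession[taxa$taxon == tx])
    }, integer(1))
  }

  he <- group_he(G_struct, groups)
  ref_n <- min(table(groups$group))
  he$resampled_mean_He <- vapply(seq_len(nrow(he)), function(i) {
    resampled_group_he(G_struct, groups, he$group[i], ref_n,
                       n_reps = he_reps, seed = seed + i)$resampled_mean_He
  }, numeric(1))
  res$group_he <- he

  clusters_path <- file.path(dir, "clusters.tsv")
  if (file.exists(clusters_path)) {
    cl <- utils::read.table(clusters_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    names(cl) <- c("accession", "group")
    res$mean_fst_clusters <-
      mean_multilocus_fst(G_struct, cl, exclude_groups = exclude_clusters)
  }

  scan <- fst_scan(G_struct, groups, map, groups_used = contrast)
  if (!is.null(snp_ids))
    res$scan_snps <- scan[scan$marker %in% snp_ids, , drop = FALSE]
  res$scan <- scan

  pairs <- intra_lg_ld(G_ld, map)
  profile <- ld_decay_profile(pairs, bin_width = 0.5)
  bin <- profile[profile$bin_lo <= ld_dist_cM & profile$bin_hi > ld_dist_cM, ]
  res$median_r2_at_dist <- if (nrow(bin)) bin$median[1] else NA_real_
  res
}
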