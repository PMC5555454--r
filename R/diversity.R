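#' Nei's expected heterozygosity for a biallelic marker
#'
#' @param p allele frequency (either allele; He is symmetric in p and 1-p).
#' @return 2 p (1 - p).
#' @export
nei_he <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  2 * p * (1 - p)
}

# ALT allele frequency per marker within a subset (NA when no calls)
allele_freq <- function(G, subset = NULL) {
  if (!is.null(subset)) G <- G[subset, , drop = FALSE]
  n_called <- colSums(!is.na(G))
  ifelse(n_called > 0, colSums(G, na.rm = TRUE) / (2 * n_called), NA_real_)
}

#' Histogram of minor allele frequencies
#'
#' Bins the within-subset MAF of every marker into `n_bins` equal-width
#' bins on \[0, 0.5\]. Markers monomorphic within the subset (MAF 0) fall
#' in the first bin; markers with no calls in the subset are excluded.
#'
#' @param G genotype matrix.
#' @param subset optional accession ids restricting the frequency
#'   computation.
#' @param n_bins number of bins (default 20).
#' @return data.frame with `bin_lo`, `bin_hi`, `count`.
#' @export
maf_histogram <- function(G, subset = NULL, n_bins = 20) {
  p <- allele_freq(G, subset)
  maf <- pmin(p, 1 - p)
  maf <- maf[!is.na(maf)]
  width <- 0.5 / n_bins
  idx <- pmin(floor(maf * (2 * n_bins)) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin_lo = width * (seq_len(n_bins) - 1L),
             bin_hi = width * seq_len(n_bins),
             count = counts)
}

# frequency histogram on [0,1] used for joint-histogram marginals
freq_histogram_counts <- function(freq, n_bins = 10) {
  idx <- pmin(floor(freq * n_bins) + 1L, n_bins)
  tabulate(idx, nbins = n_bins)
}

#' Joint allele-frequency histogram between two groups
#'
#' For each marker the within-group frequency of the globally minor allele
#' (minor over the whole panel) is computed in each group and the pair is
#' binned on a `n_bins` x `n_bins` grid over \[0, 1\] x \[0, 1\]. Using the
#' globally minor allele keeps the axis variable consistent across groups;
#' set `axis = "per_group_maf"` to bin each group's own MAF instead.
#' Markers with no calls in either group are excluded.
#'
#' @param G genotype matrix.
#' @param groups group assignment data.frame (`accession`, `group`).
#' @param group_a,group_b the two (disjoint) group labels.
#' @param n_bins bins per axis (default 10).
#' @param axis `"global_minor"` (default) or `"per_group_maf"`.
#' @return list with `counts` (matrix, rows = `group_a` bins),
#'   `groups`, `n_markers`.
#' @export
joint_maf_histogram <- function(G, groups, group_a, group_b, n_bins = 10,
                                axis = c("global_minor", "per_group_maf")) {
  axis <- match.arg(axis)
  acc_a <- groups$accession[groups$group == group_a]
  acc_b <- groups$accession[groups$group == group_b]
  if (!length(acc_a) || !length(acc_b)) stop("both groups must be non-empty")
  if (length(intersect(acc_a, acc_b))) stop("groups must be disjoint")
  fa <- allele_freq(G, acc_a)
  fb <- allele_freq(G, acc_b)
  if (axis == "global_minor") {
    p_all <- allele_freq(G)
    flip <- !is.na(p_all) & p_all > 0.5   # minor allele is REF: use 1 - p
    fa[flip] <- 1 - fa[flip]
    fb[flip] <- 1 - fb[flip]
  } else {
    fa <- pmin(fa, 1 - fa)
    fb <- pmin(fb, 1 - fb)
  }
  ok <- !is.na(fa) & !is.na(fb)
  ia <- pmin(floor(fa[ok] * n_bins) + 1L, n_bins)
  ib <- pmin(floor(fb[ok] * n_bins) + 1L, n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (k in seq_along(ia)) counts[ia[k], ib[k]] <- counts[ia[k], ib[k]] + 1L
  list(counts = counts, groups = c(group_a, group_b), n_markers = sum(ok))
}

#' Per-group mean expected heterozygosity
#'
#' Mean over markers of Nei's He computed from within-group allele
#' frequencies (called genotypes only). Markers with no calls in a group
#' are excluded from that group's mean; markers monomorphic within the
#' group contribute He = 0.
#'
#' @param G genotype matrix.
#' @param groups group assignment data.frame.
#' @return data.frame with `group`, `mean_He`, `n_markers`, `n_accessions`.
#' @export
group_he <- function(G, groups) {
  validate_groups(groups, G)
  labs <- unique(groups$group)
  res <- lapply(labs, function(g) {
    acc <- groups$accession[groups$group == g]
    he <- nei_he(allele_freq(G, acc))
    data.frame(group = g, mean_He = mean(he, na.rm = TRUE),
               n_markers = sum(!is.na(he)), n_accessions = length(acc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Sample-size-equalising resampled mean He
#'
#' Draws `n_reps` subsamples of `reference_n` accessions (without
#' replacement) from the target group, computes the mean He over markers in
#' each, and returns the mean over replicates. Used to compare gene
#' diversity between groups of unequal size.
#'
#' @param G genotype matrix.
#' @param groups group assignment data.frame.
#' @param target_group group label to resample.
#' @param reference_n subsample size (must not exceed the group size).
#' @param n_reps number of replicates (default 50).
#' @param seed optional RNG seed for reproducibility.
#' @return list with `resampled_mean_He`, `per_rep` (numeric vector),
#'   `n_reps`, `reference_n`.
#' @export
resampled_group_he <- function(G, groups, target_group, reference_n,
                               n_reps = 50, seed = NULL) {
  acc <- groups$accession[groups$group == target_group]
  if (!length(acc)) stop("unknown or empty group: ", target_group)
  if (reference_n > length(acc))
    stop("reference_n (", reference_n, ") exceeds group size (",
         length(acc), ")")
  if (!is.null(seed)) set.seed(seed)
  per_rep <- vapply(seq_len(n_reps), function(i) {
    draw <- sample(acc, reference_n)
    mean(nei_he(allele_freq(G, draw)), na.rm = TRUE)
  }, numeric(1))
  list(resampled_mean_He = mean(per_rep), per_rep = per_rep,
       n_reps = n_reps, reference_n = reference_n)
}
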