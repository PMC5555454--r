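#' Per-SNP summary statistics
#'
#' For each marker: number of called genotypes, missing rate, observed
#' heterozygosity (fraction of called genotypes equal to dosage 1), ALT
#' allele frequency and minor allele frequency, all computed over called
#' genotypes only. Markers with no calls are flagged and get `NA`
#' frequencies.
#'
#' @param G genotype matrix (see [validate_genotypes()]).
#' @return data.frame with one row per marker: `marker`, `n_called`,
#'   `missing_rate`, `het_rate`, `p_alt`, `maf`, `undefined` (no calls).
#' @export
snp_summary <- function(G) {
  validate_genotypes(G)
  n <- nrow(G)
  n_called <- colSums(!is.na(G))
  alt <- colSums(G, na.rm = TRUE)
  het <- colSums(G == 1L, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  data.frame(
    marker = colnames(G),
    n_called = as.integer(n_called),
    missing_rate = (n - n_called) / n,
    het_rate = ifelse(n_called > 0, het / n_called, NA_real_),
    p_alt = p_alt,
    maf = pmin(p_alt, 1 - p_alt),
    undefined = n_called == 0L,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Filter markers on missing rate, heterozygosity and MAF
#'
#' Keeps markers with `missing_rate < max_missing` AND
#' `het_rate < max_het` AND `maf >= min_maf` (markers with no calls are
#' always dropped). Thresholds read literally as "discard at >= threshold"
#' for missing rate and heterozygosity, and "discard below threshold" for
#' MAF. The accession set is unchanged.
#'
#' @param G genotype matrix.
#' @param max_missing discard markers with missing rate at or above this.
#' @param max_het discard markers with observed heterozygosity at or above
#'   this.
#' @param min_maf discard markers with minor allele frequency below this.
#' @return the filtered genotype matrix (possibly with zero columns, with a
#'   warning).
#' @export
filter_snps <- function(G, max_missing = 0.2, max_het = 0.05,
                        min_maf = 0.02) {
  stopifnot(max_missing >= 0, max_missing <= 1, max_het >= 0, max_het <= 1,
            min_maf >= 0, min_maf <= 1)
  s <- snp_summary(G)
  keep <- !s$undefined & s$missing_rate < max_missing &
    s$het_rate < max_het & s$maf >= min_maf
  if (!any(keep)) warning("no markers survive the filters")
  G[, keep, drop = FALSE]
}

#' Count markers polymorphic within a subset of accessions
#'
#' A marker is polymorphic in the subset when both alleles are observed
#' among its called genotypes; a single heterozygous call suffices.
#'
#' @param G genotype matrix.
#' @param subset character vector of accession ids.
#' @return integer count.
#' @export
polymorphic_count <- function(G, subset) {
  if (length(subset) == 0L) stop("subset must be non-empty")
  unknown <- setdiff(subset, rownames(G))
  if (length(unknown))
    stop("unknown accessions: ", paste(utils::head(unknown, 5), collapse = ", "))
  sub <- G[subset, , drop = FALSE]
  mx <- suppressWarnings(apply(sub, 2, max, na.rm = TRUE))
  mn <- suppressWarnings(apply(sub, 2, min, na.rm = TRUE))
  sum(is.finite(mx) & is.finite(mn) & mx > 0 & mn < 2)
}
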