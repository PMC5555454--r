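#' Genotypic r2 between two dosage vectors
#'
#' Squared Pearson correlation of dosages over pairwise-complete
#' accessions. For near-fully inbred lines this coincides with the
#' haplotype r2; no phasing is attempted. Returns `NA` when fewer than two
#' complete pairs remain or either marker has zero variance.
#'
#' @param g_a,g_b dosage vectors of equal length.
#' @return r2 in \[0, 1\], or `NA` when undefined.
#' @export
pairwise_r2 <- function(g_a, g_b) {
  stopifnot(length(g_a) == length(g_b))
  ok <- !is.na(g_a) & !is.na(g_b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- g_a[ok]; b <- g_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' All intra-linkage-group marker pairs with r2 and genetic distance
#'
#' Computes r2 for every pair of markers on the same linkage group
#' (optionally capped at `max_dist_cM`). Markers absent from the map are
#' excluded with a warning. r2 uses pairwise-complete accessions.
#'
#' @param G genotype matrix (MAF-filtered upstream as appropriate).
#' @param map marker map.
#' @param max_dist_cM optional distance cap.
#' @return data.frame: `marker_a`, `marker_b`, `linkage_group`, `dist_cM`,
#'   `r2` (`NA` where undefined, e.g. a monomorphic marker).
#' @export
intra_lg_ld <- function(G, map, max_dist_cM = NULL) {
  in_map <- colnames(G) %in% map$marker
  if (!all(in_map)) {
    warning(sum(!in_map), " markers absent from map; excluded from LD")
    G <- G[, in_map, drop = FALSE]
  }
  idx <- match(colnames(G), map$marker)
  lg <- map$linkage_group[idx]
  cm <- map$cM[idx]
  out <- lapply(unique(lg), function(l) {
    sel <- which(lg == l)
    if (length(sel) < 2L) return(NULL)
    ord <- sel[order(cm[sel])]
    # markers with <2 complete pairs or zero variance give NA from cor
    r2 <- suppressWarnings(stats::cor(G[, ord, drop = FALSE],
                                      use = "pairwise.complete.obs"))^2
    pos <- cm[ord]
    ut <- which(upper.tri(r2), arr.ind = TRUE)
    d <- abs(pos[ut[, 1]] - pos[ut[, 2]])
    df <- data.frame(marker_a = colnames(G)[ord][ut[, 1]],
                     marker_b = colnames(G)[ord][ut[, 2]],
                     linkage_group = l, dist_cM = d, r2 = r2[ut],
                     stringsAsFactors = FALSE)
    if (!is.null(max_dist_cM)) df <- df[df$dist_cM <= max_dist_cM, ]
    df
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(marker_a = character(), marker_b = character(),
                      linkage_group = character(), dist_cM = numeric(),
                      r2 = numeric())
  rownames(out) <- NULL
  out
}

#' Bin LD pairs by distance and summarise with quantiles
#'
#' Pairs are binned by `dist_cM` into fixed-width bins; within each bin the
#' 5-95% quantiles (5% steps) and the median of r2 are reported together
#' with the pair count. Bins with fewer than `min_pairs` pairs are
#' suppressed; pairs with undefined r2 are dropped.
#'
#' @param pairs data.frame from [intra_lg_ld()] (or [physical_ld()], with
#'   `dist_col = "dist_bp"`).
#' @param bin_width bin width on the distance axis (default 0.5 cM).
#' @param quantiles quantile levels (default 5% steps from 5 to 95%).
#' @param min_pairs minimum pairs per reported bin (default 10).
#' @param dist_col distance column name.
#' @return data.frame: `bin_lo`, `bin_hi`, `bin_mid`, `n_pairs`, `median`,
#'   and one `q<level>` column per quantile.
#' @export
ld_decay_profile <- function(pairs, bin_width = 0.5,
                             quantiles = seq(0.05, 0.95, by = 0.05),
                             min_pairs = 10, dist_col = "dist_cM") {
  if (nrow(pairs) == 0L) stop("no LD pairs supplied")
  pairs <- pairs[!is.na(pairs$r2), , drop = FALSE]
  d <- pairs[[dist_col]]
  bin <- floor(d / bin_width)
  out <- lapply(sort(unique(bin)), function(b) {
    r2 <- pairs$r2[bin == b]
    if (length(r2) < min_pairs) return(NULL)
    q <- stats::quantile(r2, probs = quantiles, names = FALSE)
    row <- data.frame(bin_lo = b * bin_width, bin_hi = (b + 1) * bin_width,
                      bin_mid = (b + 0.5) * bin_width,
                      n_pairs = length(r2), median = stats::median(r2))
    qdf <- as.data.frame(as.list(q))
    names(qdf) <- sprintf("q%02d", round(quantiles * 100))
    cbind(row, qdf)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no bin reaches min_pairs = ", min_pairs)
  rownames(out) <- NULL
  out
}

#' Kinship-corrected r2 (r2_V)
#'
#' Squared generalised-least-squares partial correlation of two dosage
#' vectors given a kinship (covariance) matrix: the kinship restricted to
#' accessions complete at both markers is Cholesky-factorised, both dosage
#' vectors are whitened with the inverse factor, the whitened intercept is
#' projected out of each, and the squared Pearson correlation of the
#' residuals is returned (clipped to \[0, 1\]). With an identity kinship
#' this equals [pairwise_r2()] exactly.
#'
#' @param g_a,g_b dosage vectors.
#' @param K kinship matrix covering the accessions of `g_a`/`g_b` (rows in
#'   the same order).
#' @param eps ridge added to the diagonal if the restricted kinship is not
#'   positive definite (default 1e-6).
#' @return r2_V in \[0, 1\], or `NA` when undefined (zero variance).
#' @export
r2v <- function(g_a, g_b, K, eps = 1e-6) {
  stopifnot(length(g_a) == length(g_b), nrow(K) == length(g_a))
  ok <- !is.na(g_a) & !is.na(g_b)
  if (sum(ok) < 3L) return(NA_real_)
  a <- g_a[ok]; b <- g_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  V <- K[ok, ok, drop = FALSE]
  L <- tryCatch(t(chol(V)), error = function(e) NULL)
  if (is.null(L))
    L <- tryCatch(t(chol(V + diag(eps, nrow(V)))), error = function(e)
      stop("kinship matrix singular even after regularisation"))
  wa <- forwardsolve(L, a)
  wb <- forwardsolve(L, b)
  w1 <- forwardsolve(L, rep(1, length(a)))
  proj <- function(y) y - w1 * sum(w1 * y) / sum(w1 * w1)
  ra <- proj(wa); rb <- proj(wb)
  if (sum(ra^2) == 0 || sum(rb^2) == 0) return(NA_real_)
  r2 <- (sum(ra * rb)^2) / (sum(ra^2) * sum(rb^2))
  min(max(r2, 0), 1)
}

#' Kinship-corrected r2 for all marker pairs of a matrix
#'
#' Fast whole-matrix version of [r2v()]: missing dosages are mean-imputed,
#' all markers are whitened with the inverse Cholesky factor of the
#' kinship once, the whitened intercept is projected out and the full
#' squared correlation matrix of the residuals is returned. Exact for
#' complete data; with missing data it deviates from the per-pair
#' complete-case [r2v()] by the imputation.
#'
#' @param G genotype matrix (columns = markers to correlate).
#' @param K kinship for the rows of `G`.
#' @param eps diagonal ridge fallback (default 1e-6).
#' @return symmetric matrix of r2_V values with unit diagonal.
#' @export
r2v_matrix <- function(G, K, eps = 1e-6) {
  stopifnot(nrow(K) == nrow(G))
  X <- G
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  L <- tryCatch(t(chol(K)), error = function(e) t(chol(K + diag(eps, nrow(K)))))
  W <- forwardsolve(L, X)
  w1 <- forwardsolve(L, rep(1, nrow(X)))
  W <- W - outer(w1, colSums(W * w1) / sum(w1 * w1))
  # uncentered correlation of the intercept-projected residuals (the
  # whitened intercept, not the arithmetic mean, is the GLS centering)
  cp <- crossprod(W)
  d <- sqrt(diag(cp))
  R <- (cp / outer(d, d))^2
  R[d == 0, ] <- NA_real_; R[, d == 0] <- NA_real_
  diag(R) <- 1
  R <- pmin(pmax(R, 0), 1)
  dimnames(R) <- list(colnames(G), colnames(G))
  R
}

#' r2 against physical distance for markers sharing a scaffold
#'
#' Emits a pair for every two markers located on the same scaffold with bp
#' positions; `dist_bp = |bp_a - bp_b|`. Markers without physical
#' coordinates are skipped silently.
#'
#' @param G genotype matrix.
#' @param map marker map with `scaffold` and `bp` columns.
#' @return data.frame: `marker_a`, `marker_b`, `scaffold`, `dist_bp`, `r2`.
#' @export
physical_ld <- function(G, map) {
  empty <- data.frame(marker_a = character(), marker_b = character(),
                      scaffold = character(), dist_bp = numeric(),
                      r2 = numeric())
  if (!all(c("scaffold", "bp") %in% names(map))) return(empty)
  phys <- map[!is.na(map$scaffold) & !is.na(map$bp) &
                map$marker %in% colnames(G), , drop = FALSE]
  out <- lapply(unique(phys$scaffold), function(sc) {
    sub <- phys[phys$scaffold == sc, , drop = FALSE]
    if (nrow(sub) < 2L) return(NULL)
    r2 <- suppressWarnings(stats::cor(G[, sub$marker, drop = FALSE],
                                      use = "pairwise.complete.obs"))^2
    ut <- which(upper.tri(r2), arr.ind = TRUE)
    data.frame(marker_a = sub$marker[ut[, 1]], marker_b = sub$marker[ut[, 2]],
               scaffold = sc,
               dist_bp = abs(sub$bp[ut[, 1]] - sub$bp[ut[, 2]]),
               r2 = r2[ut], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Per-linkage-group LD matrix (heatmap surface)
#'
#' Returns the symmetric r2 (or kinship-corrected r2_V) matrix for the
#' markers of one linkage group, ordered by cM position, with unit
#' diagonal — the surface plotted in LD heatmaps before/after kinship
#' correction.
#'
#' @param G genotype matrix.
#' @param map marker map.
#' @param lg linkage group label.
#' @param kinship optional kinship matrix; when given, r2_V via
#'   [r2v_matrix()] is returned instead of raw r2.
#' @return symmetric matrix with markers ordered by map position.
#' @export
ld_matrix <- function(G, map, lg, kinship = NULL) {
  sub <- map[map$linkage_group == lg & map$marker %in% colnames(G), ,
             drop = FALSE]
  if (nrow(sub) < 2L) stop("fewer than 2 mapped markers on linkage group ", lg)
  sub <- sub[order(sub$cM), ]
  Gl <- G[, sub$marker, drop = FALSE]
  if (is.null(kinship)) {
    R <- suppressWarnings(stats::cor(Gl, use = "pairwise.complete.obs"))^2
    diag(R) <- 1
  } else {
    R <- r2v_matrix(Gl, kinship)
  }
  R
}
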