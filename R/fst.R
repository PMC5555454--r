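#' Per-group allele counts for differentiation statistics
#'
#' For every marker and group: number of called diploid individuals `n`,
#' ALT allele frequency `p` (NA when no calls) and observed heterozygote
#' fraction `h`.
#'
#' @param G genotype matrix.
#' @param groups group assignment data.frame.
#' @param groups_used optional group labels to restrict to (order kept).
#' @return list of three markers x groups matrices: `n`, `p`, `h`.
#' @export
group_allele_counts <- function(G, groups, groups_used = NULL) {
  validate_groups(groups, G)
  labs <- if (is.null(groups_used)) unique(groups$group) else groups_used
  n <- p <- h <- matrix(NA_real_, ncol(G), length(labs),
                        dimnames = list(colnames(G), labs))
  for (k in seq_along(labs)) {
    acc <- groups$accession[groups$group == labs[k]]
    if (!length(acc)) stop("group has zero accessions: ", labs[k])
    sub <- G[acc, , drop = FALSE]
    nk <- colSums(!is.na(sub))
    n[, k] <- nk
    p[, k] <- ifelse(nk > 0, colSums(sub, na.rm = TRUE) / (2 * nk), NA_real_)
    h[, k] <- ifelse(nk > 0, colSums(sub == 1L, na.rm = TRUE) / nk, NA_real_)
  }
  list(n = n, p = p, h = h)
}

# coerce scalar/vector per-group input into 1-marker matrices
as_counts_matrices <- function(n, p, h) {
  if (is.null(dim(n))) {
    n <- matrix(n, 1); p <- matrix(p, 1); h <- matrix(h, 1)
  }
  list(n = unname(n), p = unname(p), h = unname(h))
}

#' Weir-Cockerham theta components (a, b, c) per marker
#'
#' Variance-component estimator of F_ST for r groups at a biallelic
#' marker. Groups with no calls or undefined frequency are dropped
#' marker-wise; markers with fewer than two usable groups, mean sample
#' size of 1, or a zero total variance (a + b + c = 0) are flagged
#' undefined (`NA` theta).
#'
#' @param n,p,h markers x groups matrices (or per-group vectors for a
#'   single marker) of sample sizes, ALT frequencies and observed het
#'   fractions, as from [group_allele_counts()].
#' @return data.frame with per-marker `a`, `b`, `c`, `theta`, `r`
#'   (usable groups).
#' @export
wc_fst_components <- function(n, p, h) {
  x <- as_counts_matrices(n, p, h)
  n <- x$n; p <- x$p; h <- x$h
  usable <- n >= 1 & !is.na(p)
  n <- ifelse(usable, n, 0)
  p <- ifelse(usable, p, 0)
  h <- ifelse(usable, ifelse(is.na(h), 0, h), 0)
  r <- rowSums(usable)
  N <- rowSums(n)                  # r * nbar
  nbar <- N / r
  nc <- (N - rowSums(n^2) / N) / (r - 1)
  pbar <- rowSums(n * p) / N
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / N
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) * s2 / r - (2 * nbar - 1) * hbar / (4 * nbar))
  cc <- hbar / 2
  bad <- r < 2 | nbar <= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
  data.frame(a = a, b = b, c = cc, theta = theta, r = r, row.names = NULL)
}

#' Weir-Cockerham theta (F_ST) per marker
#'
#' @inheritParams wc_fst_components
#' @return numeric vector of per-marker theta (negative estimates
#'   retained; `NA` where undefined).
#' @export
wc_fst <- function(n, p, h) {
  wc_fst_components(n, p, h)$theta
}

# unweighted H_S, H_T and usable group count per marker
hs_ht <- function(p, n) {
  if (is.null(dim(p))) { p <- matrix(p, 1); n <- matrix(n, 1) }
  p <- unname(p); n <- unname(n)
  usable <- n >= 1 & !is.na(p)
  k <- rowSums(usable)
  pu <- ifelse(usable, p, NA_real_)
  hs <- rowMeans(2 * pu * (1 - pu), na.rm = TRUE)
  pbar <- rowMeans(pu, na.rm = TRUE)
  ht <- 2 * pbar * (1 - pbar)
  hs[k < 2] <- NA_real_; ht[k < 2] <- NA_real_
  list(hs = hs, ht = ht, k = k)
}

#' Nei's G_ST per marker
#'
#' `G_ST = (H_T - H_S) / H_T` with `H_S` the unweighted mean within-group
#' He and `H_T` the He of the unweighted mean frequency. Undefined
#' (`NA`) when `H_T = 0` or fewer than 2 usable groups.
#'
#' @inheritParams wc_fst_components
#' @export
nei_gst <- function(n, p, h = NULL) {
  x <- hs_ht(p, n)
  ifelse(!is.na(x$ht) & x$ht > 0, (x$ht - x$hs) / x$ht, NA_real_)
}

#' Jost's D per marker
#'
#' `D = ((H_T - H_S) / (1 - H_S)) * k / (k - 1)` with `H_S`, `H_T` as in
#' [nei_gst()] and `k` the number of usable groups. Undefined when
#' `H_S = 1`.
#'
#' @inheritParams wc_fst_components
#' @export
jost_d <- function(n, p, h = NULL) {
  x <- hs_ht(p, n)
  ifelse(!is.na(x$hs) & x$hs < 1,
         (x$ht - x$hs) / (1 - x$hs) * x$k / (x$k - 1), NA_real_)
}

#' Per-SNP differentiation scan along the genetic map
#'
#' Computes Weir-Cockerham theta, Nei's G_ST, Jost's D, per-group He and
#' per-group ALT frequencies for every mapped marker, ordered by
#' (linkage group, cM) with a cumulative Manhattan-plot coordinate
#' (cM offset by the cumulative length of preceding linkage groups).
#' Markers monomorphic across the used groups are excluded (count in
#' attribute `n_monomorphic`); unmapped markers are reported in attribute
#' `unmapped`.
#'
#' @param G genotype matrix.
#' @param groups group assignment data.frame.
#' @param map marker map.
#' @param groups_used group labels to contrast (default: all).
#' @param exclude_groups labels dropped before the scan.
#' @return data.frame: `marker`, `linkage_group`, `cM`, `cum_pos`, `fst`,
#'   `gst`, `jost_d`, `n_groups_used`, one `he_<group>` and `p_<group>`
#'   column per group.
#' @export
fst_scan <- function(G, groups, map, groups_used = NULL,
                     exclude_groups = NULL) {
  labs <- if (is.null(groups_used)) unique(groups$group) else groups_used
  labs <- setdiff(labs, exclude_groups)
  if (length(labs) < 2L) stop("need at least 2 groups after exclusion")
  groups <- groups[groups$group %in% labs, , drop = FALSE]
  cnt <- group_allele_counts(G, groups, labs)
  comp <- wc_fst_components(cnt$n, cnt$p, cnt$h)
  gst <- nei_gst(cnt$n, cnt$p)
  d <- jost_d(cnt$n, cnt$p)
  scan <- data.frame(marker = colnames(G), fst = comp$theta, gst = gst,
                     jost_d = d, n_groups_used = comp$r,
                     stringsAsFactors = FALSE)
  for (g in labs) {
    scan[[paste0("p_", g)]] <- cnt$p[, g]
    scan[[paste0("he_", g)]] <- 2 * cnt$p[, g] * (1 - cnt$p[, g])
  }
  # monomorphic across used groups: pooled frequency 0 or 1
  pool <- rowSums(cnt$n * cnt$p, na.rm = TRUE) / rowSums(cnt$n, na.rm = TRUE)
  mono <- !is.na(pool) & (pool == 0 | pool == 1)
  unmapped <- scan$marker[!scan$marker %in% map$marker]
  scan <- scan[!mono & scan$marker %in% map$marker, , drop = FALSE]
  idx <- match(scan$marker, map$marker)
  scan$linkage_group <- map$linkage_group[idx]
  scan$cM <- map$cM[idx]
  lgs <- unique(map$linkage_group[order(map$linkage_group)])
  lg_len <- vapply(lgs, function(l) max(map$cM[map$linkage_group == l]),
                   numeric(1))
  offset <- stats::setNames(cumsum(c(0, utils::head(lg_len, -1))), lgs)
  scan$cum_pos <- scan$cM + offset[as.character(scan$linkage_group)]
  scan <- scan[order(scan$linkage_group, scan$cM), , drop = FALSE]
  rownames(scan) <- NULL
  first <- c("marker", "linkage_group", "cM", "cum_pos", "fst", "gst",
             "jost_d", "n_groups_used")
  scan <- scan[, c(first, setdiff(names(scan), first))]
  attr(scan, "n_monomorphic") <- sum(mono)
  attr(scan, "unmapped") <- unmapped
  scan
}

#' Multilocus multi-group F_ST
#'
#' The ratio-of-sums Weir-Cockerham estimate
#' `sum(a) / sum(a + b + c)` over all usable markers, with the simple mean
#' of per-marker theta reported alongside (the two summaries of "mean
#' F_ST" in common use).
#'
#' @param G genotype matrix.
#' @param groups group assignment data.frame.
#' @param exclude_groups optional labels to omit.
#' @return list: `multilocus` (ratio of sums), `mean_per_marker`,
#'   `n_markers` used.
#' @export
mean_multilocus_fst <- function(G, groups, exclude_groups = NULL) {
  labs <- setdiff(unique(groups$group), exclude_groups)
  if (length(labs) < 2L) stop("need at least 2 groups after exclusion")
  groups <- groups[groups$group %in% labs, , drop = FALSE]
  cnt <- group_allele_counts(G, groups, labs)
  comp <- wc_fst_components(cnt$n, cnt$p, cnt$h)
  use <- !is.na(comp$a) & !is.na(comp$theta)
  if (!any(use)) stop("no usable markers for multilocus F_ST")
  list(multilocus = sum(comp$a[use]) /
         sum(comp$a[use] + comp$b[use] + comp$c[use]),
       mean_per_marker = mean(comp$theta[use]),
       n_markers = sum(use))
}

#' One-way ANOVA of per-marker F_ST across linkage groups
#'
#' Fixed-effects one-way ANOVA of the scan's F_ST values grouped by
#' linkage group.
#'
#' @param scan data.frame from [fst_scan()].
#' @return list: `F`, `df` (length 2), `p_value`.
#' @export
anova_fst_by_lg <- function(scan) {
  scan <- scan[!is.na(scan$fst), , drop = FALSE]
  tab <- table(scan$linkage_group)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 linkage groups with >= 2 markers each")
  fit <- stats::lm(fst ~ factor(linkage_group), data = scan)
  av <- stats::anova(fit)
  list(F = av$`F value`[1], df = c(av$Df[1], av$Df[2]),
       p_value = av$`Pr(>F)`[1])
}

#' Empirical F_ST outlier flagging
#'
#' Flags markers whose F_ST reaches the stated empirical quantile of the
#' scan's F_ST distribution. This is a model-free, empirical flag — not a
#' neutrality test and not a posterior-based outlier model; reported
#' values carry that label.
#'
#' @param scan data.frame from [fst_scan()].
#' @param top_quantile empirical quantile (default 0.995); markers with
#'   `fst >= quantile(fst, top_quantile)` are flagged.
#' @return data.frame of flagged markers with `rank` (1 = highest F_ST)
#'   and the scan's per-group frequency columns; attribute
#'   `method = "empirical, not model-based"` and `threshold`.
#' @export
empirical_outliers <- function(scan, top_quantile = 0.995) {
  if (nrow(scan) == 0L) stop("empty scan")
  ok <- !is.na(scan$fst)
  thr <- stats::quantile(scan$fst[ok], probs = top_quantile, names = FALSE)
  out <- scan[ok & scan$fst >= thr, , drop = FALSE]
  out <- out[order(-out$fst), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "method") <- "empirical, not model-based"
  attr(out, "threshold") <- thr
  out
}
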