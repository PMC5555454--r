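# Small fixture builders and independent brute-force oracles used across
# the suite. Oracles are deliberately written as plain scalar loops,
# independent of the vectorised implementations they check.

toy_geno <- function(values, n_acc, acc = sprintf("acc%d", seq_len(n_acc)),
                     markers = NULL) {
  G <- matrix(as.integer(values), nrow = n_acc)
  if (is.null(markers)) markers <- sprintf("m%d", seq_len(ncol(G)))
  dimnames(G) <- list(acc, markers)
  G
}

random_geno <- function(n_acc, n_mark, missing_rate = 0.05, seed = 99) {
  set.seed(seed)
  p <- runif(n_mark, 0.1, 0.9)
  G <- sapply(p, function(pp) rbinom(n_acc, 2, pp))
  G[matrix(runif(n_acc * n_mark) < missing_rate, n_acc)] <- NA
  G <- matrix(as.integer(G), n_acc)
  dimnames(G) <- list(sprintf("a%03d", seq_len(n_acc)),
                      sprintf("m%03d", seq_len(n_mark)))
  G
}

# direct scalar transcription of the Weir & Cockerham (1984) a, b, c
oracle_wc_theta <- function(n, p, h) {
  use <- !is.na(p) & n >= 1
  n <- n[use]; p <- p[use]; h <- h[use]
  r <- length(n)
  if (r < 2) return(NA_real_)
  nbar <- sum(n) / r
  if (nbar <= 1) return(NA_real_)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

oracle_gst <- function(p) {
  hs <- 0
  for (pk in p) hs <- hs + 2 * pk * (1 - pk)
  hs <- hs / length(p)
  pbar <- sum(p) / length(p)
  ht <- 2 * pbar * (1 - pbar)
  if (ht == 0) return(NA_real_)
  (ht - hs) / ht
}

oracle_jost_d <- function(p) {
  k <- length(p)
  hs <- mean(sapply(p, function(pk) 2 * pk * (1 - pk)))
  pbar <- mean(p)
  ht <- 2 * pbar * (1 - pbar)
  if (hs == 1) return(NA_real_)
  (ht - hs) / (1 - hs) * k / (k - 1)
}

# naive O(n^3) agglomerative Ward (Lance-Williams on the raw
# dissimilarities); returns the cophenetic distance matrix
oracle_ward_cophenetic <- function(D) {
  n <- nrow(D)
  d <- as.matrix(D)
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- seq_len(n)
  coph <- matrix(0, n, n)
  while (length(active) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      ci <- active[i]; cj <- active[j]
      if (d[ci, cj] < bestd) { bestd <- d[ci, cj]; best <- c(ci, cj) }
    }
    ci <- best[1]; cj <- best[2]
    for (x in members[[ci]]) for (y in members[[cj]]) {
      coph[x, y] <- bestd; coph[y, x] <- bestd
    }
    for (ck in setdiff(active, best)) {
      ni <- sizes[ci]; nj <- sizes[cj]; nk <- sizes[ck]
      d[ci, ck] <- ((ni + nk) * d[ci, ck] + (nj + nk) * d[cj, ck] -
                      nk * bestd) / (ni + nj + nk)
      d[ck, ci] <- d[ci, ck]
    }
    members[[ci]] <- c(members[[ci]], members[[cj]])
    sizes[ci] <- sizes[ci] + sizes[cj]
    active <- setdiff(active, cj)
  }
  coph
}

# tiny mapped panel with two linkage groups for LD / scan tests
small_mapped_panel <- function(seed = 7, n_acc = 40, per_lg = 15) {
  set.seed(seed)
  G <- random_geno(n_acc, 2 * per_lg, missing_rate = 0.02, seed = seed)
  map <- data.frame(marker = colnames(G),
                    linkage_group = rep(1:2, each = per_lg),
                    cM = round(c(sort(runif(per_lg, 0, 50)),
                                 sort(runif(per_lg, 0, 50))), 2))
  list(G = G, map = map)
}
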