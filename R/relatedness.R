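#' Allele-sharing distance between accessions
#'
#' For accessions i and j, over markers called in both, each marker
#' contributes `2 - |g_i - g_j|` shared alleles out of 2; the distance is
#' one minus the fraction of shared alleles. Pairs with zero jointly
#' called markers get `NA` (flagged with a warning).
#'
#' @param G genotype matrix (at least 2 accessions).
#' @return symmetric n x n matrix with zero diagonal and attribute
#'   `kind = "distance"`.
#' @export
allele_sharing_distance <- function(G) {
  validate_genotypes(G)
  if (nrow(G) < 2L) stop("need at least 2 accessions")
  ibs <- ibs_matrix(G)
  D <- 1 - ibs
  diag(D) <- 0
  attr(D, "kind") <- "distance"
  D
}

#' Identity-by-state matrix
#'
#' Proportion of alleles shared between two accessions over jointly called
#' markers, without regard to allele frequencies:
#' `ibs = sum(2 - |g_i - g_j|) / (2 * n_shared)`. The diagonal is 1 by
#' definition. `ibs = 1 - allele_sharing_distance` on the same marker set.
#'
#' @param G genotype matrix.
#' @return symmetric n x n matrix, attribute `kind = "ibs"`.
#' @export
ibs_matrix <- function(G) {
  validate_genotypes(G)
  if (nrow(G) < 2L) stop("need at least 2 accessions")
  # |g_i - g_j| summed over markers via indicator cross-products:
  # |0-1| = |1-2| = 1, |0-2| = 2
  A0 <- (!is.na(G) & G == 0L) + 0
  A1 <- (!is.na(G) & G == 1L) + 0
  A2 <- (!is.na(G) & G == 2L) + 0
  M <- (!is.na(G)) + 0
  n_shared <- M %*% t(M)
  diffsum <- A0 %*% t(A1) + A1 %*% t(A0) + A1 %*% t(A2) + A2 %*% t(A1) +
    2 * (A0 %*% t(A2) + A2 %*% t(A0))
  ibs <- 1 - diffsum / (2 * n_shared)
  if (any(n_shared == 0)) {
    warning("some accession pairs share no called markers; IBS set to NA")
    ibs[n_shared == 0] <- NA_real_
  }
  diag(ibs) <- 1
  dimnames(ibs) <- list(rownames(G), rownames(G))
  attr(ibs, "kind") <- "ibs"
  ibs
}

#' Genomic kinship matrix (centered, standardised cross-product)
#'
#' Standardises each marker as `x = (g - 2p) / sqrt(2 p (1 - p))` with `p`
#' the ALT frequency on the full panel, sets missing entries to 0 after
#' centering (mean imputation), and returns `K = X X' / m` over the `m`
#' usable (polymorphic) markers. For fully inbred lines the diagonal is
#' close to 2 (1 + f with f near 1); for an outbred panel it is close
#' to 1.
#'
#' @param G genotype matrix; monomorphic markers (MAF 0 or no calls) are
#'   excluded since their standardisation is undefined.
#' @return symmetric n x n matrix, attribute `kind = "kinship"` and
#'   `n_markers` = number of markers used.
#' @export
kinship_matrix <- function(G) {
  validate_genotypes(G)
  p <- allele_freq(G)
  use <- !is.na(p) & p > 0 & p < 1
  if (!any(use)) stop("all markers monomorphic; kinship undefined")
  Gs <- G[, use, drop = FALSE]
  p <- p[use]
  X <- sweep(Gs, 2, 2 * p, `-`)
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), `/`)
  X[is.na(X)] <- 0
  K <- tcrossprod(X) / sum(use)
  attr(K, "kind") <- "kinship"
  attr(K, "n_markers") <- sum(use)
  K
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under the Ward criterion (Lance-Williams
#' update applied to the supplied dissimilarities, `stats::hclust`
#' method `"ward.D"`).
#'
#' @param D symmetric distance matrix (no `NA` off-diagonal entries).
#' @return an `hclust` object.
#' @export
ward_tree <- function(D) {
  if (any(is.na(D[upper.tri(D)])))
    stop("distance matrix has undefined pairs; Ward clustering needs all pairs")
  stats::hclust(stats::as.dist(D), method = "ward.D")
}

#' Export a dendrogram as newick
#'
#' Branch lengths come from the Ward merge heights; for display purposes
#' only (germplasm trees of this kind are customarily drawn not to scale).
#'
#' @param tree an `hclust` object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Thresholded IBS network
#'
#' Builds a graph whose nodes are accessions and whose edges connect pairs
#' with IBS strictly greater than `threshold`. Isolated nodes are
#' retained. IBS can be recomputed on a marker subset (e.g. markers
#' polymorphic within a taxon) via `markers`.
#'
#' @param G genotype matrix.
#' @param threshold IBS threshold (default 0.8); edges require
#'   `ibs > threshold`.
#' @param markers optional marker ids restricting the IBS computation.
#' @param groups optional group assignment; stored as a vertex attribute
#'   `group`.
#' @param ibs optional precomputed IBS matrix (ignored when `markers` is
#'   given).
#' @return an `igraph` graph with edge attribute `ibs`.
#' @export
ibs_network <- function(G, threshold = 0.8, markers = NULL, groups = NULL,
                        ibs = NULL) {
  if (!is.null(markers)) {
    if (!length(markers)) stop("marker subset is empty")
    unknown <- setdiff(markers, colnames(G))
    if (length(unknown)) stop("unknown markers in subset")
    ibs <- ibs_matrix(G[, markers, drop = FALSE])
  } else if (is.null(ibs)) {
    ibs <- ibs_matrix(G)
  }
  acc <- rownames(ibs)
  idx <- which(upper.tri(ibs) & !is.na(ibs) & ibs > threshold, arr.ind = TRUE)
  edges <- data.frame(from = acc[idx[, 1]], to = acc[idx[, 2]],
                      ibs = ibs[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = acc))
  if (!is.null(groups)) {
    lab <- groups$group[match(acc, groups$accession)]
    g <- igraph::set_vertex_attr(g, "group", value = lab)
  }
  attr(g, "threshold") <- threshold
  g
}

#' Write an IBS network as an edge list (and optionally GraphML)
#'
#' @param net igraph object from [ibs_network()].
#' @param edge_path TSV path for the `acc1 acc2 ibs` edge list.
#' @param graphml_path optional GraphML output path.
#' @export
write_network <- function(net, edge_path, graphml_path = NULL) {
  ed <- igraph::as_data_frame(net, what = "edges")
  names(ed) <- c("acc1", "acc2", "ibs")[seq_len(ncol(ed))]
  if (nrow(ed) == 0L)
    ed <- data.frame(acc1 = character(), acc2 = character(), ibs = numeric())
  utils::write.table(ed, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(net, graphml_path, format = "graphml")
  invisible(edge_path)
}
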