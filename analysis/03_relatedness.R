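#!/usr/bin/env Rscript
# Stage 3 — relatedness structure.
#
# Allele-sharing distance and IBS matrices, the genomic kinship matrix,
# a Ward dendrogram (newick) and the thresholded IBS network (edges at
# IBS > 0.8), including the network restricted to markers polymorphic in
# the wild-like group — the view that resolves structure hidden by
# ascertainment.

suppressPackageStartupMessages(library(germscan))
panel <- "results/panel"
out <- "results/relatedness"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

G <- read_genotypes(file.path(panel, "genotypes.tsv"))
groups <- read_groups(file.path(panel, "groups.tsv"), G)
Gf <- filter_snps(G)

D <- allele_sharing_distance(Gf)
write_matrix_tsv(D, file.path(out, "distance.tsv"))
write_matrix_tsv(1 - D, file.path(out, "ibs.tsv"))
K <- kinship_matrix(Gf)
write_matrix_tsv(K, file.path(out, "kinship.tsv"))
cat(sprintf("kinship diagonal mean %.2f (inbred lines sit near 2)\n",
            mean(diag(K))))

write_newick(ward_tree(D), file.path(out, "ward_tree.nwk"))

net <- ibs_network(Gf, threshold = 0.8, groups = groups, ibs = 1 - D)
write_network(net, file.path(out, "ibs_network_edges.tsv"),
              file.path(out, "ibs_network.graphml"))
cat(sprintf("IBS > 0.8 network: %d nodes, %d edges\n",
            igraph::vcount(net), igraph::ecount(net)))

wild <- groups$accession[groups$group == "wild"]
poly_wild <- colnames(Gf)[vapply(seq_len(ncol(Gf)), function(j) {
  g <- Gf[wild, j]; g <- g[!is.na(g)]
  length(g) > 0 && max(g) > 0 && min(g) < 2
}, logical(1))]
net_w <- ibs_network(Gf[wild, , drop = FALSE], threshold = 0.8,
                     markers = poly_wild,
                     groups = groups[groups$group == "wild", ])
write_network(net_w, file.path(out, "ibs_network_wildpoly_edges.tsv"))
cat(sprintf("wild-only network on %d wild-polymorphic markers: %d edges\n",
            length(poly_wild), igraph::ecount(net_w)))
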