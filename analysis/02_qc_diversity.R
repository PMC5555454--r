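#!/usr/bin/env Rscript
# Stage 2 — marker QC and per-group diversity.
#
# Applies the array-style marker filters (missing rate < 0.2, observed
# heterozygosity < 0.05, MAF >= 0.02), then summarises MAF spectra per
# group, joint allele-frequency histograms between group pairs, and mean
# expected heterozygosity with 50-replicate size-equalised resampling.

suppressPackageStartupMessages(library(germscan))
panel <- "results/panel"
out <- "results/diversity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

G <- read_genotypes(file.path(panel, "genotypes.tsv"))
groups <- read_groups(file.path(panel, "groups.tsv"), G)

summ <- snp_summary(G)
write_table(summ, file.path(out, "snp_summary.tsv"))
Gf <- filter_snps(G, max_missing = 0.2, max_het = 0.05, min_maf = 0.02)
cat(sprintf("markers: %d genotyped, %d after filters\n", ncol(G), ncol(Gf)))

hists <- lapply(c(total = NA, split(groups$accession, groups$group)),
                function(acc) maf_histogram(Gf, if (all(is.na(acc))) NULL else acc))
for (nm in names(hists)) hists[[nm]]$group <- nm
write_table(do.call(rbind, hists), file.path(out, "maf_histograms.tsv"))

he <- group_he(Gf, groups)
ref_n <- min(table(groups$group))
he$resampled_mean_He <- vapply(seq_len(nrow(he)), function(i)
  resampled_group_he(Gf, groups, he$group[i], ref_n, n_reps = 50,
                     seed = 100 + i)$resampled_mean_He, numeric(1))
write_table(he, file.path(out, "group_he.tsv"))
cat("mean He by group (resampled to equal n):\n")
print(he, row.names = FALSE)

pairs <- utils::combn(unique(groups$group), 2, simplify = FALSE)
jrows <- lapply(pairs, function(pr) {
  jh <- joint_maf_histogram(Gf, groups, pr[1], pr[2])
  data.frame(group_a = pr[1], group_b = pr[2],
             bin_a = rep(1:10, 10), bin_b = rep(1:10, each = 10),
             count = as.vector(jh$counts))
})
write_table(do.call(rbind, jrows), file.path(out, "joint_maf_histograms.tsv"))

for (g in unique(groups$group)) {
  n_poly <- polymorphic_count(Gf, groups$accession[groups$group == g])
  cat(sprintf("markers polymorphic within %s: %d of %d\n", g, n_poly,
              ncol(Gf)))
}
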