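#!/usr/bin/env Rscript
# Stage 1 — build the study panel.
#
# Simulates the default structured panel: three diverged groups (wild-,
# winter- and spring-like) of 100 near-homozygous lines each, ~2,000
# mapped SNPs on 7 linkage groups plus 10 planted outlier loci on LGs 5
# and 6 strongly differentiated between the winter- and spring-like
# groups. Writes the genotype table, consensus-style map, group labels
# and the simulation truth under results/panel/.

suppressPackageStartupMessages(library(germscan))
out <- "results/panel"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_panel(sim_config(seed = 1))

write_genotypes(sim$genotypes, file.path(out, "genotypes.tsv"))
write_map(sim$map, file.path(out, "map.tsv"))
write_groups(sim$groups, file.path(out, "groups.tsv"))
write_table(sim$truth$markers, file.path(out, "truth_markers.tsv"))

cat(sprintf("panel: %d accessions x %d markers on %d linkage groups\n",
            nrow(sim$genotypes), ncol(sim$genotypes),
            length(unique(sim$map$linkage_group))))
cat(sprintf("planted outlier loci: %d (LGs %s)\n",
            sum(sim$truth$markers$outlier),
            paste(unique(sim$truth$markers$linkage_group[
              sim$truth$markers$outlier]), collapse = ", ")))
cat(sprintf("missing-call rate: %.3f\n", mean(is.na(sim$genotypes))))
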