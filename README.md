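# germscan

Diversity, linkage-disequilibrium and differentiation scans for SNP-array
germplasm panels of inbred lines.

Breeders and population geneticists characterising a germplasm collection
— elite cultivars, landraces and wild relatives genotyped on a mapped SNP
array — routinely run the same sequence of analyses: marker quality
filters, allele-frequency spectra and gene diversity per genetic group,
relatedness matrices with dendrograms and identity-by-state (IBS)
networks, intra-chromosomal LD decay (and how much of it is mere kinship
structure), and a per-SNP differentiation scan along the genetic map to
find candidate regions under divergent selection. `germscan` packages
that sequence as tested, reusable functions, together with a synthetic
genotype generator that reproduces the statistical structure such panels
exhibit, so every estimator is validated against known truth.

## The statistics at the core

For a biallelic marker with ALT dosage g ∈ {0, 1, 2}:

- **MAF / He** — minor allele frequency min(p, 1−p) and Nei's expected
  heterozygosity He = 2p(1−p), computed within groups over called
  genotypes, with sample-size-equalising resampling (50 replicates) for
  fair between-group comparison.
- **Allele-sharing distance / IBS** — per pair of accessions, shared
  alleles per jointly called marker are 2 − |g_i − g_j|; distance is one
  minus the shared fraction, IBS its complement (frequency-free).
- **Kinship** — K = XXᵀ/m with x = (g − 2p)/√(2p(1−p)), missing set to 0
  after centring; diagonal ≈ 1 + f (≈ 2 for inbred lines).
- **r² and r²_V** — squared dosage correlation within linkage groups
  against cM (or bp) distance; r²_V whitens both dosage vectors with the
  inverse Cholesky factor of the kinship, projects out the whitened
  intercept and correlates the residuals — the GLS partial correlation
  that removes relatedness-driven LD. r²_V = r² exactly when K = I.
- **F_ST (Weir–Cockerham θ)** — variance-components a, b, c per marker;
  θ = a/(a+b+c); multilocus mean as the ratio of sums Σa/Σ(a+b+c).
- **Nei's G_ST and Jost's D** — (H_T − H_S)/H_T and
  [(H_T − H_S)/(1 − H_S)]·k/(k−1) from unweighted group means, D being
  the measure not bounded by within-group heterozygosity.
- **Empirical outliers** — markers at the top quantile (default 0.5%) of
  the scan's F_ST distribution, explicitly labelled "empirical, not
  model-based".

## Worked example

Simulate the default study panel — three diverged groups (wild-, winter-
and spring-like) of 100 near-homozygous lines, ~2,000 mapped SNPs on 7
linkage groups, drift F = 0.3, plus 10 planted outlier loci on LGs 5 and
6 differentiated between the winter- and spring-like groups — then filter
and scan it:

```r
library(germscan)

sim <- simulate_panel(sim_config(seed = 1))
G   <- filter_snps(sim$genotypes)      # missing < 0.2, het < 0.05, MAF >= 0.02

mean_multilocus_fst(G, sim$groups)$multilocus
#> [1] 0.3151021

scan    <- fst_scan(G, sim$groups, sim$map, groups_used = c("winter", "spring"))
flagged <- empirical_outliers(scan, top_quantile = 0.99)
planted <- sim$truth$markers$marker[sim$truth$markers$outlier]
sum(planted %in% flagged$marker)
#> [1] 10
```

The multilocus θ (0.315) recovers the simulated drift coefficient 0.3,
and all 10 planted outliers rank in the top 1% of the empirical F_ST
distribution. LD decays steeply with genetic distance within each group:

```r
acc  <- sim$groups$accession[sim$groups$group == "winter"]
G_ld <- filter_snps(sim$genotypes[acc, ], 0.2, 0.05, 0.05)
prof <- ld_decay_profile(intra_lg_ld(G_ld, sim$map), bin_width = 0.5)
prof$median[prof$bin_lo %in% c(0, 5)]
#> [1] 0.07291667 0.03099485
```

The median r² falls from 0.073 below 0.5 cM to 0.031 at 5 cM. The
numbered scripts under `analysis/` run the full sequence on this panel
(simulation, QC + diversity, relatedness, LD, F_ST scan) and write their
tables under `results/`; `run_pipeline()` does the same from a single
config with a checksummed output manifest.

Real data enter through `read_genotypes()` (delimited table or biallelic
VCF), `read_map()` (marker, linkage group, cM, optional scaffold/bp) and
`read_groups()`.

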