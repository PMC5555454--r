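---
title: "Diversity, LD and differentiation scans for SNP-array germplasm panels"
author: "germscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity, LD and differentiation scans for SNP-array germplasm panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`germscan` implements the analysis sequence commonly applied to a large
germplasm collection of a selfing crop genotyped on a mapped SNP array:
marker quality control, allele-frequency spectra and gene diversity per
genetic group, relatedness matrices with dendrograms and identity-by-state
(IBS) networks, intra-chromosomal linkage disequilibrium (LD) decay with a
kinship-corrected variant, and a per-SNP differentiation scan along the
genetic map. It also ships a synthetic genotype generator that reproduces
the statistical structure these analyses assume, so every stage can be
exercised — and its estimators validated against known truth — without any
external data.

The intended substrate is a dosage matrix (accessions × biallelic markers,
entries 0/1/2/NA counting an arbitrarily designated ALT allele), a marker
map (linkage group and cM position, optionally scaffold and bp), and a
group assignment (e.g. wild/landrace vs winter-sown vs spring-sown
material). Every statistic in the package is invariant under the
orientation flip `g -> 2 - g`, so which allele is called ALT is
immaterial; this is tested as a property.

## Marker quality control

`snp_summary()` computes, per marker over called genotypes: missing rate,
observed heterozygosity (fraction of dosage-1 calls), ALT frequency and
MAF. `filter_snps()` discards markers with missing rate ≥ `max_missing`
(default 0.2) or heterozygosity ≥ `max_het` (default 0.05 — in a
predominantly selfing crop a heterozygous cluster usually signals a
paralogous or failed assay rather than true heterozygosity), and keeps
markers with MAF ≥ `min_maf`. Two filtered views of one input are used
downstream, as is standard for this analysis sequence: MAF ≥ 0.02 for
structure/diversity work and MAF ≥ 0.05 for LD, where rare alleles make
r² unstable. Thresholds are read strictly ("discard at ≥"), which is
documented and configurable.

## Diversity

Gene diversity is Nei's expected heterozygosity He = 2p(1−p) from
within-group frequencies over called genotypes; no small-sample correction
is applied by default since the plain estimator is the conventional report
for array panels of inbred lines. Because groups differ in size,
`resampled_group_he()` re-estimates a group's mean He from repeated
subsamples of a reference size (50 replicates by default), which separates
genuine diversity differences from sample-size artefacts.

MAF spectra use 20 equal-width bins on [0, 0.5]; markers monomorphic
within a subset are kept at MAF 0, because the excess of rare and absent
alleles in wild material *is* the signal of interest under array
ascertainment. The joint allele-frequency histogram between two groups
bins, by default, the within-group frequency of the *globally minor*
allele on a 10 × 10 grid. Per-group MAF is not a consistent allele across
groups — a marker can have different minor alleles in two groups — so
binning per-group MAF (available via `axis = "per_group_maf"`) folds the
distribution and weakens the between-group correlation signal the plot is
meant to show. Bin counts are configurable; bin indices are computed by
`floor(f * n_bins)` so boundary frequencies bin identically everywhere.

## Relatedness

The allele-sharing distance between two accessions is one minus the
proportion of shared alleles over jointly called markers
(`2 − |g_i − g_j|` shared per marker out of 2); IBS is its complement,
computed without reference to allele frequencies. The genomic kinship is
the cross-product of the centred, standardised genotype matrix
(`x = (g − 2p)/sqrt(2p(1−p))`, missing set to 0 after centring, i.e. mean
imputation) divided by the marker count. Mean imputation is used here —
and only here — because the matrix product needs complete data; distance
and IBS use pairwise-complete markers instead, matching their pairwise
definitions. Standardisation frequencies come from the full analysis
panel, not per group. For fully inbred lines the kinship diagonal sits
near 2 (1 + f with f ≈ 1); this is expected, not an error.

Dendrograms use the Ward criterion (`hclust` method `"ward.D"`, the
Lance–Williams update on the supplied dissimilarities) and export to
newick; merge heights are cosmetic, as germplasm trees of this kind are
customarily displayed not to scale. The test suite checks the merge
structure against an independent naive O(n³) Ward implementation. IBS
networks connect accessions with IBS strictly above a threshold (default
0.8) and can be recomputed on a marker subset — e.g. markers polymorphic
within a wild taxon — which is the standard device for resolving structure
that ascertainment hides.

## Linkage disequilibrium

r² is the squared Pearson correlation of dosages over pairwise-complete
accessions. This genotypic r² coincides with the haplotype r² when lines
are (near-)fully inbred, which is the intended regime; no phasing or EM
reconstruction is attempted. Pairs are formed within linkage groups only,
distances are |ΔcM|, and decay profiles report the median and the 5–95%
quantiles (5% steps) in fixed-width bins (default 0.5 cM; the bin width is
a package choice, not an external prescription) with bins under 10 pairs
suppressed. Zero-variance or all-missing pairs yield NA and are excluded
from profiles. For markers sharing a scaffold with bp coordinates,
`physical_ld()` produces the same statistic against physical distance.

The kinship-corrected r²_V is the squared GLS partial correlation: the
kinship restricted to the accessions complete at both markers is
Cholesky-factorised, both dosage vectors are whitened by the inverse
factor, the *whitened intercept* (not the arithmetic mean) is projected
out, and the residuals are correlated. With an identity kinship this
reduces exactly to r² (tested to 1e-10). If the restricted kinship is not
positive definite a ridge of 1e-6 is added once. `r2v_matrix()` is a
whole-matrix fast path that mean-imputes missing dosages and whitens once;
it is exact for complete data and deviates from the per-pair
complete-case `r2v()` only through the imputation.

## Differentiation scan

Per SNP, the scan reports the Weir–Cockerham variance-components estimator
θ (the default F_ST), Nei's G_ST and Jost's D, with per-group He and
frequencies, ordered by map position with a cumulative Manhattan
coordinate. G_ST and D use unweighted group means (H_S = mean 2p_k(1−p_k),
H_T from the unweighted mean frequency; D additionally scales by
k/(k−1)). Negative per-marker θ estimates are retained in scans and means
— clipping is a display decision, not an estimation one. Markers
monomorphic across the used groups are excluded with a logged count.

"Mean F_ST" is reported two ways, because the phrase is ambiguous in
common usage: the multilocus ratio-of-sums Σa / Σ(a+b+c) (the default
headline number) and the simple mean of per-marker θ. A one-way
fixed-effects ANOVA of per-marker F_ST by linkage group tests for
heterogeneity along the genome.

Outlier flagging is deliberately empirical: markers at or above a stated
quantile of the scan's F_ST distribution (default 0.995) are flagged, and
the output is labelled "empirical, not model-based". A posterior-based
neutrality model is out of scope here; the empirical flag is a transparent
substitute whose behaviour is fully determined by the scan itself, and it
should be read as a ranking device, not a significance test.

## The synthetic panel generator

`simulate_panel()` produces genotypes, map, group labels and truth records
from one seed, drawing in a fixed documented order so identical configs
reproduce identical panels. The model, chosen to yield the structure the
analyses assume at desk scale rather than to claim demographic realism:

1. Ancestral frequencies are uniform on a configurable range (default
   0.05–0.95, array-like: very rare alleles are under-represented on
   genotyping arrays by construction).
2. Group frequencies follow the Balding–Nichols Beta distribution around
   the ancestral frequency with per-group drift F.
3. Founder pools (default 8 haplotypes per group) are allocated by
   *stratified rounding*: each locus gets `round(K·p)` ALT copies on
   random founders. An iid Bernoulli pool would superimpose a second
   bottleneck of variance ≈ p(1−p)/K on the drawn drift and an atom of
   chance fixations; stratified allocation keeps the realized group
   divergence equal to `drift_F` (at the cost of quantising group
   frequencies to multiples of 1/K), so the drift parameter means what it
   says when the estimators are validated against it.
4. Each sample haplotype copies founders in a mosaic along each linkage
   group, with breakpoints from a Poisson process (default 0.1
   switches/cM). Fewer founders and fewer switches give stronger,
   longer-range LD; the resulting decay is approximately exponential in
   cM, which is all the LD machinery needs.
5. Lines self with probability `inbreeding_prob` (default 0.98 — the
   second haplotype duplicates the first), residual heterozygous calls are
   injected at 0.2%, and calls are masked missing at 3%.
6. Planted outlier loci displace the designated group pair symmetrically
   by ±sqrt(F_pair·p(1−p)) around a mid-range ancestral frequency (sign
   random). This realizes the target between-pair differentiation
   (G_ST = F_pair exactly at the frequency level) *reliably*; an
   independent Balding–Nichols redraw at the outlier F would make the
   realized divergence a heavy-tailed random variable that is frequently
   near zero, defeating the purpose of planting recoverable outliers.
   With a small founder pool the displacement quantises to the nearest
   pool frequency, so realized outlier differentiation lands at or
   slightly above the target.
7. Optional ascertainment drops loci whose pooled MAF in the
   cultivated-like groups falls below a threshold, reproducing the
   wild-group excess of rare/absent alleles and its depressed He that
   discovery-panel bias causes in real arrays.
8. Physical coordinates group consecutive markers into scaffolds of fixed
   genetic span (default 1 cM) at 5.6 Mb/cM, the genome-scale arithmetic
   for a ~4.45 Gb genome on a ~800 cM map.

Default sizes — 3 groups × 100 lines, 7 linkage groups × 286 markers
(~2,000 loci) + 10 outliers, drift F = 0.3 — are the conditions under
which the suite validates parameter recovery: the multilocus θ recovers
F = 0.3 within ±0.03 across seeds, planted outliers are recovered at the
top 1% of the empirical F_ST distribution, and the median r² falls
strictly from the sub-0.5 cM bin to the 5 cM bin. These sizes are the
package's default study conditions; larger panels (full-array scale) are
reachable through the config.

What the generator does *not* emulate: admixture and gene flow between
groups, realistic recombination-rate variation along chromosomes,
genotyping error beyond a uniform residual-het rate, and linked selection.
Passing tests on this generator therefore demonstrate estimator
correctness and pipeline behaviour under the stated model, not robustness
to every feature of real germplasm data.

## Numerical choices and degenerate inputs

- Markers with no calls are flagged, never silently dropped mid-statistic;
  frequencies are NA and excluded where undefined.
- Accession pairs with zero jointly called markers get NA distance/IBS
  with a warning.
- θ is NA when fewer than two usable groups remain, when the mean sample
  size is 1, or when a + b + c = 0; H_T = 0 makes G_ST NA; H_S = 1 makes
  D NA.
- Quantiles use the default type-7 definition of `stats::quantile`.
- Cholesky failure in r²_V triggers one ridge regularisation (1e-6), then
  an error — never a silent pseudo-inverse.
- Ties in Ward clustering follow `stats::hclust`; test matrices are
  generated tie-free.

## Pipeline and provenance

`run_pipeline()` executes the stages in dependency order from one config
(either file inputs or a simulation config — exactly one), with stage
toggles, and writes a `manifest.json` listing every output file with its
MD5 checksum, the thresholds, the seed and the accession/marker counts
after each filter view, so any run can be audited and reproduced
byte-for-byte. The numbered scripts under `analysis/` are thin narrative
drivers over the same functions and write their tables under `results/`;
`scripts/acceptance.R` recomputes the headline quantities from scratch on
the default panel for a given seed.

## Known limitations

- The empirical outlier flag has no error-rate control; it ranks, it does
  not test.
- Genotypic r² understates haplotype r² in the presence of real
  heterozygosity; the package targets near-inbred panels.
- The kinship-corrected whole-matrix fast path mean-imputes missing data;
  for exact complete-case semantics use the per-pair function.
- Group labels are an input: inferring them (model-based clustering,
  discriminant analysis) is outside the package's scope.
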