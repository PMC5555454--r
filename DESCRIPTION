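Package: germscan
Title: Diversity, Linkage Disequilibrium and Differentiation Scans for SNP
    Array Germplasm Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing biallelic SNP genotype matrices from
    germplasm collections of inbred lines: marker quality filters
    (missing rate, heterozygosity, minor allele frequency), allele
    frequency spectra and Nei's expected heterozygosity with
    sample-size-equalising resampling, allele-sharing distance, IBS and
    genomic kinship matrices with Ward dendrograms and thresholded IBS
    networks, intra-linkage-group linkage disequilibrium decay profiles
    (r2) with a kinship-corrected r2 (GLS whitening), per-SNP
    differentiation scans (Weir-Cockerham theta, Nei's G_ST, Jost's D)
    along a genetic map with empirical outlier flagging, and a
    Balding-Nichols founder-mosaic genotype simulator that reproduces the
    statistical structure such panels exhibit (diverged groups of inbred
    lines, distance-decaying LD, ascertainment bias, planted outlier
    loci).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
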