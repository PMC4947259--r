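Package: sibscan
Title: Marker-Trait Association in Full-Sib Families from Genotyping-by-Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-marker association analysis for forage-grass full-sib
    families genotyped by sequencing. Simulates pair-cross families with
    map-based meiosis, QTL-driven heading-date phenotypes and an ordinal
    aftermath-heading score; filters variants by genotype quality, mapping
    quality, presence and minor allele frequency; selects pseudo-testcross
    markers segregating 1:1 with a chi-square check; runs per-family
    Kruskal-Wallis scans with Benjamini-Hochberg q-values; estimates
    linkage-disequilibrium decay by maximum-likelihood haplotype
    frequencies from unphased diplotypes; performs mixed-linear-model
    genome-wide association with a kinship matrix and principal components;
    and anchors markers to a genetic linkage map through a genome-zipper
    table with median-statistic heatmap binning. Phenotype statistics
    (variance components, line-mean heritability, conditional means) use
    'lme4'.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
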