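Package: pedQTL
Title: Pedigree-Based Association Mapping and QTL Validation for Inbred
    Breeding Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dissects quantitative trait loci in small, highly related
    inbred breeding panels, as used for milling-quality traits in hexaploid
    wheat. Provides variance-component phenotype analysis with broad-sense
    heritability, a kinship mixed-linear-model association scan with a
    binary kernel-type covariate and Storey q-value control of the false
    discovery rate, map-based grouping of marker-trait associations into
    QTLs, linkage-disequilibrium block detection, pedigree tracing of QTL
    origin by haplotype-block similarity, conversion of array SNPs into
    genome- plus allele-specific PCR assays for polyploids with in-silico
    PCR verification, and validation in doubled-haploid populations via
    allele-mean t-tests and multi-marker regression prediction. A
    synthetic breeding-population generator (pedigree meiosis under the
    Haldane model, multi-environment phenotypes, doubled haploids,
    homoeologous contig triplets) makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    ape,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
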