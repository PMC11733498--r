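Package: haploscan
Title: Haploblock Discovery and Parallel-Adaptation Scans from Population Genotype Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and genotypes large structural-variant haploblocks
    (chromosomal inversions and related rearrangements) from diploid genotype
    matrices via windowed local principal component analysis and
    multidimensional scaling, validates calls with heterozygosity and linkage
    disequilibrium diagnostics, and tests haploblock frequency clines along
    latitude against a random-SNP empirical null. Companion genome scans
    compute moment-based whitened differentiation (XtX surrogate) and
    group-contrast statistics, Kendall tau environment associations, Fay and
    Wu's H, and covariate-adjusted trait associations, aggregated into
    nonoverlapping windows with the weighted-Z analysis; enrichment
    statistics quantify haploblock involvement among outlier windows.
    Degeneracy-aware genetic-load estimation classifies coding sites as
    zero-fold or four-fold degenerate and summarises derived-allele
    frequencies with a site-subsampling bootstrap. A synthetic-data module
    generates multi-population samples along a latitudinal gradient with
    planted haploblocks, traits, and toy coding genes so that every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
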