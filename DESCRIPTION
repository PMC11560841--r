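Package: sc3dmulti
Title: Single-Cell 3D Genome and DNA Methylome Analysis on Simulated
    snm3C-seq Cohorts
Version: 0.1.0
Authors@R:
    person("sc3dmulti", "Developers", email = "sc3dmulti@example.org",
           role = c("aut", "cre"))
Description: Joint analysis of single-cell chromatin conformation and DNA
    methylation profiles of the kind produced by snm3C-seq. Implements
    contact-distance decay classification of cells (short- versus long-range
    enriched conformations), random-walk imputation of per-cell contact
    matrices, pseudobulk summary-statistic loop calling with an empirical
    FDR against diagonal-shuffled backgrounds, ANOVA-based differential
    loops, super-interactive promoters, insulation-score domain boundaries
    and chi-square differential boundaries, A/B compartment eigenvectors
    with saddle compartmentalization strength, methylation feature matrices
    with coverage-based imputation, 3C gene scores, meta-cell construction
    and loop-versus-methylation cross-correlation lag analysis, and
    regulatory overlap statistics (motif enrichment, fine-mapped variant
    overlap, SNP-gene linking). Ships a deterministic synthetic-data
    generator that emulates snm3C-seq-like cohorts with planted loops,
    boundaries, compartments and methylation dynamics so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
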