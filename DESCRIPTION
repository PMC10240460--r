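Package: breedsig
Title: Discovery of Breed-Specific Genetic Signatures from Multi-Sample VCFs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide discovery of breed-enriched and breed-specific
    genetic signatures in multi-breed cohorts. Starting from a jointly
    called, annotated multi-sample VCF and a sample-to-breed panel, the
    package computes per-breed homozygous-carrier frequencies (breed
    variant frequency, BVF) for SNPs, short INDELs and short tandem
    repeats (STRs), scans both allele orientations for fixed signatures,
    types STR loci by repeat-unit decomposition and two-group k-means,
    aggregates signatures into gene hotspots, high-density stretches,
    multi-type breed-specific structures and 10-kb block summaries,
    derives breed similarity matrices and per-dog breed composition, and
    ships a planted-truth cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
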