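Package: strandinv
Title: Bayesian Genotyping and Phasing of Inversions from Strand-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genotypes and phases genomic inversions at user-supplied
    coordinates from single-cell Strand-seq libraries. Builds directional
    composite read sets (a Watson-Watson composite and a phased
    Watson-Crick composite), estimates the background rate of
    mis-oriented reads by the mode of a kernel density estimate over
    genomic bins, and scores each putative inversion with a Bayesian
    binomial mixture over four genotypes (REF, the two heterozygote
    phases, and HOM) and three error states (no error, always-WC, and
    missing/deletion). Also provides prior construction from genotype
    frequencies or from the self-overlap structure of an inversion
    catalogue, simplified de novo strand-switch discovery, deltaW-based
    breakpoint adjustment with re-genotyping, trio Mendelian-concordance
    accounting, and a seeded Strand-seq simulator so the whole pipeline
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
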