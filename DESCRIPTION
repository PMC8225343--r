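Package: episfs
Title: Epiallele Site-Frequency Spectra and Selection on Gene Body Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-epigenetic analysis of gene body methylation (gbM).
    Calls cytosine methylation from bisulfite count tables with a binomial
    test against the bisulfite no-conversion rate, classifies gene-by-accession
    methylation states (gbM, UM, mCHG, mCHH) against genome-wide coding-sequence
    background, infers ancestral gene states from outgroup methylomes, builds
    hypergeometric-projected unfolded site-frequency spectra of gene and
    cytosine epialleles, and fits a mutation-selection-drift stationary model
    (confluent-hypergeometric sampling distribution) by random-walk MCMC to
    estimate epimutation rates and the population-scaled selection coefficient
    4*Ne*s acting on methylation state. Also tests the association between
    epiallelic methylation state and gene expression with mixed models,
    permutation calibration, paired median and coefficient-of-variation
    comparisons. A synthetic-data module generates bisulfite count tables,
    annotations, state matrices and expression counts with the statistical
    structure the analysis assumes, so the full pipeline runs offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    lme4,
    emmeans,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
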