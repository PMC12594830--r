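Package: thioacetylome
Title: Quantitative Analysis of the Labile Cysteine S-Acetylome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for label-free quantitative proteomics of thioester-linked
    cysteine S-acetylation. Parses peptide-level quantification tables with
    modification-site annotations, normalizes peptide abundances to parent
    proteins, fits blocked linear-model contrasts with consensus within-block
    correlation and empirical-Bayes variance moderation, classifies
    reducing-agent lability (TCEP versus DTT) and acetyl-CoA dose-response
    behaviour of individual sites, performs Fisher overrepresentation and
    preranked permutation gene-set enrichment analysis, and provides
    multivariate summaries (PCA, correlation-distance average-linkage
    clustering, row z-scores). A seeded synthetic-acetylome generator with
    named scenario presets reproduces the statistical structure each analysis
    stage assumes, so the full pipeline is testable without raw mass
    spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
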