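Package: neolus
Title: Texture-Based Classification of Neonatal Lung Ultrasound Pathologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying the six most common
    neonatal lung pathologies (Normal, TTN, PTX, RDS, CLD, CON) from
    B-mode lung-ultrasound frames. Images are cleaned and normalized,
    decomposed with a five-level 2D dual-tree complex wavelet transform,
    and summarized by statistical, grey-level co-occurrence, grey-level
    run-length and local-binary-pattern texture features computed on the
    top and bottom halves of every sub-image. Image features are fused
    with three clinical covariates (gestational age, cumulative
    gestational age at scan, days of life), ranked by per-fold chi-square
    tests and classified with a regularized linear discriminant model
    under leave-one-out and leave-one-subject-out cross-validation.
    Because clinical neonatal data are access-restricted, the package
    ships a seeded speckle-phantom generator that emulates the canonical
    lung-ultrasound morphologies (pleural line, A-lines, separate and
    coalescent B-lines, consolidation, double lung point) so the whole
    pipeline can be exercised and validated on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
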