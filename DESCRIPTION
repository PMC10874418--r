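Package: somperturb
Title: Self-Organizing Map Transcriptome Portraits and Gaussian-Process
    Perturbation-Time Inference for Age-Structured Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for age-structured case/control expression
    cohorts: nuisance-covariate residualization and gene centering,
    self-organizing map (SOM) expression portraits, segmentation of
    co-expressed gene modules (spots) from summary maps, gene-set Z-score and
    Fisher overrepresentation annotation, per-age-group differential
    expression, Gaussian-process branch-point inference of the age at which a
    module's disease trajectory diverges from the control trajectory, and
    eQTL tissue enrichment of perturbed modules. Includes a synthetic cohort
    generator with planted co-expressed modules and perturbation times for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
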