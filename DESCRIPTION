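Package: crossisc
Title: Inter-Subject Correlation Analysis with Crossed Random Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for group analysis of naturalistic-viewing
    fMRI through inter-subject correlation (ISC). Quantifies head motion as
    framewise displacement and applies volume censoring and run-level
    exclusion; builds a single nuisance regression (polynomial trends,
    band-stop frequency regressors implementing a retention band, demeaned
    motion parameters and their derivatives, tissue signals, and an optional
    attention-control regressor); smooths per-node data on a triangulated
    surface mesh; computes per-node pairwise Fisher-z ISC matrices; fits
    crossed random-effects linear mixed models by restricted maximum
    likelihood for within-group synchrony, between-group contrasts, and
    child-to-adult neural maturity as a function of age, with Satterthwaite
    degrees of freedom; and controls familywise error by Monte Carlo
    simulation of maximum cluster extent on the mesh. Includes a synthetic
    cohort generator with a closed-form expected-ISC oracle so the full
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
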