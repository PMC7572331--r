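Package: conncpm
Title: Connectome-Based Predictive Modelling of Behavioural Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Connectome-based predictive modelling (CPM) of continuous
    behavioural scores (e.g. full-scale and verbal IQ) from functional
    connectivity matrices.  Implements per-edge association screening with
    Huber robust regression, sign-split positive/negative network summary
    scores, univariate linear prediction under leave-one-out
    cross-validation, and normalized-rank identification of the edges most
    consistently associated with the score.  Includes a seeded synthetic
    connectome-cohort generator with planted signal edges for calibration
    and power studies, and readers/writers for plain-text connectome and
    cohort manifest formats with AAL-116 region labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
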