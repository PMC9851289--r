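Package: tsrval
Title: Validation of Transcriptome Signature Reversion for Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether transcriptome signature reversion
    (TSR) predicts drug potency against specific tumor types. Estimates
    each drug's mean normalized dose-response AUC (mnAUC) with a crossed
    random-intercept REML model, builds per-gene drug perturbation
    signatures from long-format expression experiments and combines
    timepoints by random-effects meta-analysis, removes the
    viability-driven component of the signatures by per-gene regression
    on log mnAUC, derives tumor-versus-normal signatures from count
    matrices with upper-quartile normalization and precision-weighted
    moderated statistics, scores drugs against tumor signatures with
    KS-based connectivity (reversal) scores in both the original and the
    non-zeroing variant, and quantifies how much reversal scores explain
    of drug potency per tumor type. Includes a synthetic-data generator
    that plants a viability-response gene program for recovery testing,
    and a pipeline runner with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    metafor,
    edgeR,
    jsonlite
Config/testthat/edition: 3
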