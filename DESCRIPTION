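Package: tractconcord
Title: Histology-Informed Concordance Evaluation of Short-Range Prefrontal Tractography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate short-range (U-fiber) prefrontal tractography
    against the non-human-primate tract-tracing literature. Encodes the 14
    Brodmann-area / 5-partition prefrontal scheme and its 91-pair histological
    ground-truth matrix, classifies reconstructed bundles with
    population-prevalence rules (robust true positive, true positive, true
    negative, false positive, false negative), and derives concordance
    statistics overall and per partition. Includes a streamline data model
    with TRK/TCK/NIfTI readers and writers, bundle geometry and comparison
    metrics (arc length, length filtering, streamline density maps, outlier
    rejection, weighted Dice, bundle adjacency), a rule-based plausibility
    scorer, and a synthetic bundle simulator for cohort and scan-rescan
    studies.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
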