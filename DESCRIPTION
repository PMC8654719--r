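Package: esbench
Title: Empirical Effect-Size Benchmarks and Power Analysis for
    Clustered Meta-Research Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deriving field-specific small/medium/large
    effect-size benchmarks from effect sizes extracted out of
    meta-analyses, with an end-to-end pipeline: Cohen's d / Hedges' g
    harmonization, rule-based data cleaning with auditable counts,
    percentile benchmarks with distribution-shape descriptives,
    cluster-robust and clustered-bootstrap regression of effect
    magnitude on study-level correlates, exact noncentral-t power and
    sample-size calculations for paired and independent designs, and
    z-based statistical-power profiles of meta-analyses across a grid
    of plausible true effects. Includes a clustered synthetic-data
    generator with closed-form ground truth so every stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    sandwich,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
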