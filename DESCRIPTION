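Package: pepset
Title: Peptide-Centric Differential Protein Expression via Competitive
    Peptide Set Tests
Version: 0.1.0
Authors@R:
    person("pepset", "developers", email = "pepset@example.org",
           role = c("aut", "cre"))
Description: Infers differentially expressed proteins directly from
    peptide-level quantitation. Fits per-peptide linear models with
    empirical-Bayes moderated t-statistics, estimates the common
    within-protein inter-peptide correlation by a mixed-model variance
    component method, and tests each protein's peptide set against the
    rest of the peptidome with a correlation-adjusted two-sample t-test
    using either a standard-deviation or a robust scaled-MAD background
    scale. Also provides aggregation-based comparator workflows
    (summation and robust-regression rollup followed by protein-level
    moderated t-tests), a peptidome simulator for Type I error, power,
    FDR and TPR benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    lme4,
    limma,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
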