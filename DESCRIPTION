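Package: livdevscreen
Title: Liver-Development Gene Screens for HCV Cirrhosis and Hepatocellular Carcinoma Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A knowledge-driven expression-screening pipeline for HCV-cirrhosis
    and HCV-induced hepatocellular carcinoma microarray cohorts. Implements
    probe-level background correction and distribution-free normalization by
    regression on probe technical covariates (GC content, melting temperature,
    probe position) as a robust alternative to quantile normalization; a
    combined mean-variance (Welch t plus variance-F, Fisher-combined)
    differential-expression screen over curated liver-development gene sets
    with expression-pattern classification; one-sided Kolmogorov-Smirnov
    expressed-above-background calls for genes silent in normal liver and
    two-sample K-S contrasts of liver genes against their non-liver paralogs;
    a marker-panel set-cover coverage statistic for the BMP-inhibitor panel;
    and scaled principal-components discrimination with cross-cohort loading
    projection and leave-one-out cross-validated ROC. A fully seeded synthetic
    probe-level cohort generator with planted ground truth emulates the study
    design (12 normal, 30 cirrhosis, 31 early and 18 late tumor samples) so
    every stage is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    limma,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
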