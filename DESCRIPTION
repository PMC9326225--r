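Package: chdtriage
Title: Case-Only Genetic Diagnosis Pipeline for Congenital Heart Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a case-only genetic-diagnosis workflow for congenital
    heart disease (CHD) cohorts profiled by combined whole-exome and
    low-coverage whole-genome sequencing. Provides an ACMG/AMP
    evidence-combination classifier driven by a swappable rule table,
    technical and inheritance-consistency triage of small variants against a
    curated gene panel, five-tier copy-number-variant triage with aneuploidy
    promotion and mosaic-fraction reporting, five-category per-sample
    etiology assignment, diagnostic-yield statistics (Agresti-Coull binomial
    confidence intervals, Fisher-exact conditional-MLE odds ratios,
    recurrence tables, a landscape matrix), candidate-gene prediction by
    high-confidence interaction with the panel, and a synthetic-cohort
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    withr
Config/testthat/edition: 3
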