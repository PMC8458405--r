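Package: oppti
Title: Outlier Protein and Transcript Overexpression Detection in Omics Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects markers (proteins, phosphosites, or transcripts)
    overexpressed in subsets of tumors within quantitative omics cohorts.
    For every marker a background expression level is inferred per sample
    from its k nearest co-expressed neighbors; the signed perpendicular
    distance of each sample from the observed-versus-inferred regression
    line is the dysregulation score, thresholded at the 95th percentile of
    scores from non-dysregulated background markers selected by a
    Kolmogorov-Smirnov criterion. Cohort-level enrichment of overexpression
    events is assessed by within-sample score permutation with
    Benjamini-Hochberg correction. Also provides per-sample pathway
    activity scoring via one-sided Kolmogorov-Smirnov tests, cross-cohort
    classification rules, a synthetic-cohort simulator, and a benchmarking
    harness with univariate comparator methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    optparse,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
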