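Package: scna
Title: Structural Covariance Network Analysis of Regional Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Group-level structural covariance network analysis for regional
    brain morphometry. Builds Pearson structural covariance graphs per group
    from subjects-by-regions tables of cortical thickness, surface area, mean
    curvature and non-cortical volume; constructs directed cross-property
    covariance graphs; sweeps graph density over a configurable grid and
    reduces weighted degree, clustering coefficient, eigenvector centrality
    and in-/out-degree curves to area-under-curve summaries; and contrasts
    groups by permutation testing with Benjamini-Hochberg false discovery
    rate control. Includes a latent-factor synthetic cohort generator with
    plantable covariance effects, confound regression, tabular readers and
    writers, and a summary-statistics t-test helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
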