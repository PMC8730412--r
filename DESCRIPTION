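Package: neonconn
Title: Graph-Theoretic Analysis of Neonatal Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction and analysis of fractional-anisotropy-weighted
    structural connectomes on a 90-region neonatal parcellation. Computes
    whole-brain graph metrics (global efficiency, weighted transitivity,
    Louvain modularity, small-worldness), scores hypothesis-based
    left-hemisphere language tracts (SLF 1-3, ILF, arcuate), performs
    covariate-adjusted permutation-based edge-wise group comparison with
    link-based false-discovery-rate control, and fits the univariate-screen
    to multivariate regression protocol linking connectivity to Bayley-III
    neurodevelopmental outcomes. Includes a synthetic cohort generator
    emulating two neonatal brain-injury cohorts (hypoxic-ischemic
    encephalopathy and congenital heart disease) with planted hypoconnected
    pathways and ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
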