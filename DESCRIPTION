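Package: padk
Title: Kinetic Models and Estimation Pipelines for mRNA Deadenylation and Decapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-species kinetic models of mRNA poly(A) tail metabolism in which
    decapping is either coupled to (serial) or uncoupled from (parallel)
    deadenylation: closed-form and numerical chase trajectories, steady states,
    mean poly(A) tail lengths and half-life estimators, plus the estimation
    pipelines used around such models in practice. Includes lag-exponential
    reporter decay fitting with profile-likelihood confidence intervals,
    SLAM-seq half-life estimation from T-to-C conversion tables with read-count,
    conversion-rate and goodness-of-fit gating, RIP-seq log2 enrichment
    normalization with input subtraction and median centering, nanopore-style
    per-read poly(A) tail aggregation with paired Wilcoxon comparisons and
    correlation analysis, and seeded synthetic-data generators with known ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
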