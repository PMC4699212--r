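Package: streamclass
Title: Online Mixture-Model Classification and Evidence Accumulation for
    Auditory Streaming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates bistable auditory streaming (integration versus
    segregation of alternating ABA- and ABAB tone sequences) as an online
    classification process over a generalized-normal mixture with competing
    centroid and mixing-probability updates.  Provides deterministic and
    stochastic (K-counter) switching dynamics, percept phase extraction,
    phase-duration statistics (per-trial normalization, pooled and per-trial
    lag correlations by transition type, random-intercept mixed-effects
    tests), build-up curves and parameter sweeps, plus a synthetic
    subject-report generator with controllable lag-1 correlation and
    between-subject rate heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
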