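Package: domhier
Title: Winner-Loser Dominance Dynamics, Hierarchy Indices and
    Beta-Binomial Models for Intersexual Dominance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how adult sex ratio shapes dominance of
    females over males in group-living animals. Provides a spatially
    explicit agent-based simulation of grouping and agonistic
    interactions with self-reinforcing winner-loser updating of
    dominance values; dominance-hierarchy statistics computed from
    winner-loser interaction matrices (average dominance index, tie-aware
    ranks, female dominance index, unknown-relation proportion,
    sex-classed aggression fractions); maximum-likelihood beta-binomial
    regression and mixed models with Laplace-approximated random
    intercepts, boundary likelihood-ratio tests against chi-square
    mixtures, and likelihood-based pseudo R-squared; generators for
    synthetic interaction matrices and grouped overdispersed binomial
    data with known parameters; and pipelines that run the full
    simulation experiment and the companion analysis of packaged field
    summaries from wild capuchin monkey groups.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    jsonlite,
    withr
Config/testthat/edition: 3
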