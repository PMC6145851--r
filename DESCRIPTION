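Package: netdyn
Title: Time-Resolved Brain Network Topology from Parcellated BOLD Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for time-resolved functional connectivity and network
    cartography of parcellated BOLD fMRI data. Estimates sliding-window
    coupling with the multiplication of temporal derivatives, detects
    communities on signed weighted graphs with an iterated Louvain algorithm
    and consensus clustering, summarises topology with the participation
    coefficient and module-degree z-score (the cartographic profile), tracks
    regional flexibility with Hungarian label matching, tests dynamism
    against stationary vector-autoregressive surrogate nulls, and provides
    group-level crossover, pupillometry and task-design statistics. A
    seeded synthetic-data generator produces modular BOLD-like cohorts,
    pupil traces and block designs with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    lme4,
    lmerTest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
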