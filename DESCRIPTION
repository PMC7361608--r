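Package: opinionets
Title: Attitude Networks and Opinion-Based Group Detection for
    Longitudinal Likert Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds bipartite person-attitude graphs from longitudinal
    Likert survey panels, projects them into weighted participant-agreement
    and signed attitude-alignment networks, detects emergent opinion-based
    factions via thresholded connected components cross-validated with
    k-means clustering, and quantifies polarization across survey waves
    through bridging-edge counts. Ships a synthetic-cohort generator with a
    planted two-faction structure whose divergence ramps across waves,
    survey scoring utilities (scale means, Cronbach's alpha, attention-check
    and panel-matching bookkeeping), and the downstream group statistics:
    one-way ANOVA with partial eta-squared and its noncentral-F confidence
    interval, Wilks lambda MANOVA with Rao's F approximation, binary
    logistic regression with Wald odds-ratio intervals, chi-squared
    association tests, and Pearson correlations. Graphs export to GraphML,
    GEXF and edge-list CSV with deterministic force-directed layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
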