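Package: recurnet
Title: Cross-Recurrence Network Analysis of Longitudinal Elemental
    Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs per-element attractors from longitudinal
    elemental biomarker profiles (metal:calcium intensity ratios sampled
    along developmental time), quantifies pairwise non-linear coupling
    with cross-recurrence quantification analysis (CRQA), builds
    per-subject weighted metabolic networks from recurrence-rate and
    diagonal-line-entropy edges, and tests exposure-group effects on
    network centrality metrics with element-by-exposure linear mixed
    models. Includes a seeded synthetic-cohort generator emulating shared
    periodic structure (circaseptan and seasonal cycles) and a dichotomous
    lead-exposure factor.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    lme4,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    lmerTest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
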