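Package: asymmap
Title: Hemispheric Asymmetry of Activity and Connectivity on Cortical Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify hemispheric lateralization of task-related
    activity and of seed-based functional connectivity on triangulated
    cortical surface meshes. Implements per-subject signed and unsigned
    reward-related asymmetry (RRA) maps, the functional connectivity
    asymmetry (FCA) coefficient comparing homologous seed vertices'
    whole-brain correlation profiles, incremental group PCA (MIGP) for
    group pseudo-time-series, Fisher-randomization cluster-mass inference
    on meshes, conjunction ("functional asymmetry cluster") analyses with
    cross-index correlation and behavioural covariate screening, and
    seed-by-network connectivity-profile ANOVA with post hoc contrasts.
    A synthetic-cohort generator with planted, known lateralization
    provides ground truth for parameter-recovery and type-I-error testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    rlang,
    xml2,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
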