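Package: rrowflow
Title: Information Flow and Functional Parcellation of Prefrontal Spike
    Ensembles in the Restaurant Row Foraging Task
Version: 0.1.0
Authors@R:
    person("rrowflow", "maintainers", email = "rrowflow@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for spike ensembles recorded along a linear
    probe while rats perform the Restaurant Row economic foraging task.
    Implements shuffle-normalized transfer entropy between simultaneously
    recorded cells, plug-in mutual information between binned firing rates
    and task variables, peri-event time histograms in absolute and
    zone-normalized time, data-driven detection of functional subregion
    boundaries along the dorso-ventral axis, economic threshold fitting,
    and a synthetic session/ensemble generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
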