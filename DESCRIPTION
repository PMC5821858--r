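Package: ccnet
Title: Longitudinal EEG Functional Network Analysis for Corpus Callosotomy Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds surrogate-corrected mutual-information functional networks from
    multichannel scalp EEG and tracks their topology across pre- and post-operative
    recordings of corpus callosotomy patients. Provides phase-randomization surrogate
    significance testing for pairwise mutual information, weighted graph measures
    (betweenness centrality, Onnela clustering, characteristic path length, global
    clustering) normalized against degree- and weight-preserving random null models,
    small-worldness, betweenness-based hub extraction and hub-shift summaries, and the
    outcome-group statistical battery (repeated-measures ANOVA with Bonferroni
    post-hocs, Levene homogeneity tests). Includes a synthetic 19-channel cohort
    generator with planted pre-/post-operative connectivity structure so the full
    pipeline is testable without patient data, plus CSV, Pajek and minimal EDF input
    and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
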