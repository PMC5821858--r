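# ccnet

Longitudinal EEG functional-network analysis for corpus callosotomy
outcomes.

ccnet builds weighted functional brain networks from multichannel scalp EEG
using surrogate-corrected mutual information, tracks their graph topology
across repeated recording sessions (pre-operative, 3 months, 1 and 2 years
after surgery), and runs the outcome-group statistical battery used to
study how interrupting the corpus callosum reorganizes cortical networks in
Lennox-Gastaut-type epilepsy: do high-betweenness hubs migrate away from
the paramedian strip, does the network become more homogeneous, and does
small-worldness move toward or away from the random-network regime
depending on surgical outcome?

## What it provides

- **Connectivity**: pairwise mutual information (plug-in estimator on
  rank-equiprobable bins, C++), phase-randomization surrogates, per-pair
  significance thresholds at the exact permutation level, and adjacency
  matrices at patient, group and difference level
  (`mutual_information()`, `phase_randomize()`, `epoch_adjacency()`,
  `group_adjacency()`, `difference_matrix()`).
- **Graph metrics**: weighted betweenness centrality, Onnela weighted
  clustering, characteristic path length, and null-normalized global
  clustering / path length / small-worldness against degree- and
  weight-preserving random references; hub extraction and
  paramedian-vs-lateral hub-shift summaries (`weighted_betweenness()`,
  `local_clustering()`, `global_metrics()`, `extract_hubs()`,
  `hub_shift()`).
- **Preprocessing**: zero-phase broadband and notch filtering, common
  average re-referencing, artifact-screened 1-second epoch selection, and
  FFT band decomposition (`broadband_filter()`, `average_rereference()`,
  `segment_and_select()`, `band_filter()`).
- **Statistics**: within-subject repeated-measures ANOVA across sessions
  with Bonferroni post-hocs, outcome classification (>80% two-year seizure
  reduction), and Levene homogeneity tests with an exact permutation
  p-value (`rm_anova()`, `classify_outcome()`, `levene_test()`).
- **Synthetic cohort**: a stable multivariate-autoregressive generator with
  planted pre-/post-operative coupling structure and clinically consistent
  covariates, so every pipeline stage is testable end to end without
  patient data (`generate_cohort()`, `make_condition_coupling()`).
- **I/O and pipeline**: CSV and Pajek `.net` network export, a minimal EDF
  signal reader/writer, YAML-configurable batch stages with provenance
  stamping and resumable outputs (`run_simulate()`, `run_connect()`,
  `run_metrics()`, `run_report()`, plus a CLI at `inst/cli/ccnet.R`).

## Worked example

Simulate a small synthetic cohort and look at what surgery does to the
good-outcome groups' networks (this is the planted ground truth the test
suite also recovers):

```r
library(ccnet)

# a small synthetic cohort: 2 patients per outcome group, 60 epochs/session
cohort <- generate_cohort(
  n_per_group = c(I_HighGood = 2, II_LowGood = 2,
                  III_HighBad = 2, IV_LowBad = 2),
  seed = 1, n_epochs = 60)
cohort
#> <cc_cohort> 8 patients x 4 sessions (60 epochs each)
#>
#>  I_HighGood  II_LowGood III_HighBad   IV_LowBad
#>           2           2           2           2

# surrogate-corrected MI adjacency matrices for every patient-session
adj <- cohort_adjacency(cohort, n_surrogates = 200, seed = 2)

# group-average networks of the good-outcome groups, before and after surgery
good <- c("I_HighGood", "II_LowGood")
pre  <- group_session_adjacency(adj, cohort, good, "preop")
post <- group_session_adjacency(adj, cohort, good, "y2")

# hubs migrate away from the paramedian strip
hub_shift(extract_hubs(pre), extract_hubs(post))
#> $pre_paramedian
#> [1] 5
#> $pre_lateral
#> [1] 0
#> $post_paramedian
#> [1] 0
#> $post_lateral
#> [1] 5
#> $shift
#> [1] -5

# small-worldness rises toward the random-network regime
global_metrics(pre,  n_random = 100, seed = 3)
#> <global_metrics> CPL 56.6103 (norm 1.0697)  GCC 0.1871 (norm 1.0138)  small-worldness 0.9477  [100 refs]
global_metrics(post, n_random = 100, seed = 4)
#> <global_metrics> CPL 68.4778 (norm 0.9988)  GCC 0.5298 (norm 0.9998)  small-worldness 1.0010  [100 refs]

# interhemispheric lateral coupling strengthens while paramedian coupling drops
d <- difference_matrix(post, pre)
pp <- paramedian_channels()
mean(d[pp, pp][upper.tri(d[pp, pp])])
#> [1] -0.01946948
mean(d[homologous_lateral_pairs()])
#> [1] 0.006587707
```

The same analysis scales to the full study design (groups of 6/11/6/7
patients, 300 epochs, 1000 surrogates) through the batch stages:

```sh
Rscript inst/cli/ccnet.R simulate --out cohort/ --seed 1
Rscript inst/cli/ccnet.R connect  --in cohort/ --out analysis/
Rscript inst/cli/ccnet.R metrics  --in analysis/ --out metrics/
Rscript inst/cli/ccnet.R report   --in metrics/  --out report/
```

`run_connect()` also accepts real recordings dropped into the same
directory layout (`metadata.csv` plus one CSV or EDF signal matrix per
patient-session).

## Documentation

The methods vignette (`vignettes/ccnet-methods.Rmd`) documents the
estimator conventions, the null models, the synthetic generator's planted
structure, and the package's validation design and limitations.
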