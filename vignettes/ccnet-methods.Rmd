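---
title: "Methods: surrogate-corrected MI networks for longitudinal EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate-corrected MI networks for longitudinal EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ccnet builds weighted functional networks from multichannel scalp EEG and
tracks their topology across repeated recording sessions, with the
longitudinal corpus-callosotomy design in mind: four recordings per patient
(pre-operative, 3 months, 1 year, 2 years), outcome groups defined by
two-year seizure reduction, and network measures compared within patients
across sessions. This vignette documents the methodological choices, the
defaults, and the synthetic cohort generator used to validate the pipeline
end to end without patient data.

## Signal model and preprocessing

Recordings are 19-channel 10-20 montage EEG sampled at 200 Hz
(`montage_1020()`, `ccnet_config()$fs`). Preprocessing follows the standard
chain:

1. `broadband_filter()`: 1-70 Hz zero-phase band-pass (FIR, order 200,
   applied with `filtfilt`) plus a 58-62 Hz second-order Butterworth notch
   for line noise, then per-channel demeaning.
2. `average_rereference()`: common-average reference. This is idempotent
   and removes any signal component common to all channels.
3. `segment_and_select()`: the recording is cut into non-overlapping
   1-second windows; windows containing extreme peaks (robust z-score above
   `reject_z = 6`, scaled by the median absolute deviation) are rejected as
   artifacts, and the requested number of epochs (default 300) is drawn
   uniformly at random from the surviving windows under a seed.

Within 1-second epochs (200 samples) a long FIR filter is not usable, so
`band_filter()` isolates classical bands by zero-phase FFT masking of the
epoch spectrum instead. Both filters are linear and phase-neutral; the
broadband FIR is reserved for continuous recordings.

## Connectivity: surrogate-corrected mutual information

Pairwise dependence is measured by plug-in mutual information in bits
(`mutual_information()`, implemented in C++): both series are ranked and
partitioned into `n_bins = 8` equiprobable bins, and MI is computed from the
joint histogram. Equiprobable (rank) binning makes the estimate invariant
under strictly monotone transformations of either signal and bounds it by
`log2(n_bins)` = 3 bits. With 200 samples and an 8x8 joint histogram the
estimator has a positive finite-sample bias, which is exactly why a
surrogate correction is needed.

The null model is phase randomization (`phase_randomize()`): the epoch's
Fourier amplitudes are kept and the free phases are replaced by i.i.d.
uniform draws (respecting conjugate symmetry, with the DC and Nyquist bins
fixed), destroying any cross-signal dependence while preserving each
signal's amplitude spectrum and autocorrelation.

`epoch_adjacency()` builds one adjacency matrix per recording session:

- The observed MI is averaged over epochs for each channel pair.
- A null ensemble of `n_surrogates = 1000` MI values per pair is built by
  repeatedly drawing a random epoch, phase-randomizing every channel, and
  recomputing the pairwise MI (the pooled per-session convention; a
  per-epoch mode is available).
- The per-pair significance threshold is the order statistic
  `k = ceiling((1 - alpha) * (S + 1))` of the `S` null values — the exact
  permutation-test convention, whose exceedance probability is
  `(S + 1 - k)/(S + 1)`, approximately `alpha = 0.05`. With `S = 200` this
  is 10/201 = 0.0498, which is what the calibration check in the test suite
  verifies empirically.
- In the default `"threshold"` mode, sub-threshold weights are set to zero
  and significant weights keep their observed MI; a `"subtract"` mode
  (observed minus threshold, floored at zero) is also provided.

Group-level networks are plain averages of patient matrices for one session
(`group_adjacency()`, `group_session_adjacency()`), and contrasts between
sessions are element-wise differences (`difference_matrix()`). For display,
`top_fraction_edges()` selects the strongest 30% of edges; all metrics are
computed on the full weighted matrix, never on the display subset.

## Graph metrics

All measures treat MI weights as connection strengths, with shortest-path
lengths defined on inverse weights (strong = close).

- `weighted_betweenness()`: exact Brandes betweenness with fractional
  credit over co-shortest paths, normalized by `(n-1)(n-2)/2` so a star
  center scores 1. Hubs are the `hub_k = 5` highest-betweenness channels
  (`extract_hubs()`, ties broken deterministically in montage order), and
  `hub_shift()` summarizes their paramedian/lateral distribution.
- `local_clustering()`: the Onnela weighted clustering coefficient — weights
  scaled by the matrix maximum, geometric mean of the three edge weights
  over closed triangles, normalized by `k(k-1)`. The global coefficient
  (GCC) is the channel mean. On a fully connected uniform-weight network
  every node scores exactly 1.
- `characteristic_path_length()` (CPL): mean shortest-path distance over
  pairs. Significance masking can disconnect a network, in which case the
  default falls back to the harmonic mean of distances (the reciprocal of
  global efficiency; infinite distances contribute zero) with a warning.
- `global_metrics()`: CPL and GCC are normalized by their means over
  `n_random = 100` random references that preserve both the degree sequence
  (Maslov-Sneppen rewiring) and the weight multiset (random reassignment).
  Small-worldness is the ratio of normalized GCC to normalized CPL. A
  complete uniform network is a fixed point of this null model, so its
  normalized metrics and small-worldness equal 1 exactly — an identity the
  acceptance checks exploit.

## Statistics

- `rm_anova()`: one-way within-subject ANOVA across the four sessions via
  `aov(y ~ session + Error(subject))`, degrees of freedom
  `(s-1, (s-1)(n-1))` (e.g. F(3,15) for six patients). When the omnibus
  test is significant, Bonferroni-corrected paired t-tests compare all
  session pairs. An optional Greenhouse-Geisser correction is available.
- `levene_test()`: the classic Levene statistic (one-way F on absolute
  deviations from the group mean) compares channel-wise dispersion of node
  metrics between states; a drop in dispersion after surgery indicates a
  more homogeneous network. The default p-value is a label-permutation null
  of the W statistic: the F(1, n-2) approximation is anti-conservative at
  the small group sizes used here (empirical size about 0.059 at nominal
  0.05 for two groups of 10, versus 0.035 for the median-centered variant),
  while the permutation test is exact under exchangeability. The classic
  approximation remains available via `p_method = "f"`.
- `classify_outcome()` / `assign_group()`: good outcome is strictly more
  than 80% seizure reduction at two years; groups cross that with high/low
  pre-operative seizure frequency (cutoff 10 events/day) into the four
  cohort groups I-IV.

`longitudinal_report()` bundles these: per group and metric the session
trajectories and RM-ANOVA, the combined good-outcome groups' small-worldness
test, and pre-op vs 3-month Levene tests.

## Synthetic cohort generator

Because real patient EEG cannot ship with the package, `generate_cohort()`
produces a cohort with known ground truth. Signals follow a stable
first-order multivariate autoregressive model: with coupling matrix `C`
(entries in [0, 1)) the transition matrix is `diag(0.5) + 0.5 * C`, driven
by unit Gaussian innovations; each epoch discards a 300-sample burn-in. The
0.5 coupling scale keeps even a strong planted coupling of 0.8 stable.
Dependence between two channels grows monotonically with their coupling
entry, so MI recovers the planted structure.

Three coupling templates (`make_condition_coupling()`) encode the planted
biology on the 10-20 scalp:

- **preop**: strong paramedian backbone (midline spokes Fz-Cz-Pz plus
  parasagittal chains F3-C3-P3 / F4-C4-P4 at strength `b = 0.25`), lateral
  channels attached at `0.45 b`, and only faint (`0.10 b`) homologous
  interhemispheric and intra-lateral links. Shortest paths route through
  the paramedian channels, which therefore carry the hubs.
- **postop_good**: the backbone weakens to `0.45 b` while homologous
  interhemispheric pairs rise to `0.55 b` and lateral chains to `0.45 b` —
  a flatter, more homogeneous network whose hubs disperse laterally and
  whose small-worldness rises toward 1.
- **postop_bad**: mean paramedian coupling stays within 10% of pre-op, but
  it is concentrated star-like on the eight midline spokes (`1.30 b`) while
  the parasagittal chains halve and the faint lateral couplings almost
  vanish (`0.02 b`). The strong subnetwork becomes tree-like, so clustering
  falls relative to the rewired null and small-worldness decreases — the
  retained-midline-hub pattern of a poor outcome.

Per patient, templates receive small lognormal weight jitter, clinical
covariates (seizure frequency, percent reductions) are drawn consistently
with the planted group, and good-outcome patients interpolate linearly from
pre-op to the good template across the follow-ups while bad-outcome
patients switch to the bad template from 3 months on. Default group sizes
are 6/11/6/7.

Determinism: every patient, session, surrogate ensemble and random-reference
ensemble draws its seed through `fan_seed()` from one master seed, so any
sub-result can be recomputed bit-identically in isolation.

## Validation design and reduced sizes

The test suite validates against independent oracles rather than stored
numbers: a separately coded entropy-identity MI estimator, brute-force
simple-path enumeration for betweenness/CPL on small graphs, closed-form
networks (stars, paths, triangles, complete graphs), and empirical
calibration of the surrogate threshold and of both statistical tests
against their nominal levels. Parameter-recovery checks run the full
pipeline on reduced-size cohorts (50 epochs per session, 100 surrogates,
100 random references) — a deliberate package choice to keep the suite
within minutes while leaving the planted effects far above noise — and
small-worldness trends are evaluated on group-average networks, matching
the per-group definition of the quantity used in the report.

`scripts/acceptance.R` recomputes the two analytic identities (mean LCC and
small-worldness of a complete uniform 19-node network, both exactly 1) and
the surrogate calibration rate (nominal 0.05) against the installed package
and writes them as JSON.

## Limitations

- The plug-in MI estimator is biased upward at small samples; the pipeline
  relies on the surrogate threshold, not on unbiasedness.
- Phase randomization tests the null of a linear Gaussian process; strongly
  non-Gaussian artifacts can inflate detections.
- The EDF writer/reader covers only the subset needed here (16-bit, 1-s
  records, no annotations).
- The harmonic-mean CPL fallback changes the metric's meaning on
  disconnected graphs; the accompanying warning should not be ignored.
- The synthetic generator is a validation instrument, not a biophysical
  model; its templates encode the expected direction of effects, not their
  clinical magnitudes.
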