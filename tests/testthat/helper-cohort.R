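# Reduced-scale cohort analyses are expensive; cache them so the
# planted-structure and small-worldness checks share one run per seed.
# Reduced study conditions: 50 epochs/session, 100 surrogates/pair.
.cohort_cache <- new.env(parent = emptyenv())

cohort_analysis <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.cohort_cache[[key]])) {
    coh <- generate_cohort(seed = seed, n_epochs = 50)
    adj <- cohort_adjacency(coh, n_surrogates = 100,
                            seed = fan_seed(seed, 99))
    .cohort_cache[[key]] <- list(cohort = coh, adj = adj)
  }
  .cohort_cache[[key]]
}

group_session_sw <- function(an, groups, session, seed) {
  g <- group_session_adjacency(an$adj, an$cohort, groups, session)
  suppressWarnings(global_metrics(g, n_random = 100,
                                  seed = seed))$small_worldness
}
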