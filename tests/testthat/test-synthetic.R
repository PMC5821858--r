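test_that("coupling model validates its invariants", {
  C <- matrix(0, 3, 3)
  expect_s3_class(coupling_model(C), "coupling_model")
  C2 <- C; C2[1, 2] <- 0.5
  expect_error(coupling_model(C2), "symmetric")
  C3 <- C; C3[1, 2] <- C3[2, 1] <- 1.2
  expect_error(coupling_model(C3), "in \\[0, 1\\)")
  C4 <- C; diag(C4) <- 0.1
  expect_error(coupling_model(C4), "diagonal")
})

test_that("unstable systems are refused before emitting data", {
  C <- matrix(c(0, 0.99, 0.99, 0), 2)
  m <- coupling_model(C, ar_coeffs = c(0.9, 0.9))
  expect_false(is_stable(m))
  mont2 <- data.frame(channel = c("a", "b"), x = 0, y = 0,
                      region = "lateral", hemisphere = "left")
  expect_error(generate_coupled_epochs(m, 5, montage = mont2), "unstable")
  expect_error(generate_coupled_epochs(coupling_model(matrix(0, 2, 2)),
                                       n_epochs = 0, montage = mont2),
               "positive")
})

test_that("generation is deterministic and dependence follows coupling", {
  mont2 <- data.frame(channel = c("a", "b"), x = 0, y = 0,
                      region = "lateral", hemisphere = "left")
  C <- matrix(c(0, 0.5, 0.5, 0), 2)
  m <- coupling_model(C)
  e1 <- generate_coupled_epochs(m, 10, seed = 7, montage = mont2)
  e2 <- generate_coupled_epochs(m, 10, seed = 7, montage = mont2)
  expect_identical(e1$data, e2$data)
  # monotone dependence: larger coupling, larger mean epoch MI (>= 100 epochs)
  mi_at <- vapply(c(0.2, 0.4), function(cpl) {
    Cc <- matrix(c(0, cpl, cpl, 0), 2)
    eps <- generate_coupled_epochs(coupling_model(Cc), 100, seed = 5,
                                   montage = mont2)
    mean(vapply(seq_len(100), function(e)
      mutual_information(eps$data[e, 1, ], eps$data[e, 2, ]), numeric(1)))
  }, numeric(1))
  expect_lt(mi_at[1], mi_at[2])
})

test_that("zero coupling yields surrogate exceedance near the nominal level", {
  C <- matrix(0, 19, 19)
  eps <- generate_coupled_epochs(coupling_model(C), n_epochs = 50, seed = 1)
  det <- epoch_adjacency(eps, n_surrogates = 200, seed = 2, details = TRUE)
  ex <- sweep(det$observed, c(2, 3), det$threshold, `>`)
  exceed <- mean(matrix(ex, nrow = dim(ex)[1])[, upper.tri(det$threshold)])
  n_trials <- 50 * 171
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / n_trials)
  expect_gt(exceed, ci[1])
  expect_lt(exceed, ci[2])
})

test_that("a single planted edge becomes the strongest network weight", {
  mont <- montage_1020()
  C <- matrix(0, 19, 19, dimnames = list(mont$channel, mont$channel))
  C["C3", "C4"] <- C["C4", "C3"] <- 0.8
  eps <- generate_coupled_epochs(coupling_model(C), n_epochs = 30, seed = 5)
  adj <- epoch_adjacency(eps, n_surrogates = 100, seed = 6)
  top <- which(unclass(adj) == max(adj), arr.ind = TRUE)
  expect_setequal(rownames(adj)[top[, 1]], c("C3", "C4"))
})

test_that("condition couplings plant the intended contrasts", {
  mont <- montage_1020()
  pp <- mont$channel[mont$region == "paramedian"]
  ll <- mont$channel[mont$region == "lateral"]
  ppm <- function(C) mean(C[pp, pp][upper.tri(C[pp, pp])])
  llm <- function(C) mean(C[ll, ll][upper.tri(C[ll, ll])])
  cv <- function(C) { v <- C[upper.tri(C)]; v <- v[v > 0]; sd(v) / mean(v) }
  pre <- make_condition_coupling("preop")$coupling
  good <- make_condition_coupling("postop_good")$coupling
  bad <- make_condition_coupling("postop_bad")$coupling
  expect_gt(ppm(pre), llm(pre))
  expect_lt(cv(good), cv(pre))                   # homogenization
  expect_lt(ppm(good), ppm(pre))                 # paramedian weakening
  hl <- homologous_lateral_pairs()
  expect_gt(mean(good[hl]), mean(pre[hl]))       # interhemispheric increase
  expect_lt(abs(ppm(bad) / ppm(pre) - 1), 0.10)  # bad outcome retains core
  expect_error(make_condition_coupling("preop", base_strength = 0.95),
               "base_strength")
  for (cond in c("preop", "postop_good", "postop_bad")) {
    expect_true(is_stable(make_condition_coupling(cond)))
  }
})

test_that("cohort generation round-trips labels, counts and determinism", {
  small <- c(I_HighGood = 2, II_LowGood = 2, III_HighBad = 2, IV_LowBad = 2)
  coh <- generate_cohort(n_per_group = small, seed = 3, n_epochs = 4,
                         n_samples = 64)
  expect_length(coh$patients, 8)
  expect_equal(sum(lengths(lapply(coh$patients, `[[`, "sessions"))), 32)
  meta <- cohort_metadata(coh)
  relab <- assign_group(meta$preop_seizure_freq, meta$reduction_y2,
                        freq_cutoff = coh$config$freq_cutoff)
  expect_equal(relab, meta$group)
  expect_setequal(names(coh$patients[[1]]$reductions), c("m3", "y1", "y2"))
  coh2 <- generate_cohort(n_per_group = small, seed = 3, n_epochs = 4,
                          n_samples = 64)
  expect_identical(cohort_metadata(coh2), meta)
  expect_identical(coh2$patients[[5]]$sessions$y1$data,
                   coh$patients[[5]]$sessions$y1$data)
  expect_error(generate_cohort(n_per_group = c(I_HighGood = 1), seed = 1),
               "four groups")
})
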