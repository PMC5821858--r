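test_that("betweenness and path length match the brute-force oracle", {
  set.seed(14)
  for (r in 1:30) {
    n <- sample(4:7, 1)
    w <- random_small_graph(n)
    oracle <- brute_path_metrics(w)
    expect_equal(as.numeric(weighted_betweenness(w)), oracle$bc,
                 tolerance = 1e-9)
    expect_equal(characteristic_path_length(w), oracle$cpl,
                 tolerance = 1e-9)
  }
})

test_that("closed-form betweenness: star center and path interiors", {
  star <- matrix(0, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 0.7
  bc <- weighted_betweenness(star)
  expect_equal(as.numeric(bc), c(1, rep(0, 5)))
  path4 <- matrix(0, 4, 4)
  path4[cbind(1:3, 2:4)] <- path4[cbind(2:4, 1:3)] <- 1
  expect_equal(as.numeric(weighted_betweenness(path4)),
               c(0, 2 / 3, 2 / 3, 0))
})

test_that("Onnela clustering closed forms and range", {
  full <- complete_uniform(19, 0.42)
  expect_equal(as.numeric(local_clustering(full)), rep(1, 19))
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1
  tri[2, 3] <- tri[3, 2] <- 1
  tri[1, 3] <- tri[3, 1] <- 0.125
  expect_equal(as.numeric(local_clustering(tri)), rep(0.5, 3))
  # dangling node (degree < 2) scores zero
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  expect_equal(as.numeric(local_clustering(w)), rep(0, 4))
  set.seed(2)
  r <- random_small_graph(7)
  lc <- local_clustering(r)
  expect_true(all(lc >= 0 & lc <= 1))
})

test_that("metric invariances: weight scale and node permutation", {
  set.seed(6)
  w <- random_small_graph(7)
  expect_equal(local_clustering(3 * w), local_clustering(w))
  expect_equal(weighted_betweenness(3 * w), weighted_betweenness(w))
  expect_equal(characteristic_path_length(3 * w),
               characteristic_path_length(w) / 3)
  p <- sample(7)
  expect_equal(as.numeric(local_clustering(w[p, p])),
               as.numeric(local_clustering(w))[p])
  expect_equal(as.numeric(weighted_betweenness(w[p, p])),
               as.numeric(weighted_betweenness(w))[p])
  expect_equal(characteristic_path_length(w[p, p]),
               characteristic_path_length(w))
})

test_that("disconnected graphs fall back to the harmonic mean or error", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 0.5
  expect_warning(cpl <- characteristic_path_length(w), "disconnected")
  expect_equal(cpl, 1 / mean(c(1, 0, 0, 0, 0, 1 / 2)))  # finite d: 1 and 2
  expect_error(characteristic_path_length(w, disconnected = "error"),
               "disconnected")
})

test_that("random references preserve degrees and the weight multiset", {
  set.seed(8)
  w <- random_small_graph(12, p_edge = 0.35)
  for (r in 1:10) {
    m <- ccnet:::random_reference(w)
    expect_equal(rowSums(m > 0), rowSums(w > 0))
    expect_equal(sort(m[upper.tri(m)][m[upper.tri(m)] > 0]),
                 sort(w[upper.tri(w)][w[upper.tri(w)] > 0]))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
  }
})

test_that("complete uniform network normalizes to exactly 1", {
  gm <- global_metrics(complete_uniform(19, 0.5), n_random = 30, seed = 4)
  expect_equal(gm$cpl_norm, 1)
  expect_equal(gm$gcc_norm, 1)
  expect_equal(gm$small_worldness, 1)
  expect_equal(gm$cpl_random_sd, 0)
})

test_that("small-worldness separates a lattice from a random graph", {
  # Watts-Strogatz regular ring lattice: high clustering, long paths
  ring <- matrix(0, 24, 24)
  for (i in 1:24) for (k in 1:3) {
    j <- ((i + k - 1) %% 24) + 1
    ring[i, j] <- ring[j, i] <- 1
  }
  gm_ring <- global_metrics(ring, n_random = 50, seed = 3)
  expect_gt(gm_ring$gcc_norm, 1.5)
  expect_gt(gm_ring$cpl_norm, 1.2)
  # dense ER graph is its own null up to noise
  set.seed(10)
  er <- random_small_graph(16, p_edge = 0.5)
  gm_er <- suppressWarnings(global_metrics(er, n_random = 50, seed = 3))
  expect_lt(abs(gm_er$small_worldness - 1), 0.25)
  expect_warning(global_metrics(er, n_random = 5, seed = 1), "noisy")
})

test_that("global metrics are deterministic given a seed", {
  set.seed(19)
  w <- random_small_graph(12, p_edge = 0.4)
  g1 <- suppressWarnings(global_metrics(w, n_random = 25, seed = 7))
  g2 <- suppressWarnings(global_metrics(w, n_random = 25, seed = 7))
  expect_identical(g1, g2)
})

test_that("hub extraction orders by betweenness with stable tie-breaking", {
  w <- complete_uniform(19, 0.5)
  w["C3", ] <- w[, "C3"] <- 2
  diag(w) <- 0
  h <- extract_hubs(w, k = 5)
  expect_equal(h[1], "C3")
  expect_length(h, 5)
  expect_true(attr(h, "ties"))           # remaining 18 nodes all tie
  expect_equal(h[2:5], c("Fp1", "Fp2", "F7", "F3"))  # montage-order ties
  bc <- weighted_betweenness(w)
  expect_identical(as.character(extract_hubs(bc, k = 3)), as.character(h[1:3]))
  expect_error(extract_hubs(w, k = 20), "exceeds")
})

test_that("hub shift counts the paramedian/lateral move", {
  s <- hub_shift(c("Fz", "Cz", "Pz", "C3", "T3"),
                 c("T3", "T4", "O1", "Cz", "F7"))
  expect_equal(s$pre_paramedian, 4)
  expect_equal(s$post_paramedian, 1)
  expect_equal(s$shift, -3)
  expect_error(hub_shift(c("Fz"), c("XX")), "not found")
})
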