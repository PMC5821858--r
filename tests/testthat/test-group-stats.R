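test_that("outcome classification uses a strict 80% cutoff", {
  expect_equal(classify_outcome(c(79, 80, 80.001, 100)),
               c("bad", "bad", "good", "good"))
  expect_error(classify_outcome(NA_real_), "missing")
  expect_error(classify_outcome(120), "\\[-100, 100\\]")
  expect_equal(classify_outcome(70, cutoff = 60), "good")
})

test_that("group assignment covers the 2x2 design", {
  expect_equal(assign_group(c(20, 5, 20, 5), c(90, 90, 40, 40)),
               c("I_HighGood", "II_LowGood", "III_HighBad", "IV_LowBad"))
  # boundary: freq exactly at cutoff is Low, reduction exactly at cutoff is bad
  expect_equal(assign_group(10, 80), "IV_LowBad")
  expect_equal(assign_group(10.01, 80.01), "I_HighGood")
})

test_that("RM-ANOVA reproduces textbook degrees of freedom and a known F", {
  set.seed(2)
  m <- matrix(rnorm(6 * 4), 6, 4,
              dimnames = list(NULL, c("preop", "m3", "y1", "y2")))
  res <- rm_anova(m)
  expect_s3_class(res, "rm_anova")
  expect_equal(res$df_num, 3)
  expect_equal(res$df_den, 15)
  expect_equal(res$n, 6)
  # cross-check F against an independent decomposition of sums of squares
  n <- 6; s <- 4
  gm <- mean(m)
  ss_session <- n * sum((colMeans(m) - gm)^2)
  ss_subject <- s * sum((rowMeans(m) - gm)^2)
  ss_total <- sum((m - gm)^2)
  ss_err <- ss_total - ss_session - ss_subject
  F_manual <- (ss_session / (s - 1)) / (ss_err / ((s - 1) * (n - 1)))
  expect_equal(res$F, F_manual, tolerance = 1e-10)
  expect_equal(res$p, pf(F_manual, 3, 15, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("RM-ANOVA is invariant to per-patient constants", {
  set.seed(3)
  m <- matrix(rnorm(8 * 4), 8, 4)
  shifted <- m + rnorm(8) * 10   # recycled down columns: per-patient offsets
  expect_equal(rm_anova(shifted)$F, rm_anova(m)$F, tolerance = 1e-9)
})

test_that("degenerate and missing inputs are handled explicitly", {
  flat <- matrix(rep(1:5, 4), 5, 4)  # identical session profiles
  res <- rm_anova(flat)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  m <- matrix(rnorm(6 * 4), 6, 4)
  m[2, 3] <- NA
  expect_warning(res2 <- rm_anova(m), "incomplete")
  expect_equal(res2$n, 5)
  expect_error(suppressWarnings(rm_anova(m[1:2, ] * NA)), "2 complete")
})

test_that("post-hocs appear only under a significant omnibus test", {
  set.seed(4)
  base <- matrix(rnorm(10 * 4, sd = 0.2), 10, 4,
                 dimnames = list(NULL, c("preop", "m3", "y1", "y2")))
  strong <- sweep(base, 2, c(0, 2, 2, 2), `+`)
  res <- rm_anova(strong)
  expect_lt(res$p, 0.05)
  expect_s3_class(res$posthoc, "data.frame")
  expect_equal(nrow(res$posthoc), 6)
  expect_true(all(res$posthoc$p_corrected <= 1))
  expect_true(all(grepl("preop vs ",
                        res$posthoc$pair[grepl("preop", res$posthoc$pair)])))
  weak <- rm_anova(base)
  if (weak$p >= 0.05) expect_null(weak$posthoc)
})

test_that("Greenhouse-Geisser epsilon lies in [1/(s-1), 1] and shrinks p", {
  set.seed(5)
  m <- matrix(rnorm(8 * 4), 8, 4)
  m[, 4] <- m[, 4] * 4   # heterogeneous variances violate sphericity
  res <- rm_anova(m, gg = TRUE)
  expect_gte(res$gg_epsilon, 1 / 3 - 1e-9)
  expect_lte(res$gg_epsilon, 1 + 1e-9)
  expect_gte(res$p_gg, res$p - 1e-12)
})

test_that("Levene test detects scale differences but not location shifts", {
  set.seed(6)
  a <- rnorm(40, sd = 1)
  b <- rnorm(40, sd = 4)
  res <- levene_test(a, b)
  expect_lt(res$p, 0.01)
  expect_equal(levene_test(a, b, p_method = "f")$W, res$W)
  shift <- levene_test(a, a + 100)
  expect_equal(shift$W, 0, tolerance = 1e-9)
  expect_gt(shift$p, 0.5)
  expect_warning(deg <- levene_test(rep(1, 5), rep(2, 5)), "degenerate")
  expect_equal(deg$p, 1)
  expect_error(levene_test(1, c(1, 2)), ">= 2")
})

test_that("Levene test matches the classic closed form on a tiny example", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 2, 2, 8)
  res <- levene_test(a, b, p_method = "f")
  z_a <- abs(a - mean(a)); z_b <- abs(b - mean(b))
  z <- c(z_a, z_b); zb <- c(mean(z_a), mean(z_b))
  num <- 4 * sum((zb - mean(z))^2) / 1
  den <- (sum((z_a - zb[1])^2) + sum((z_b - zb[2])^2)) / 6
  expect_equal(res$W, num / den, tolerance = 1e-9)
  expect_equal(res$p, pf(num / den, 1, 6, lower.tail = FALSE),
               tolerance = 1e-9)
})
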