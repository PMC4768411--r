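test_that("the generator honours the null/non-null split and effect distribution", {
  sim0 <- simulate_dataset(m = 100, pi1 = 0, seed = 1)
  expect_true(all(!sim0$truth$nonnull))
  expect_true(all(sim0$truth$mu == 0))

  sim1 <- simulate_dataset(m = 5000, pi1 = 1, seed = 2)
  expect_true(all(sim1$truth$nonnull))
  expect_true(all(sim1$truth$sign == 1))
  # mean of U(0, 2.5) is 1.25; SE of the mean over 15000 draws
  se <- (2.5 / sqrt(12)) / sqrt(length(sim1$truth$mu))
  expect_lt(abs(mean(sim1$truth$mu) - 1.25), 3 * se)

  simh <- simulate_dataset(m = 1000, pi1 = 0.3, seed = 3)
  expect_equal(sum(rowSums(simh$truth$nonnull) > 0), 300)
  expect_true(all(which(rowSums(simh$truth$nonnull) > 0) > 700))
})

test_that("noise has unit variance and the stated correlation structures", {
  simA <- simulate_dataset(m = 4000, pi1 = 0, seed = 4)
  expect_lt(abs(sd(simA$x) - 1), 0.02)

  # (b) within a sample, feature pairs correlate at rho
  simB <- simulate_dataset(m = 2000, pi1 = 0, structure = "within_sample",
                           rho = 0.2, seed = 5)
  rr <- vapply(seq_len(1000), function(k)
    cor(simB$x[2 * k - 1, ], simB$x[2 * k, ]), numeric(1))
  expect_lt(abs(mean(rr) - 0.2), 0.05)

  # (c) within a feature, sample pairs correlate at rho: estimated across
  # features from pairs of sample columns (a per-feature estimator would
  # absorb the feature-level shared factor into the feature mean)
  simC <- simulate_dataset(m = 2000, pi1 = 0, structure = "within_feature",
                           rho = 0.2, seed = 6)
  rc <- vapply(seq_len(20), function(k)
    cor(simC$x[, 2 * k - 1], simC$x[, 2 * k]), numeric(1))
  expect_lt(abs(mean(rc) - 0.2), 0.05)
  cross <- vapply(seq_len(999), function(k)
    cor(simC$x[2 * k - 1, ], simC$x[2 * k, ]), numeric(1))
  expect_lt(abs(mean(cross)), 3 * sd(cross) / sqrt(999))
})

test_that("score_run counts false and correct directional calls per pair", {
  truth <- list(nonnull = matrix(c(rep(TRUE, 8), rep(FALSE, 4)), 4, 3),
                sign = matrix(c(rep(1L, 8), rep(0L, 4)), 4, 3))
  calls <- matrix("none", 4, 3)
  calls[1:7] <- "up"          # 7 correct non-null calls
  calls[8] <- "down"          # wrong sign on a non-null pair
  calls[9:10] <- "up"         # 2 calls on true nulls
  sc <- score_run(calls, truth)
  expect_equal(sc$fdp, 3 / 10)
  expect_equal(sc$power, 7 / 8)

  none <- matrix("none", 4, 3)
  expect_equal(score_run(none, truth)$fdp, 0)
  perfect <- ifelse(truth$nonnull, "up", "none")
  expect_equal(score_run(perfect, truth), list(fdp = 0, power = 1))
})

test_that("operating-characteristics runs are deterministic under a fixed seed", {
  a <- simulate_operating_characteristics(pi1 = 0.3, n_reps = 2, m = 100,
                                          n = 5, seed = 77)
  b <- simulate_operating_characteristics(pi1 = 0.3, n_reps = 2, m = 100,
                                          n = 5, seed = 77)
  expect_identical(a, b)
  c2 <- simulate_operating_characteristics(pi1 = 0.3, n_reps = 2, m = 100,
                                           n = 5, seed = 78)
  expect_false(identical(a$mdfdr, c2$mdfdr))
})

test_that("a reduced study controls mdFDR and keeps the Dunnett procedure on top", {
  oc <- simulate_operating_characteristics(pi1 = 0.3, n_reps = 30, m = 300,
                                           seed = 12, detail = TRUE)
  expect_true(all(oc$mdfdr <= 0.05 + 3 * oc$se_mdfdr))
  pw <- attr(oc, "reps")[["0.3"]]$power
  for (comp in c("holm", "hochberg", "bonferroni", "guo")) {
    d <- pw[, "dunnett"] - pw[, comp]
    expect_gte(mean(d), -2 * sd(d) / sqrt(nrow(pw)))
  }
})
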