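test_that("statistics match a direct hand computation", {
  # 4 groups of 3; reference last.  Expected values computed from the
  # definition: pooled s^2 = total within-group SS / (12 - 4), then
  # T_i = (mean_i - mean_ref) / (s * sqrt(1/3 + 1/3)).
  g1 <- c(1, 2, 3); g2 <- c(0, 0, 1); g3 <- c(5, 5, 5); ref <- c(0, 1, 2)
  x <- matrix(c(g1, g2, g3, ref), nrow = 1)
  d <- group_design(rep(c("g1", "g2", "g3", "ref"), each = 3), "ref")
  st <- dunnett_statistics(x, d)
  ss <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) +
    sum((g3 - mean(g3))^2) + sum((ref - mean(ref))^2)
  s <- sqrt(ss / 8)
  se <- s * sqrt(1 / 3 + 1 / 3)
  expect_equal(st$df, 8)
  expect_equal(unname(st$t[1, ]),
               c(mean(g1) - 1, mean(g2) - 1, mean(g3) - 1) / se)
  expect_false(st$undefined[1])
})

test_that("identical group means give zero statistics; constant features are flagged", {
  x <- rbind(rep(c(3, 4, 5), 4),          # same values in every group
             rep(7, 12))                  # constant: zero pooled variance
  d <- group_design(rep(c("a", "b", "c", "ref"), each = 3), "ref")
  st <- dunnett_statistics(x, d)
  expect_equal(unname(st$t[1, ]), c(0, 0, 0))
  expect_true(st$undefined[2])
  m <- dunnett_null_model(d)
  p <- screening_pvalue(st, m)
  expect_equal(unname(p), c(1, 1))        # zero max-|T| and undefined both p=1
})

test_that("balanced many-to-one null correlation is 1/2; unbalanced follows the product form", {
  m <- dunnett_null_model(n = c(10, 10, 10, 10))
  expect_equal(m$df, 36)
  expect_equal(m$rho[upper.tri(m$rho)], rep(0.5, 3))
  mu <- dunnett_null_model(n = c(4, 9, 6))
  g <- sqrt(c(4 / 10, 9 / 15))
  expect_equal(mu$rho[1, 2], g[1] * g[2])
  expect_true(isSymmetric(mu$rho))
  ev <- eigen(mu$rho, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > 0)
})

test_that("tail probability has the right limits and monotonicity", {
  m <- dunnett_null_model(n = c(10, 10, 10, 10))
  expect_equal(dunnett_tail(0, m), 1)
  cs <- seq(0, 8, by = 0.25)
  p <- dunnett_tail(cs, m)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0 & p <= 1))
  # q = 1 reduces to the two-sided Student tail exactly
  m1 <- dunnett_null_model(n = c(6, 6))
  expect_equal(dunnett_tail(cs, m1), 2 * pt(-cs, 10), tolerance = 1e-12)
})

test_that("quadrature agrees with an independent Monte-Carlo multivariate-t oracle", {
  m <- dunnett_null_model(n = c(10, 10, 10, 10))
  for (cc in c(1, 2.5, 3.5)) {
    mc <- mc_max_abs_tail(cc, equicorr(3, 0.5), 36, draws = 2e5, seed = 99)
    expect_lt(abs(dunnett_tail(cc, m) - mc$p), 3 * mc$se)
  }
})

test_that("quadrature agrees with mvtnorm's multivariate-t rectangle probability", {
  m <- dunnett_null_model(n = c(10, 10, 10, 10))
  for (cc in c(1.5, 3)) {
    ref <- 1 - mvtnorm::pmvt(lower = rep(-cc, 3), upper = rep(cc, 3), df = 36,
                             corr = equicorr(3, 0.5),
                             algorithm = mvtnorm::GenzBretz(abseps = 1e-6))
    expect_lt(abs(dunnett_tail(cc, m) - as.numeric(ref)), 5e-5)
  }
})

test_that("Monte-Carlo fallback for non-product correlations is seeded and close to quadrature", {
  # product-form rho given only as a matrix: exercises the MC path
  mq <- dunnett_null_model(n = c(10, 10, 10, 10))
  mmc <- dunnett_null_model(rho = equicorr(3, 0.5), df = 36)
  p1 <- dunnett_tail(2.5, mmc, mc_draws = 1e5, mc_seed = 7)
  p2 <- dunnett_tail(2.5, mmc, mc_draws = 1e5, mc_seed = 7)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_lt(abs(as.numeric(p1) - dunnett_tail(2.5, mq)),
            3 * attr(p1, "mc_se"))
})

test_that("screening p equals the pairwise-adjusted p at the max |T| and dominates Bonferroni", {
  toy <- toy_dataset(m = 40, shifts = c(2, 0, -1), seed = 8)
  st <- dunnett_statistics(toy$x, toy$design)
  mod <- dunnett_null_model(toy$design)
  p <- screening_pvalue(st, mod)
  tmax <- apply(abs(st$t), 1, max)
  expect_equal(unname(p), dunnett_pairwise_pvalue(tmax, mod))
  # Dunnett-adjusted p never exceeds q * two-sided t p (Bonferroni)
  tg <- seq(0.1, 6, by = 0.1)
  expect_true(all(dunnett_tail(tg, mod) <= pmin(1, 3 * 2 * pt(-tg, mod$df)) + 1e-12))
})

test_that("spline-accelerated tail matches the exact quadrature", {
  mod <- dunnett_null_model(n = c(10, 10, 10, 10))
  f <- dunnett_tail_fun(mod)
  set.seed(2)
  cs <- c(0, runif(300, 0, 9), 12)
  expect_lt(max(abs(f(cs) - dunnett_tail(cs, mod))), 2e-6)
})

test_that("screening p-values are uniform under the global null", {
  sim <- simulate_dataset(m = 10000, n = 10, q = 3, pi1 = 0, seed = 314)
  st <- dunnett_statistics(sim$x, sim$design, validated = TRUE)
  mod <- dunnett_null_model(sim$design)
  p <- screening_pvalue(st, mod, tail_fun = dunnett_tail_fun(mod))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})
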