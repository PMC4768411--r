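# Independent Monte-Carlo oracle for P(max_i |T_i| >= c) under a central
# multivariate t: samples the correlated normal numerator through a Cholesky
# factor and divides by an independent chi factor.  Deliberately shares no
# code with the package's quadrature.
mc_max_abs_tail <- function(cc, rho, df, draws = 2e5, seed = 1L) {
  set.seed(seed)
  q <- nrow(rho)
  Z <- matrix(rnorm(draws * q), draws) %*% chol(rho)
  W <- sqrt(rchisq(draws, df) / df)
  Tmax <- do.call(pmax, as.data.frame(abs(Z))) / W
  p <- mean(Tmax >= cc)
  list(p = p, se = sqrt(p * (1 - p) / draws))
}

equicorr <- function(q, r) {
  m <- matrix(r, q, q)
  diag(m) <- 1
  m
}

# Small many-to-one dataset with a known layout: 4 groups of `n`, reference
# last, optional per-group mean shifts for the first feature.
toy_dataset <- function(m = 20, n = 5, shifts = c(0, 0, 0), seed = 1L,
                        sd = 1) {
  set.seed(seed)
  x <- matrix(rnorm(m * 4 * n, sd = sd), m)
  for (g in 1:3) x[1, ((g - 1) * n + 1):(g * n)] <- x[1, ((g - 1) * n + 1):(g * n)] + shifts[g]
  rownames(x) <- paste0("f", seq_len(m))
  list(x = x, design = group_design(rep(c("a", "b", "c", "ref"), each = n),
                                    "ref"))
}
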