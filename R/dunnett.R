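#' Null model for Dunnett many-to-one statistics
#'
#' The joint null distribution of the standardized many-to-one mean
#' differences is a central q-variate t with the pooled degrees of freedom
#' and correlation `r_ik = gamma_i * gamma_k`, where
#' `gamma_i = sqrt(n_i / (n_i + n_0))` and `n_0` is the reference-group size.
#' For a balanced design all off-diagonal correlations equal 1/2.
#'
#' @param design a [group_design()] object, or `NULL` when `n` or `rho` is
#'   given directly.
#' @param n per-group sample sizes with the reference group **last**
#'   (alternative to `design`).
#' @param df pooled degrees of freedom; required with `rho`, derived as
#'   `sum(n) - length(n)` otherwise.
#' @param rho an explicit q x q correlation matrix for non-standard models.
#'   When `rho` is not of the many-to-one product form, tail probabilities
#'   fall back to Monte-Carlo evaluation (see [dunnett_tail()]).
#' @return An object of class `mdfdr_null_model` with elements `q`, `df`,
#'   `rho`, and `gamma` (`NULL` when only an arbitrary `rho` was supplied).
#' @examples
#' m <- dunnett_null_model(n = c(10, 10, 10, 10))
#' m$rho  # all off-diagonal entries 1/2
#' @export
dunnett_null_model <- function(design = NULL, n = NULL, df = NULL, rho = NULL) {
  if (!is.null(design)) {
    stopifnot(inherits(design, "mdfdr_design"))
    n <- design$n
  }
  if (!is.null(n)) {
    if (length(n) < 2L || any(n < 2)) stop("need >= 2 groups of size >= 2")
    p <- length(n)
    n0 <- n[p]
    ni <- n[-p]
    gamma <- sqrt(ni / (ni + n0))
    rho <- outer(gamma, gamma)
    diag(rho) <- 1
    if (is.null(df)) df <- sum(n) - p
    q <- p - 1L
  } else if (!is.null(rho)) {
    rho <- as.matrix(rho)
    if (is.null(df)) stop("'df' is required when only 'rho' is given")
    if (!isSymmetric(unname(rho)) || any(abs(diag(rho) - 1) > 1e-12))
      stop("'rho' must be a symmetric correlation matrix with unit diagonal")
    if (min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop("'rho' must be positive semi-definite")
    q <- nrow(rho)
    gamma <- NULL
  } else stop("supply 'design', 'n', or 'rho'")
  if (df <= 0) stop("pooled degrees of freedom must be positive")
  structure(list(q = as.integer(q), df = df, rho = unname(rho), gamma = gamma),
            class = "mdfdr_null_model")
}

#' Dunnett many-to-one test statistics
#'
#' For each feature j and experimental group i, computes
#' `T_ij = (mean_i - mean_ref) / (s_j * sqrt(1/n_i + 1/n_ref))`,
#' where `s_j^2` is the within-group variance pooled across all `p` groups
#' on `sum(n) - p` degrees of freedom. The sign convention is experimental
#' minus reference, so a positive statistic means higher expression in the
#' experimental group ("up").
#'
#' @param x numeric features-by-samples matrix.
#' @param design a [group_design()] object.
#' @param validated set `TRUE` to skip re-validation when the pair has
#'   already passed [validate_inputs()].
#' @return An object of class `mdfdr_stats`: list with `t` (m x q matrix,
#'   columns named after the experimental groups), `df`, `s` (pooled
#'   within-group standard deviation per feature), `undefined` (logical,
#'   features constant across all samples, whose statistics are not
#'   estimable), `feature_ids` and `design`.
#' @details Features with zero pooled variance carry no evidence and cannot
#'   be standardized; their statistics are set to 0 and flagged in
#'   `undefined`, and [screening_pvalue()] assigns them p = 1 so they are
#'   never selected.
#' @export
dunnett_statistics <- function(x, design, validated = FALSE) {
  if (!validated) {
    v <- validate_inputs(x, design)
    x <- v$x
    design <- v$design
  }
  groups <- design$groups
  p <- design$p
  n <- design$n
  # per-group means and within-group sums of squares, vectorized over features
  idx <- lapply(groups, function(g) which(design$group_labels == g))
  means <- vapply(idx, function(ii) rowMeans(x[, ii, drop = FALSE]),
                  numeric(nrow(x)))
  if (nrow(x) == 1L) means <- matrix(means, nrow = 1L)
  ss <- 0
  for (g in seq_len(p)) {
    xg <- x[, idx[[g]], drop = FALSE]
    ss <- ss + rowSums((xg - means[, g])^2)
  }
  df <- sum(n) - p
  s2 <- ss / df
  undefined <- s2 <= 0
  s <- sqrt(s2)
  n0 <- n[p]
  tmat <- matrix(0, nrow(x), p - 1L,
                 dimnames = list(rownames(x), groups[-p]))
  for (i in seq_len(p - 1L)) {
    se <- s * sqrt(1 / n[i] + 1 / n0)
    ti <- (means[, i] - means[, p]) / se
    ti[undefined] <- 0
    tmat[, i] <- ti
  }
  structure(list(t = tmat, df = df, s = s, undefined = undefined,
                 feature_ids = rownames(x), design = design),
            class = "mdfdr_stats")
}

# Gauss-Legendre nodes/weights for the 2-D conditional-independence
# representation of the max-|T| tail: conditioning on the reference-group
# latent variable Z0 and the pooled scale W = sqrt(chi^2_df / df) makes the
# q components independent.  Node counts of 64 x 64 give absolute errors
# below 1e-10 for df >= 2 (checked against node doubling).
.dunnett_quad_nodes <- function(df, nz = 64L, nw = 64L) {
  gz <- pracma::gaussLegendre(nz, -9, 9)
  wz <- gz$w * dnorm(gz$x)
  wlo <- sqrt(qchisq(1e-15, df) / df)
  whi <- sqrt(qchisq(1 - 1e-15, df) / df)
  gw <- pracma::gaussLegendre(nw, wlo, whi)
  # density of W: f(w) = 2 w df dchisq(df w^2, df)
  ww <- gw$w * 2 * gw$x * df * dchisq(df * gw$x^2, df)
  list(z = rep(gz$x, times = nw), w = rep(gw$x, each = nz),
       wt = as.vector(outer(wz, ww)))
}

.dunnett_tail_quad <- function(cvec, gamma, df, chunk = 128L) {
  nodes <- .dunnett_quad_nodes(df)
  s <- sqrt(1 - gamma^2)
  ng <- length(nodes$z)
  out <- numeric(length(cvec))
  for (st in seq(1L, length(cvec), by = chunk)) {
    ii <- st:min(st + chunk - 1L, length(cvec))
    cw <- outer(cvec[ii], nodes$w)
    P <- matrix(1, length(ii), ng)
    for (k in seq_along(gamma)) {
      gz <- matrix(gamma[k] * nodes$z, length(ii), ng, byrow = TRUE)
      P <- P * (pnorm((cw - gz) / s[k]) - pnorm((-cw - gz) / s[k]))
    }
    out[ii] <- 1 - as.vector(P %*% nodes$wt)
  }
  pmin(pmax(out, 0), 1)
}

.dunnett_tail_mc <- function(cvec, rho, df, draws = 2e5, seed = 1L) {
  L <- chol(rho + diag(1e-12, nrow(rho)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  Z <- matrix(rnorm(draws * nrow(rho)), draws) %*% L
  Tmax <- apply(abs(Z / sqrt(rchisq(draws, df) / df)), 1L, max)
  est <- vapply(cvec, function(cc) mean(Tmax >= cc), numeric(1))
  attr(est, "mc_se") <- sqrt(est * (1 - est) / draws)
  est
}

#' Tail probability of the maximum absolute Dunnett statistic
#'
#' Computes `P(max_i |T_i| >= c)` under the central multivariate t null
#' model of the many-to-one comparisons. For the product-correlation model
#' implied by a design (always the case for models built from group sizes)
#' the probability is evaluated by deterministic two-dimensional
#' Gauss-Legendre quadrature over the reference-group latent variable and
#' the pooled-scale variable, with absolute accuracy better than 1e-8.
#' For an arbitrary correlation matrix the function falls back to
#' Monte-Carlo evaluation with a fixed seed; the Monte-Carlo standard error
#' is attached as attribute `"mc_se"`.
#'
#' @param c vector of non-negative thresholds.
#' @param model a [dunnett_null_model()].
#' @param mc_draws,mc_seed Monte-Carlo settings for the fallback path.
#' @return Vector of tail probabilities in `[0, 1]`, non-increasing in `c`.
#' @examples
#' m <- dunnett_null_model(n = c(10, 10, 10, 10))
#' dunnett_tail(c(0, 2.5), m)
#' @export
dunnett_tail <- function(c, model, mc_draws = 2e5, mc_seed = 1L) {
  stopifnot(inherits(model, "mdfdr_null_model"), all(c >= 0))
  if (model$q == 1L) return(2 * pt(-c, model$df))
  if (!is.null(model$gamma))
    .dunnett_tail_quad(c, model$gamma, model$df)
  else
    .dunnett_tail_mc(c, model$rho, model$df, draws = mc_draws, seed = mc_seed)
}

#' Fast evaluator for repeated Dunnett tail computations
#'
#' Precomputes the tail probability on a dense grid of thresholds and
#' returns a monotone spline interpolator. Useful when the same null model
#' is evaluated at many thousands of statistics (e.g. inside simulations);
#' the interpolation error is below 1e-6 in absolute value.
#'
#' @param model a [dunnett_null_model()] of the product-correlation form.
#' @param c_max upper end of the grid; thresholds above it map to the exact
#'   quadrature value at `c_max` (below 1e-12 for the default).
#' @return A function `f(c)` returning tail probabilities.
#' @export
dunnett_tail_fun <- function(model, c_max = 14) {
  stopifnot(inherits(model, "mdfdr_null_model"))
  if (model$q == 1L) return(function(c) 2 * pt(-c, model$df))
  if (is.null(model$gamma))
    stop("spline acceleration requires the many-to-one product correlation")
  grid <- c(seq(0, 3, by = 0.01), seq(3.02, 9, by = 0.02),
            seq(9.1, c_max, by = 0.1))
  tg <- .dunnett_tail_quad(grid, model$gamma, model$df)
  tg <- rev(cummax(rev(tg)))            # absorb numerical noise: nonincreasing
  keep <- !duplicated(tg)
  f <- splinefun(grid[keep], tg[keep], method = "monoH.FC")
  floorv <- tg[length(tg)]
  function(c) {
    out <- pmin(pmax(f(pmin(c, c_max)), floorv), 1)
    out
  }
}

#' Per-feature screening p-value from the maximum absolute statistic
#'
#' The screening hypothesis for a feature states that no experimental group
#' differs from the reference. Its p-value is the Dunnett max-|T| tail
#' probability evaluated at the feature's largest absolute statistic, giving
#' one p-value per feature for the selection step.
#'
#' @param stats an [dunnett_statistics()] result.
#' @param model a [dunnett_null_model()]; defaults to the model implied by
#'   the design stored in `stats`.
#' @param tail_fun optional evaluator from [dunnett_tail_fun()] to reuse
#'   across calls.
#' @return Numeric vector of p-values, one per feature; features with
#'   undefined statistics get p = 1.
#' @export
screening_pvalue <- function(stats, model = NULL, tail_fun = NULL) {
  stopifnot(inherits(stats, "mdfdr_stats"))
  if (is.null(model)) model <- dunnett_null_model(stats$design)
  tmax <- apply(abs(stats$t), 1L, max)
  p <- if (is.null(tail_fun)) dunnett_tail(tmax, model) else tail_fun(tmax)
  p <- as.numeric(p)
  p[stats$undefined] <- 1
  names(p) <- stats$feature_ids
  p
}

#' Single-step Dunnett-adjusted pairwise p-value
#'
#' The adjusted p-value of a single many-to-one comparison is the
#' probability, under the joint null, that the maximum absolute component
#' exceeds the observed absolute statistic — identical in form to the
#' screening tail, evaluated at `|t|`.
#'
#' @param t vector of observed statistics (any sign).
#' @param model a [dunnett_null_model()].
#' @inheritParams dunnett_tail
#' @return Adjusted p-values in `[0, 1]`, strictly decreasing in `|t|`.
#' @export
dunnett_pairwise_pvalue <- function(t, model, mc_draws = 2e5, mc_seed = 1L) {
  dunnett_tail(abs(t), model, mc_draws = mc_draws, mc_seed = mc_seed)
}
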