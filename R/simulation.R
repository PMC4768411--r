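#' Generate a synthetic many-to-one expression dataset
#'
#' Emulates the operating-characteristics study design: `q` experimental
#' groups plus a reference group (reference last), `n` samples per group,
#' `m` features with unit-variance Gaussian noise. A proportion `pi1` of
#' features is non-null: for those features each experimental-group mean is
#' drawn independently from `U(0, effect_max)` while the reference mean is
#' 0, so every non-null (feature, comparison) pair is truly up-regulated.
#' The remaining `m0 = round(m * (1 - pi1))` features have all means zero.
#'
#' Three correlation structures are available, each generated exactly by a
#' shared-factor construction (`sqrt(rho) * Z_shared + sqrt(1 - rho) * Z_own`):
#' \describe{
#'   \item{`independent`}{all entries independent.}
#'   \item{`within_sample`}{within a sample, any pair of features has
#'     correlation `rho`; distinct samples are independent.}
#'   \item{`within_feature`}{within a feature, any pair of samples has
#'     correlation `rho`; distinct features are independent.}
#' }
#'
#' @param m number of features.
#' @param n samples per group (balanced).
#' @param q number of experimental groups.
#' @param pi1 proportion of non-null features in `[0, 1]`.
#' @param structure correlation structure, see Details.
#' @param rho equicorrelation parameter in `[0, 1)`.
#' @param effect_max upper end of the uniform effect-size distribution.
#' @param seed optional integer seed.
#' @return A list with `x` (m x (q+1)n matrix), `design`
#'   ([group_design()], groups `grp1 ... grpq`, reference `"ref"`), and
#'   `truth`: list with `mu` (m x q matrix of true mean differences),
#'   `nonnull` (logical m x q) and `sign` (m x q, `+1` where non-null).
#' @export
simulate_dataset <- function(m = 1000, n = 10, q = 3, pi1 = 0.1,
                             structure = c("independent", "within_sample",
                                           "within_feature"),
                             rho = 0, effect_max = 2.5, seed = NULL) {
  structure <- match.arg(structure)
  stopifnot(m >= 1, n >= 2, q >= 1, pi1 >= 0, pi1 <= 1, rho >= 0, rho < 1)
  if (!is.null(seed)) set.seed(seed)
  p <- q + 1L
  N <- p * n
  m0 <- round(m * (1 - pi1))
  mu <- matrix(0, m, q)
  if (m0 < m)
    mu[(m0 + 1L):m, ] <- runif((m - m0) * q, 0, effect_max)
  mean_mat <- cbind(mu, 0)[, rep(seq_len(p), each = n), drop = FALSE]
  noise <- switch(structure,
    independent = matrix(rnorm(m * N), m, N),
    within_sample = {
      shared <- rnorm(N)                       # one factor per sample column
      sqrt(rho) * matrix(shared, m, N, byrow = TRUE) +
        sqrt(1 - rho) * matrix(rnorm(m * N), m, N)
    },
    within_feature = {
      shared <- rnorm(m)                       # one factor per feature row
      sqrt(rho) * matrix(shared, m, N) +
        sqrt(1 - rho) * matrix(rnorm(m * N), m, N)
    })
  x <- mean_mat + noise
  labels <- rep(c(paste0("grp", seq_len(q)), "ref"), each = n)
  rownames(x) <- paste0("feature_", seq_len(m))
  colnames(x) <- paste0("sample_", seq_len(N))
  design <- group_design(labels, reference = "ref")
  nonnull <- mu != 0
  list(x = x, design = design,
       truth = list(mu = mu, nonnull = nonnull,
                    sign = ifelse(nonnull, sign(mu), 0)))
}

#' Score one run against the simulation truth
#'
#' Every directional pairwise call is one discovery; a discovery is false
#' when it lands on a truly-null (feature, comparison) pair (type-I error)
#' or on a non-null pair with the wrong sign (directional error). The
#' realized mixed-directional false discovery proportion is the fraction of
#' false discoveries among all discoveries (0 when there are none), and the
#' realized power is the fraction of truly non-null pairs rejected with the
#' correct sign.
#'
#' @param result an [run_mdfdr()] result (or any object with a `calls`
#'   matrix over `{"up","down","none"}`).
#' @param truth the `truth` component of [simulate_dataset()].
#' @return List with `fdp` and `power`, both in `[0, 1]`.
#' @export
score_run <- function(result, truth) {
  calls <- if (is.matrix(result)) result else result$calls
  stopifnot(all(dim(calls) == dim(truth$nonnull)))
  disc <- calls != "none"
  call_sign <- matrix(0L, nrow(calls), ncol(calls))
  call_sign[calls == "up"] <- 1L
  call_sign[calls == "down"] <- -1L
  correct <- disc & truth$nonnull & (call_sign == truth$sign)
  false <- disc & !correct
  list(fdp = sum(false) / max(1, sum(disc)),
       power = sum(correct) / max(1, sum(truth$nonnull)))
}

.procedure_spec <- function(name) {
  switch(name,
    dunnett    = list(screening = "dunnett", pairwise = "dunnett",
                      src = "dunnett"),
    holm       = list(screening = "dunnett", pairwise = "holm",
                      src = "dunnett"),
    hochberg   = list(screening = "dunnett", pairwise = "hochberg",
                      src = "dunnett"),
    bonferroni = list(screening = "dunnett", pairwise = "bonferroni",
                      src = "dunnett"),
    guo        = list(screening = "bonferroni", pairwise = "bonferroni",
                      src = "raw"),
    stop("unknown procedure: ", name))
}

#' Estimate mdFDR and average power by simulation
#'
#' Replicates the operating-characteristics study: for each value of the
#' non-null proportion `pi1`, datasets are generated with
#' [simulate_dataset()] and all requested procedures are run on the *same*
#' replications (paired comparison), accumulating the realized
#' mixed-directional FDP and power from [score_run()].
#'
#' Procedures: `"dunnett"` (Dunnett screening + single-step Dunnett
#' pairwise), `"holm"`, `"hochberg"`, `"bonferroni"` (Dunnett screening +
#' the named step procedure on the Dunnett-adjusted pairwise p-values) and
#' `"guo"` (Bonferroni screening + Bonferroni pairwise on raw two-sided t
#' p-values).
#'
#' @param pi1 vector of non-null proportions (the x-axis of the study).
#' @param n_reps replications per `pi1` value.
#' @param procedures subset of the five procedure names.
#' @param m,n,q,structure,rho,effect_max passed to [simulate_dataset()].
#' @param alpha nominal mdFDR level.
#' @param seed root seed; per-replication seeds are drawn from it once, so
#'   results are reproducible and identical datasets are shared across
#'   procedures.
#' @param detail keep the per-replication FDP and power matrices? When
#'   `TRUE` they are attached as attribute `"reps"` (a list indexed by
#'   `pi1` with elements `fdp` and `power`, replications x procedures),
#'   enabling paired procedure comparisons.
#' @return A long-format `data.frame` with one row per (procedure, pi1):
#'   columns `procedure`, `structure`, `rho`, `pi1`, `mdfdr`, `power`,
#'   `se_mdfdr`, `se_power`, `n_reps`.
#' @export
simulate_operating_characteristics <- function(
    pi1 = seq(0.05, 0.5, by = 0.05), n_reps = 200,
    procedures = c("dunnett", "holm", "hochberg", "bonferroni", "guo"),
    m = 1000, n = 10, q = 3,
    structure = c("independent", "within_sample", "within_feature"),
    rho = 0, effect_max = 2.5, alpha = 0.05, seed = 1L, detail = FALSE) {
  structure <- match.arg(structure)
  procedures <- match.arg(procedures, several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max, length(pi1) * n_reps),
                      n_reps, length(pi1))
  sizes <- c(rep(n, q), n)
  model <- dunnett_null_model(n = sizes)
  tail_fun <- if (q > 1L) dunnett_tail_fun(model) else NULL
  specs <- lapply(procedures, .procedure_spec)
  out <- vector("list", length(pi1) * length(procedures))
  reps <- if (detail) setNames(vector("list", length(pi1)),
                               as.character(pi1)) else NULL
  k <- 0L
  for (a in seq_along(pi1)) {
    fdp <- matrix(NA_real_, n_reps, length(procedures))
    pow <- matrix(NA_real_, n_reps, length(procedures))
    for (r in seq_len(n_reps)) {
      sim <- simulate_dataset(m = m, n = n, q = q, pi1 = pi1[a],
                              structure = structure, rho = rho,
                              effect_max = effect_max,
                              seed = rep_seeds[r, a])
      stats <- dunnett_statistics(sim$x, sim$design, validated = TRUE)
      for (s in seq_along(specs)) {
        res <- .run_from_stats(stats, model, alpha,
                               specs[[s]]$screening, specs[[s]]$pairwise,
                               specs[[s]]$src, tail_fun)
        sc <- score_run(res, sim$truth)
        fdp[r, s] <- sc$fdp
        pow[r, s] <- sc$power
      }
    }
    if (detail) {
      colnames(fdp) <- colnames(pow) <- procedures
      reps[[a]] <- list(fdp = fdp, power = pow)
    }
    for (s in seq_along(procedures)) {
      k <- k + 1L
      out[[k]] <- data.frame(
        procedure = procedures[s], structure = structure, rho = rho,
        pi1 = pi1[a],
        mdfdr = mean(fdp[, s]), power = mean(pow[, s]),
        se_mdfdr = sd(fdp[, s]) / sqrt(n_reps),
        se_power = sd(pow[, s]) / sqrt(n_reps),
        n_reps = n_reps, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (detail) attr(res, "reps") <- reps
  res
}
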