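# Raw two-sided pooled-t p-values per (feature, comparison); inputs to the
# Holm/Hochberg/Bonferroni pairwise variants and to the Bonferroni screen.
.raw_t_pvalues <- function(stats) {
  p <- 2 * pt(-abs(stats$t), stats$df)
  p[stats$undefined, ] <- 1
  p
}

# Pairwise stage shared by all procedures: given per-feature pairwise
# p-values for the selected features, apply the named mdFWER procedure at
# the data-dependent level and assign directions by sign.
.pairwise_stage <- function(pairwise_p, signs, selected, level, method) {
  m <- nrow(signs); q <- ncol(signs)
  calls <- matrix("none", m, q, dimnames = dimnames(signs))
  if (length(selected) == 0L) return(calls)
  for (j in selected) {
    calls[j, ] <- switch(method,
      dunnett    = .directional_calls(pairwise_p[j, ] <= level, signs[j, ]),
      holm       = holm_directional(pairwise_p[j, ], signs[j, ], level),
      hochberg   = hochberg_directional(pairwise_p[j, ], signs[j, ], level),
      bonferroni = bonferroni_directional(pairwise_p[j, ], signs[j, ], level),
      stop("unknown pairwise method: ", method))
  }
  calls
}

# Core of the procedure operating on precomputed statistics, so that the
# simulator can run all five procedures on one dataset without recomputing
# means and variances.  pairwise_p_source: "dunnett" feeds the single-step
# Dunnett-adjusted p-values to the step-2 procedure, "raw" the unadjusted
# two-sided pooled-t p-values (the Bonferroni-screening comparator's choice).
.run_from_stats <- function(stats, model, alpha, screening, pairwise,
                            pairwise_p_source = "dunnett", tail_fun = NULL) {
  m <- nrow(stats$t)
  praw <- .raw_t_pvalues(stats)
  screening_p <- switch(screening,
    dunnett    = screening_pvalue(stats, model, tail_fun),
    bonferroni = setNames(bonferroni_screening_pvalue(praw), stats$feature_ids),
    stop("unknown screening method: ", screening))
  sel <- bh_select(screening_p, alpha)
  R <- sel$R
  level <- R * alpha / m
  pairwise_p <- matrix(NA_real_, m, ncol(stats$t), dimnames = dimnames(stats$t))
  if (R > 0L) {
    if (pairwise_p_source == "dunnett") {
      tsel <- abs(stats$t[sel$selected, , drop = FALSE])
      pv <- if (is.null(tail_fun)) dunnett_tail(as.vector(tsel), model)
            else tail_fun(as.vector(tsel))
      pairwise_p[sel$selected, ] <- pv
    } else {
      pairwise_p[sel$selected, ] <- praw[sel$selected, , drop = FALSE]
    }
    if (any(stats$undefined)) pairwise_p[stats$undefined, ] <- NA_real_
  }
  calls <- .pairwise_stage(pairwise_p, sign(stats$t), sel$selected, level,
                           pairwise)
  directed <- rowSums(calls != "none") > 0
  undirected <- setdiff(sel$selected, which(directed))
  structure(list(calls = calls,
                 pairwise_p = pairwise_p,
                 screening_p = screening_p,
                 t = stats$t,
                 selected = sel$selected,
                 R = R,
                 alpha = alpha,
                 level = level,
                 screening = screening,
                 pairwise = pairwise,
                 pairwise_p_source = pairwise_p_source,
                 undirected = undirected,
                 df = stats$df,
                 design = stats$design,
                 feature_ids = stats$feature_ids),
            class = "mdfdr_result")
}

#' Run the mdFDR-controlling testing procedure
#'
#' Executes the three-step algorithm on a features-by-samples matrix:
#' (1) per-feature screening p-values are selected by the Benjamini-Hochberg
#' step-up rule at level `alpha`, yielding `R` candidate features;
#' (2) within each selected feature, the pairwise comparisons against the
#' reference are tested at the data-dependent level `R * alpha / m` by the
#' chosen mixed-directional familywise error controlling procedure;
#' (3) each rejected comparison is called up- or down-regulated according
#' to the sign of its statistic. The combination controls the mixed
#' directional false discovery rate at `alpha`.
#'
#' The default (`screening = "dunnett"`, `pairwise = "dunnett"`) screens
#' with the max-|T| Dunnett tail probability and thresholds the single-step
#' Dunnett-adjusted pairwise p-values directly at `R * alpha / m`. The
#' `"holm"`, `"hochberg"` and `"bonferroni"` pairwise options apply the
#' named step procedure at that level to the p-values chosen by
#' `pairwise_p`: by default the Dunnett-adjusted p-values when screening is
#' `"dunnett"` (these variants are then dominated by the single-step
#' threshold, which is what makes the default procedure the most powerful
#' of the family), and the raw two-sided pooled-t p-values when screening
#' is `"bonferroni"`. `screening = "bonferroni"` with
#' `pairwise = "bonferroni"` therefore reproduces the Bonferroni-based
#' comparator procedure (Bonferroni global test, Bonferroni pairwise step
#' on raw p-values).
#'
#' @param x numeric features-by-samples matrix (row names = feature ids).
#' @param design a [group_design()] object.
#' @param alpha target mdFDR level in `(0, 1)`.
#' @param screening `"dunnett"` (max-|T| tail) or `"bonferroni"`
#'   (q times the smallest raw pairwise p).
#' @param pairwise `"dunnett"`, `"holm"`, `"hochberg"` or `"bonferroni"`.
#' @param pairwise_p which p-values feed the step-2 procedure:
#'   `"dunnett"` (single-step adjusted) or `"raw"` (two-sided pooled-t).
#'   Default follows the screening method, see Details. Ignored (always
#'   adjusted) when `pairwise = "dunnett"`.
#' @param tail_fun optional precomputed evaluator from [dunnett_tail_fun()];
#'   advanced use, for repeated runs under one design.
#' @return An object of class `mdfdr_result` with the m x q `calls` matrix
#'   over `{"up", "down", "none"}`, `pairwise_p` (NA for non-selected
#'   features), `screening_p`, `t`, `selected`, `R`, the realized pairwise
#'   `level`, and `undirected` (features selected in step 1 with no pairwise
#'   rejection; reported as not differentially expressed).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(50 * 12), 50)
#' x[1, 1:3] <- x[1, 1:3] + 8   # strong effect in group "a"
#' d <- group_design(rep(c("a", "b", "c", "ref"), each = 3), "ref")
#' fit <- run_mdfdr(x, d, alpha = 0.05)
#' fit$R
#' @export
run_mdfdr <- function(x, design, alpha = 0.05,
                      screening = c("dunnett", "bonferroni"),
                      pairwise = c("dunnett", "holm", "hochberg", "bonferroni"),
                      pairwise_p = NULL, tail_fun = NULL) {
  screening <- match.arg(screening)
  pairwise <- match.arg(pairwise)
  if (is.null(pairwise_p))
    pairwise_p <- if (screening == "dunnett") "dunnett" else "raw"
  pairwise_p <- match.arg(pairwise_p, c("dunnett", "raw"))
  if (pairwise == "dunnett") pairwise_p <- "dunnett"
  stopifnot(alpha > 0, alpha < 1)
  v <- validate_inputs(x, design)
  stats <- dunnett_statistics(v$x, v$design, validated = TRUE)
  model <- dunnett_null_model(v$design)
  .run_from_stats(stats, model, alpha, screening, pairwise, pairwise_p,
                  tail_fun)
}

#' @export
print.mdfdr_result <- function(x, ...) {
  m <- nrow(x$calls)
  cat("mdFDR procedure:", x$screening, "screening +", x$pairwise,
      "pairwise\n")
  cat(sprintf("alpha = %g; m = %d features; R = %d selected; pairwise level Ralpha/m = %.3g\n",
              x$alpha, m, x$R, x$level))
  up <- colSums(x$calls == "up"); dn <- colSums(x$calls == "down")
  for (k in seq_len(ncol(x$calls)))
    cat(sprintf("  %s vs %s: %d up, %d down\n", colnames(x$calls)[k],
                x$design$reference, up[k], dn[k]))
  cat(length(x$undirected),
      "feature(s) selected but with no pairwise rejection (reported not DE)\n")
  invisible(x)
}

#' Long-format decision table
#'
#' One record per (feature, comparison) with the statistic, screening and
#' pairwise p-values, the directional call, and whether the feature was
#' selected in the screening step. Features that were selected but received
#' no pairwise rejection are kept in the table (call `"none"`) so the
#' audit trail records them even though they are reported as not
#' differentially expressed.
#'
#' @param result an [run_mdfdr()] result.
#' @return A `data.frame` with columns `feature_id`, `comparison`, `t`,
#'   `screening_p`, `pairwise_p`, `call`, `selected`.
#' @export
decisions_table <- function(result) {
  stopifnot(inherits(result, "mdfdr_result"))
  m <- nrow(result$calls); q <- ncol(result$calls)
  sel <- logical(m); sel[result$selected] <- TRUE
  data.frame(
    feature_id = rep(result$feature_ids, times = q),
    comparison = rep(colnames(result$calls), each = m),
    t = as.vector(result$t),
    screening_p = rep(unname(result$screening_p), times = q),
    pairwise_p = as.vector(result$pairwise_p),
    call = as.vector(result$calls),
    selected = rep(sel, times = q),
    stringsAsFactors = FALSE)
}
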