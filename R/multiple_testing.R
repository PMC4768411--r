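#' Benjamini-Hochberg step-up selection of screening p-values
#'
#' Applies the BH step-up rule at level `alpha`: with sorted p-values
#' `p_(1) <= ... <= p_(m)`, rejects the `k` smallest where
#' `k = max{ i : p_(i) <= i * alpha / m }`. This is the selection step of
#' the mdFDR procedure; `R = k` then sets the data-dependent level
#' `R * alpha / m` of the pairwise stage.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param alpha selection level in `(0, 1)`.
#' @return A list of class `mdfdr_screening` with `selected` (integer
#'   indices of selected features), `R` (their number), `alpha`, and
#'   `screening_p` (the input, names preserved).
#' @examples
#' bh_select(c(0.001, 0.02, 0.04, 0.5), 0.05)$R  # 2
#' @export
bh_select <- function(p, alpha) {
  stopifnot(length(p) >= 1L, all(p >= 0 & p <= 1), alpha > 0, alpha < 1)
  selected <- which(p.adjust(p, method = "BH") <= alpha)
  structure(list(selected = selected, R = length(selected),
                 alpha = alpha, screening_p = p),
            class = "mdfdr_screening")
}

.directional_calls <- function(reject, signs) {
  calls <- rep("none", length(reject))
  calls[reject & signs > 0] <- "up"
  calls[reject & signs <= 0] <- "down"
  calls
}

#' Directional Holm procedure within a feature
#'
#' Step-down Holm over the `q` pairwise p-values of one feature at the
#' working level (the pipeline passes `R * alpha / m`): order p ascending
#' and reject while `p_(i) <= level / (q - i + 1)`. Rejected comparisons
#' are called `"up"` when the statistic is positive and `"down"` otherwise;
#' this augmented procedure controls the mixed-directional familywise error
#' within the feature.
#'
#' @param p q-vector of pairwise p-values.
#' @param signs q-vector of statistic signs (any numeric; sign is used).
#' @param level working significance level (> 0).
#' @return Character q-vector over `{"up", "down", "none"}`.
#' @export
holm_directional <- function(p, signs, level) {
  stopifnot(length(p) == length(signs), level > 0)
  .directional_calls(p.adjust(p, method = "holm") <= level, signs)
}

#' Directional Hochberg procedure within a feature
#'
#' Step-up counterpart of [holm_directional()]: find the largest `i` with
#' `p_(i) <= level / (q - i + 1)` and reject it together with all smaller
#' p-values; directions by the sign of the statistic.
#'
#' @inheritParams holm_directional
#' @return Character q-vector over `{"up", "down", "none"}`.
#' @export
hochberg_directional <- function(p, signs, level) {
  stopifnot(length(p) == length(signs), level > 0)
  .directional_calls(p.adjust(p, method = "hochberg") <= level, signs)
}

#' Directional Bonferroni procedure within a feature
#'
#' Rejects comparison `i` iff `p_i <= level / q`; directions by sign.
#'
#' @inheritParams holm_directional
#' @return Character q-vector over `{"up", "down", "none"}`.
#' @export
bonferroni_directional <- function(p, signs, level) {
  stopifnot(length(p) == length(signs), level > 0)
  .directional_calls(p.adjust(p, method = "bonferroni") <= level, signs)
}

#' Bonferroni global screening p-value
#'
#' The screening p-value of the Bonferroni global test used by the
#' Bonferroni-screening comparator: `min(1, q * min_i p_i)` over the raw
#' two-sided pairwise p-values of one feature. Combining this screening
#' test with the directional Bonferroni pairwise step reproduces the
#' earlier Bonferroni-based mdFDR procedure against which the Dunnett
#' instantiation is compared.
#'
#' @param p q-vector (or m x q matrix, handled row-wise) of raw two-sided
#'   pairwise p-values.
#' @return Scalar (or m-vector) of screening p-values.
#' @export
bonferroni_screening_pvalue <- function(p) {
  if (is.matrix(p)) return(pmin(1, ncol(p) * apply(p, 1L, min)))
  pmin(1, length(p) * min(p))
}
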