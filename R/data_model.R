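#' Describe the group structure of a many-to-one design
#'
#' Builds the sample-to-group map used throughout the package: one label per
#' sample column, one designated reference group, and `q` experimental groups
#' that are each compared against the reference (`p = q + 1` groups in total).
#'
#' @param group_labels character vector, one group label per sample column of
#'   the expression matrix.
#' @param reference single string naming the reference group; must occur in
#'   `group_labels`.
#' @return An object of class `mdfdr_design`: a list with elements
#'   `group_labels`, `reference`, `groups` (experimental groups in order of
#'   first appearance, then the reference last), `n` (named per-group sample
#'   counts in that order), `q`, `p` and `df` (pooled degrees of freedom,
#'   `sum(n) - p`).
#' @details Every group must contain at least two samples so that the pooled
#'   within-group variance has positive degrees of freedom.
#' @examples
#' d <- group_design(rep(c("small", "medium", "large", "normal"), each = 10),
#'                   reference = "normal")
#' d$q   # 3 comparisons
#' d$df  # 36
#' @export
group_design <- function(group_labels, reference) {
  group_labels <- as.character(group_labels)
  if (anyNA(group_labels)) stop("group labels must not contain NA")
  if (length(reference) != 1L || !reference %in% group_labels)
    stop("'reference' must name exactly one group present in 'group_labels'")
  exp_groups <- setdiff(unique(group_labels), reference)
  if (length(exp_groups) < 1L)
    stop("need at least one experimental group besides the reference")
  groups <- c(exp_groups, reference)
  n <- vapply(groups, function(g) sum(group_labels == g), integer(1))
  if (any(n < 2L))
    stop("every group needs at least 2 samples (pooled variance requires ",
         "positive within-group degrees of freedom); offending group(s): ",
         paste(groups[n < 2L], collapse = ", "))
  p <- length(groups)
  structure(list(group_labels = group_labels,
                 reference = reference,
                 groups = groups,
                 n = n,
                 q = p - 1L,
                 p = p,
                 df = sum(n) - p),
            class = "mdfdr_design")
}

#' @export
print.mdfdr_design <- function(x, ...) {
  cat("Many-to-one design:", x$q, "experimental group(s) vs reference '",
      x$reference, "'\n", sep = "")
  print(x$n)
  cat("pooled df:", x$df, "\n")
  invisible(x)
}

#' Validate and canonicalize an expression matrix and its design
#'
#' Checks the features-by-samples matrix against the design and reorders the
#' sample columns so that groups are contiguous with the reference group last.
#' The reordering is idempotent and has no effect on any downstream statistic;
#' it only fixes the internal column convention.
#'
#' @param x numeric matrix, features in rows, samples in columns. Row names
#'   are used as feature identifiers; missing row names are replaced by
#'   `feature_1 ... feature_m`.
#' @param design an [group_design()] object whose `group_labels` correspond to
#'   the columns of `x` in order.
#' @return A list with elements `x` (canonicalized matrix) and `design`
#'   (with relabelled `group_labels` matching the new column order).
#' @details Missing values are rejected rather than imputed: the degrees-of-
#'   freedom bookkeeping of the pooled variance assumes complete data.
#'   Duplicate feature identifiers are rejected.
#' @export
validate_inputs <- function(x, design) {
  if (!inherits(design, "mdfdr_design")) stop("'design' must be a group_design()")
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (nrow(x) < 1L) stop("expression matrix must have at least one feature")
  if (ncol(x) != length(design$group_labels))
    stop("matrix has ", ncol(x), " columns but the design describes ",
         length(design$group_labels), " samples")
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values; ",
         "these are rejected, not imputed")
  if (is.null(rownames(x)))
    rownames(x) <- paste0("feature_", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  ord <- order(match(design$group_labels, design$groups))
  x <- x[, ord, drop = FALSE]
  design$group_labels <- design$group_labels[ord]
  list(x = x, design = design)
}
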