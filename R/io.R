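.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a features-by-samples expression matrix from delimited text
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers. The delimiter is chosen by extension: comma for `.csv`,
#' tab otherwise. Feature order is preserved.
#'
#' @param path file path.
#' @return Numeric matrix with feature ids as row names and sample ids as
#'   column names.
#' @export
read_expression_matrix <- function(path) {
  d <- read.table(path, header = TRUE, sep = .delim_for(path),
                  check.names = FALSE, stringsAsFactors = FALSE,
                  quote = "\"", comment.char = "")
  if (ncol(d) < 2L) stop("matrix file needs a feature-id column plus samples")
  ids <- as.character(d[[1L]])
  vals <- d[, -1L, drop = FALSE]
  for (k in seq_along(vals)) {
    if (!is.numeric(vals[[k]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[k]]))) &
                     !is.na(vals[[k]]))
      stop("non-numeric value in column '", names(vals)[k], "', row ",
           if (length(bad)) bad[1L] else "?", " of ", path)
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- ids
  x
}

#' Read a sample-to-group assignment file
#'
#' Two-column delimited file (sample id, group label), with or without a
#' header; the reference group is named by the caller.
#'
#' @param path file path.
#' @param reference label of the reference group.
#' @param sample_ids optional sample ids (e.g. matrix column names) used to
#'   order the assignments; required if the file order differs from the
#'   matrix column order.
#' @return A [group_design()] object.
#' @export
read_group_design <- function(path, reference, sample_ids = NULL) {
  d <- read.table(path, header = FALSE, sep = .delim_for(path),
                  check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("group file needs two columns: sample id, group")
  # tolerate a header line
  if (identical(tolower(d[1, 2]), "group")) d <- d[-1L, , drop = FALSE]
  samples <- as.character(d[[1L]])
  labels <- as.character(d[[2L]])
  if (!is.null(sample_ids)) {
    pos <- match(sample_ids, samples)
    if (anyNA(pos))
      stop("samples missing from group file: ",
           paste(sample_ids[is.na(pos)], collapse = ", "))
    labels <- labels[pos]
  }
  group_design(labels, reference)
}

#' Write / read a decision table
#'
#' Tab-separated, fixed column order, p-values written with 17 significant
#' digits so that calls round-trip exactly.
#'
#' @param table a [decisions_table()] data frame.
#' @param path output path.
#' @return `write_results` invisibly returns `path`; `read_results` returns
#'   the data frame.
#' @export
write_results <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 17,
                                                   format = "g"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE, quote = "", comment.char = "",
             encoding = "UTF-8",
             colClasses = c(feature_id = "character", comparison = "character",
                            t = "numeric", screening_p = "numeric",
                            pairwise_p = "numeric", call = "character",
                            selected = "logical"))
}

#' Per-comparison and per-subset summary of directional calls
#'
#' Counts up/down calls per comparison and tabulates how many features are
#' significant in each non-empty subset of comparisons (the `2^q - 1` cells
#' of a Venn diagram over comparisons). The cells partition the features
#' with at least one directional call, so cell counts sum to that total.
#'
#' @param x an [run_mdfdr()] result or a [decisions_table()] data frame.
#' @return List with `per_comparison` (data frame: comparison, up, down)
#'   and `venn` (named integer vector; names are `+`-joined comparison
#'   subsets), plus `n_directed`, `n_selected` and `n_undirected` (the
#'   selected-but-no-pairwise-rejection count).
#' @export
summarize_by_comparison <- function(x) {
  tab <- if (inherits(x, "mdfdr_result")) decisions_table(x) else x
  stopifnot(all(c("feature_id", "comparison", "call", "selected") %in%
                  names(tab)))
  comps <- unique(tab$comparison)
  per <- data.frame(
    comparison = comps,
    up = vapply(comps, function(k) sum(tab$call == "up" &
                                         tab$comparison == k), integer(1)),
    down = vapply(comps, function(k) sum(tab$call == "down" &
                                           tab$comparison == k), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  called <- tab[tab$call != "none", , drop = FALSE]
  sets <- tapply(called$comparison, called$feature_id, function(v)
    paste(comps[sort(match(unique(v), comps))], collapse = "+"))
  venn_counts <- table(factor(unname(sets)))
  venn <- setNames(as.integer(venn_counts), names(venn_counts))
  sel_features <- unique(tab$feature_id[tab$selected])
  directed_features <- unique(called$feature_id)
  list(per_comparison = per,
       venn = venn,
       n_directed = length(directed_features),
       n_selected = length(sel_features),
       n_undirected = length(setdiff(sel_features, directed_features)))
}
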