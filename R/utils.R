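# Internal helpers shared across modules. A peak-area table is a wide tibble:
# first column `sample_id`, remaining columns one numeric vector per
# metabolite (non-negative peak areas, NA = missing).

assert_peak_tbl <- function(x, arg = "matrix") {
  if (!is.data.frame(x) || names(x)[1] != "sample_id") {
    abort(sprintf("`%s` must be a data frame whose first column is `sample_id`.", arg))
  }
  if (anyDuplicated(x$sample_id)) {
    dup <- unique(x$sample_id[duplicated(x$sample_id)])
    abort(sprintf("Duplicate sample ids: %s", paste(dup, collapse = ", ")))
  }
  met <- names(x)[-1]
  if (anyDuplicated(met)) {
    abort(sprintf("Duplicate metabolite ids: %s",
                  paste(unique(met[duplicated(met)]), collapse = ", ")))
  }
  invisible(x)
}

# wide tibble -> numeric matrix (rows = samples)
pa_matrix <- function(x) {
  assert_peak_tbl(x)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$sample_id
  m
}

# numeric matrix -> wide tibble
pa_tibble <- function(m) {
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(sample_id = rownames(m)), out)
  out
}

metabolite_ids <- function(x) names(x)[-1]

add_provenance <- function(x, step) {
  attr(x, "provenance") <- c(attr(x, "provenance"), step)
  x
}

#' Normalization provenance of a peak-area table
#'
#' @param x a peak-area or scaled tibble produced by this package.
#' @return character vector of processing steps applied so far.
#' @export
provenance <- function(x) attr(x, "provenance") %||% character()

# Align a two-class labelling with the rows of a peak table.
# `labels` is a data frame (sample_id, class) or a named character vector.
align_classes <- function(sample_ids, labels) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "class") %in% names(labels))) {
      abort("`labels` data frame needs columns `sample_id` and `class`.")
    }
    lab <- setNames(as.character(labels$class), labels$sample_id)
  } else if (!is.null(names(labels))) {
    lab <- setNames(as.character(labels), names(labels))
  } else {
    abort("`labels` must be a (sample_id, class) data frame or a named vector.")
  }
  missing <- setdiff(sample_ids, names(lab))
  if (length(missing)) {
    abort(sprintf("No class label for samples: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  cls <- factor(lab[sample_ids])
  if (nlevels(cls) != 2) {
    abort(sprintf("Exactly two classes required, got %d (%s).",
                  nlevels(cls), paste(levels(cls), collapse = ", ")))
  }
  if (any(table(cls) < 1)) abort("Both classes must be non-empty.")
  cls
}

#' Build a two-class labelling from a sample annotation table
#'
#' Convenience for the rankers: pick an annotation column and the two level
#' values that define classes A and B.
#'
#' @param samples sample annotation tibble (must contain `sample_id`).
#' @param var name of the annotation column holding the class variable.
#' @param a,b the two level values to compare.
#' @return tibble with columns `sample_id`, `class`, restricted to samples in
#'   either level.
#' @export
class_labels <- function(samples, var, a, b) {
  if (!var %in% names(samples)) abort(sprintf("No column `%s` in samples.", var))
  out <- samples[samples[[var]] %in% c(a, b), c("sample_id", var)]
  names(out) <- c("sample_id", "class")
  as_tibble(out)
}

# Rank scores descending (rank 1 = most important); ties broken by higher
# secondary magnitude, then lexicographic metabolite id, so every ranking is
# a deterministic permutation of 1..p.
score_ranks <- function(score, ids, secondary = NULL) {
  secondary <- secondary %||% score
  ord <- order(-score, -abs(secondary), ids)
  rk <- integer(length(score))
  rk[ord] <- seq_along(score)
  rk
}

rank_tbl <- function(method, ids, score, rank, extra = NULL) {
  out <- tibble(method = method, metabolite_id = ids, score = score, rank = rank)
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out
}

# require a complete (no NA) scaled matrix for the rankers
ranker_matrix <- function(x) {
  m <- pa_matrix(x)
  if (ncol(m) < 1) abort("Need at least one metabolite.")
  if (anyNA(m)) {
    abort("Rankers require complete data; impute missing values first (see `impute_missing()`).")
  }
  m
}
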