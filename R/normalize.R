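#' Normalize peak areas to a pooled reference
#'
#' Each metabolite is divided by the median of its values over the reference
#' samples, so reference medians become 1. When `samples` carries a `batch`
#' column and `by_batch = TRUE`, divisors are computed within batch from the
#' batch's own reference samples. The default reference set is every
#' pre-intervention (`timepoint == "RO"`) sample, the only shared
#' pre-intervention state in the design; pass `reference_samples` for an
#' explicit list.
#'
#' Metabolites whose reference median is zero or not estimable (all missing)
#' in any batch are excluded with a warning; their ids are recorded in the
#' `excluded` attribute.
#'
#' @param matrix wide peak-area tibble.
#' @param samples sample annotation tibble (needs `sample_id`; `timepoint`
#'   and `batch` used when applicable).
#' @param reference_samples optional explicit character vector of reference
#'   sample ids; overrides the RO default.
#' @param by_batch compute divisors per batch (default `TRUE`).
#' @return normalized peak-area tibble.
#' @export
reference_normalize <- function(matrix, samples, reference_samples = NULL,
                                by_batch = TRUE) {
  assert_peak_tbl(matrix)
  m <- pa_matrix(matrix)
  if (is.null(reference_samples)) {
    if (!"timepoint" %in% names(samples)) {
      abort("Default reference needs a `timepoint` column; or pass `reference_samples`.")
    }
    reference_samples <- samples$sample_id[samples$timepoint == "RO"]
  }
  reference_samples <- intersect(reference_samples, rownames(m))
  if (length(reference_samples) == 0) abort("Reference sample set is empty.")
  batch <- if (by_batch && "batch" %in% names(samples)) {
    setNames(samples$batch, samples$sample_id)[rownames(m)]
  } else {
    rep("all", nrow(m))
  }
  if (anyNA(batch)) abort("Every matrix sample must appear in `samples`.")
  out <- m
  bad <- character()
  for (b in unique(batch)) {
    rows <- batch == b
    ref <- intersect(reference_samples, rownames(m)[rows])
    if (length(ref) == 0) {
      abort(sprintf("Batch `%s` has no reference samples.", b))
    }
    med <- apply(m[ref, , drop = FALSE], 2, median, na.rm = TRUE)
    bad <- union(bad, colnames(m)[!is.finite(med) | med <= 0])
    out[rows, ] <- sweep(m[rows, , drop = FALSE], 2, med, `/`)
  }
  if (length(bad)) {
    warn(sprintf("Excluding %d metabolite(s) with non-positive or missing reference median: %s",
                 length(bad), paste(head(bad, 10), collapse = ", ")))
    out <- out[, setdiff(colnames(out), bad), drop = FALSE]
  }
  res <- pa_tibble(out)
  attr(res, "provenance") <- attr(matrix, "provenance")
  attr(res, "excluded") <- bad
  add_provenance(res, sprintf("reference_normalize: %d reference samples, by_batch=%s",
                              length(reference_samples), by_batch))
}

#' Impute missing peak areas
#'
#' The downstream rankers require complete data. `"halfmin"` (default)
#' replaces missing entries of a metabolite with half its minimum observed
#' value; `"rowmean"` uses the sample's mean over observed metabolites;
#' `"knn"` averages the `k` nearest samples (Euclidean distance over shared
#' observed metabolites) that observed the entry.
#'
#' @param matrix wide peak-area tibble.
#' @param method one of `"halfmin"`, `"rowmean"`, `"knn"`.
#' @param k neighbours for `"knn"`.
#' @return completed peak-area tibble.
#' @export
impute_missing <- function(matrix, method = c("halfmin", "rowmean", "knn"), k = 5) {
  method <- match.arg(method)
  m <- pa_matrix(matrix)
  if (!anyNA(m)) return(add_provenance(matrix, "impute: none needed"))
  if (method == "halfmin") {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) {
        obs <- m[!nas, j]
        if (length(obs) == 0) abort(sprintf("Metabolite `%s` has no observed values.", colnames(m)[j]))
        m[nas, j] <- min(obs) / 2
      }
    }
  } else if (method == "rowmean") {
    for (i in seq_len(nrow(m))) {
      nas <- is.na(m[i, ])
      if (any(nas)) m[i, nas] <- mean(m[i, !nas])
    }
  } else {
    full <- m
    for (i in which(rowSums(is.na(m)) > 0)) {
      for (j in which(is.na(m[i, ]))) {
        donors <- which(!is.na(full[, j]) & seq_len(nrow(full)) != i)
        if (length(donors) == 0) abort(sprintf("Metabolite `%s` has no observed values.", colnames(m)[j]))
        d <- vapply(donors, function(r) {
          shared <- !is.na(full[i, ]) & !is.na(full[r, ])
          if (!any(shared)) return(Inf)
          sqrt(mean((full[i, shared] - full[r, shared])^2))
        }, 0)
        nb <- donors[order(d)][seq_len(min(k, length(donors)))]
        m[i, j] <- mean(full[nb, j])
      }
    }
  }
  res <- pa_tibble(m)
  attr(res, "provenance") <- attr(matrix, "provenance")
  add_provenance(res, paste0("impute: ", method))
}

#' Autoscale a peak-area table
#'
#' Mean-centers each metabolite and divides by its standard deviation
#' (sample convention, n - 1) across all samples, the usual unit-variance
#' scaling applied ahead of multivariate analysis. Missing entries stay
#' missing; metabolites with fewer than 2 observed values or zero standard
#' deviation are dropped with a warning (error if nothing survives).
#'
#' @param matrix wide peak-area tibble.
#' @param log2 apply a log2 transform before centering (default off).
#' @return scaled tibble of class `scaled_matrix`; per-metabolite mean 0 and
#'   sd 1 to within 1e-8.
#' @export
autoscale <- function(matrix, log2 = FALSE) {
  assert_peak_tbl(matrix)
  m <- pa_matrix(matrix)
  if (log2) {
    if (any(m <= 0, na.rm = TRUE)) abort("log2 transform requires strictly positive values.")
    m <- base::log2(m)
  }
  n_obs <- colSums(!is.na(m))
  sds <- apply(m, 2, sd, na.rm = TRUE)
  drop <- n_obs < 2 | !is.finite(sds) | sds == 0
  if (all(drop)) abort("All metabolites are constant; nothing to scale.")
  if (any(drop)) {
    warn(sprintf("Dropping %d constant/underpopulated metabolite(s): %s",
                 sum(drop), paste(head(colnames(m)[drop], 10), collapse = ", ")))
    m <- m[, !drop, drop = FALSE]
  }
  m <- sweep(m, 2, colMeans(m, na.rm = TRUE), `-`)
  m <- sweep(m, 2, apply(m, 2, sd, na.rm = TRUE), `/`)
  res <- pa_tibble(m)
  attr(res, "provenance") <- attr(matrix, "provenance")
  res <- add_provenance(res, paste0("autoscale: mean-center + unit sd (n-1)",
                                    if (log2) " on log2 scale" else ""))
  class(res) <- c("scaled_matrix", class(res))
  res
}

#' Apply the full preprocessing chain
#'
#' Fixed order: annotation filter, pooled-reference normalization, optional
#' log2 transform, imputation, autoscaling. The chain is recorded in the
#' result's [provenance()].
#'
#' @param matrix wide peak-area tibble.
#' @param samples sample annotation tibble.
#' @param annotation metabolite annotation tibble.
#' @param reference_samples optional explicit reference sample ids.
#' @param impute imputation method, see [impute_missing()].
#' @param log2 log2-transform before scaling (default off).
#' @return a `scaled_matrix` tibble.
#' @export
preprocess_peaks <- function(matrix, samples, annotation,
                             reference_samples = NULL,
                             impute = "halfmin", log2 = FALSE) {
  matrix |>
    filter_annotated(annotation) |>
    reference_normalize(samples, reference_samples = reference_samples) |>
    impute_missing(method = impute) |>
    autoscale(log2 = log2)
}
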