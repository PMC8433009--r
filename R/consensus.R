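#' Aggregate per-method rankings by median rank
#'
#' The consensus rank of a metabolite is the median of its integer ranks
#' across methods (mean of the middle two for an even method count).
#' Metabolites are ordered by ascending consensus rank, ties broken by
#' ascending mean rank, then lexicographic id; the `k` best are flagged as
#' selected.
#'
#' @param ranks long rank tibble (`method`, `metabolite_id`, `rank`, ...) as
#'   produced by [rank_features()], or a list of per-method rank tibbles.
#'   All methods must cover the identical metabolite set.
#' @param k selection size (default 100).
#' @return a `consensus_rank_tbl` tibble: one row per metabolite in consensus
#'   order, per-method `rank_*` columns, `consensus_rank`, `mean_rank`,
#'   `selected`.
#' @export
median_rank_consensus <- function(ranks, k = 100) {
  if (is.list(ranks) && !is.data.frame(ranks)) ranks <- bind_rows(ranks)
  stopifnot(all(c("method", "metabolite_id", "rank") %in% names(ranks)))
  sets <- split(ranks$metabolite_id, ranks$method)
  base_set <- sets[[1]]
  for (meth in names(sets)[-1]) {
    d <- c(setdiff(base_set, sets[[meth]]), setdiff(sets[[meth]], base_set))
    if (length(d)) {
      abort(sprintf("Methods rank different metabolite sets; symmetric difference vs `%s`: %s",
                    meth, paste(head(sort(unique(d)), 10), collapse = ", ")))
    }
  }
  wide <- ranks |>
    select("method", "metabolite_id", "rank") |>
    tidyr::pivot_wider(names_from = "method", values_from = "rank",
                       names_prefix = "rank_")
  rk <- as.matrix(wide[, -1, drop = FALSE])
  out <- wide |>
    mutate(consensus_rank = apply(rk, 1, median),
           mean_rank = rowMeans(rk)) |>
    arrange(.data$consensus_rank, .data$mean_rank, .data$metabolite_id) |>
    mutate(selected = row_number() <= min(k, n()))
  attr(out, "k") <- k
  class(out) <- c("consensus_rank_tbl", class(out))
  out
}

#' Select the top-K consensus metabolites
#'
#' @param table a `consensus_rank_tbl` from [median_rank_consensus()].
#' @param k selection size; defaults to the `k` the table was built with.
#' @return character vector of `min(k, p)` metabolite ids, in consensus
#'   order; stable across calls.
#' @export
select_top_k <- function(table, k = attr(table, "k") %||% 100) {
  if (k < 1) abort("`k` must be >= 1.")
  head(table$metabolite_id, min(k, nrow(table)))
}

#' Test the superfamily distribution of a selection against the universe
#'
#' Goodness-of-fit chi-squared test of the selected metabolites' superfamily
#' counts against expectations proportional to the universe composition.
#' Categories with expected count below `pool_threshold` are pooled into
#' `"other"` before testing; `df` = categories after pooling minus 1. With
#' `contingency = TRUE` a 2 x S selected/not-selected contingency test is
#' run instead (sensitivity variant).
#'
#' @param selection character vector of selected metabolite ids.
#' @param annotation metabolite annotation tibble with `superfamily`.
#' @param universe character vector of universe metabolite ids (the selection
#'   must be a subset).
#' @param pool_threshold minimum expected count per category (default 5).
#' @param contingency use the 2 x S contingency variant.
#' @return object of class `superfamily_test`: counts tibble plus
#'   `statistic`, `df`, `p_value`, `pooled` (ids of pooled categories). When
#'   fewer than 2 categories survive pooling the test is reported as
#'   undefined (`NA` statistic).
#' @export
superfamily_chisq <- function(selection, annotation, universe,
                              pool_threshold = 5, contingency = FALSE) {
  off <- setdiff(selection, universe)
  if (length(off)) {
    abort(sprintf("Selection not contained in universe: %s",
                  paste(head(off, 10), collapse = ", ")))
  }
  fam <- setNames(annotation$superfamily, annotation$metabolite_id)
  if (anyNA(fam[selection]) || anyNA(fam[universe])) {
    abort("Every selected/universe metabolite needs a superfamily annotation.")
  }
  k_sel <- length(selection)
  uni_tab <- table(fam[universe])
  obs <- table(factor(fam[selection], levels = names(uni_tab)))
  if (contingency) {
    not_sel <- table(factor(fam[setdiff(universe, selection)], levels = names(uni_tab)))
    tab <- rbind(selected = as.numeric(obs), rest = as.numeric(not_sel))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    counts <- tibble(superfamily = names(uni_tab), observed = as.numeric(obs),
                     expected = as.numeric(ct$expected["selected", ]))
    res <- list(counts = counts, statistic = unname(ct$statistic),
                df = unname(ct$parameter), p_value = unname(ct$p.value),
                pooled = character(), k = k_sel, method = "contingency")
    class(res) <- "superfamily_test"
    return(res)
  }
  expected <- k_sel * as.numeric(uni_tab) / length(universe)
  names(expected) <- names(uni_tab)
  pooled <- names(expected)[expected < pool_threshold]
  observed <- as.numeric(obs)
  names(observed) <- names(uni_tab)
  if (length(pooled) > 0) {
    keep <- setdiff(names(expected), pooled)
    observed <- c(observed[keep], other = sum(observed[pooled]))
    expected <- c(expected[keep], other = sum(expected[pooled]))
  }
  counts <- tibble(superfamily = names(expected),
                   observed = unname(observed), expected = unname(expected))
  if (length(expected) < 2) {
    res <- list(counts = counts, statistic = NA_real_, df = NA_integer_,
                p_value = NA_real_, pooled = pooled, k = k_sel,
                method = "goodness-of-fit (undefined: < 2 categories after pooling)")
  } else {
    stat <- sum((observed - expected)^2 / expected)
    df <- length(expected) - 1L
    res <- list(counts = counts, statistic = stat, df = df,
                p_value = pchisq(stat, df, lower.tail = FALSE),
                pooled = pooled, k = k_sel, method = "goodness-of-fit")
  }
  class(res) <- "superfamily_test"
  res
}

#' @export
print.superfamily_test <- function(x, ...) {
  cat(sprintf("Superfamily chi-squared (%s)\n", x$method))
  if (is.na(x$statistic)) {
    cat("  test undefined\n")
  } else {
    cat(sprintf("  X-squared = %.4g, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  }
  if (length(x$pooled)) cat("  pooled into 'other':", paste(x$pooled, collapse = ", "), "\n")
  print(x$counts)
  invisible(x)
}
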