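#' Hypergeometric over-representation analysis
#'
#' For each pathway with `m` members in the universe and `k` members in the
#' selection of size `K` drawn from a universe of size `N`, the enrichment
#' p-value is the upper tail `P(X >= k)` with
#' `X ~ Hypergeometric(N, m, K)`; the universe is the annotated, filtered
#' metabolite set. Pathway member lists are intersected with the universe
#' (members outside it are dropped with a warning); pathways with no
#' universe members are omitted. Benjamini-Hochberg q-values are attached.
#'
#' @param selection character vector of selected metabolite ids (subset of
#'   `universe`).
#' @param pathways pathway tibble (`pathway_id`, `description`, list-column
#'   `members`), e.g. from [read_gmt()].
#' @param universe character vector of universe metabolite ids.
#' @return an `ora_result` tibble sorted by p-value: `pathway_id`,
#'   `description`, `m`, `k`, `expected`, `enrichment_ratio`, `p_value`,
#'   `q_value`.
#' @examples
#' pw <- tibble::tibble(pathway_id = "P1", description = "toy",
#'                      members = list(c("a", "b", "c")))
#' ora_hypergeometric(c("a", "b"), pw, letters[1:10])
#' @export
ora_hypergeometric <- function(selection, pathways, universe) {
  off <- setdiff(selection, universe)
  if (length(off)) {
    abort(sprintf("Selection not contained in universe: %s",
                  paste(head(off, 10), collapse = ", ")))
  }
  n_uni <- length(universe)
  k_sel <- length(selection)
  members <- lapply(pathways$members, intersect, universe)
  dropped <- sum(lengths(pathways$members) - lengths(members))
  if (dropped > 0) {
    warn(sprintf("Dropped %d pathway member(s) outside the universe.", dropped))
  }
  m <- lengths(members)
  k <- vapply(members, function(mm) length(intersect(mm, selection)), 0L)
  out <- tibble(
    pathway_id = pathways$pathway_id,
    description = pathways$description,
    m = m, k = k,
    expected = k_sel * m / n_uni,
    enrichment_ratio = ifelse(m > 0, k / (k_sel * m / n_uni), NA_real_),
    p_value = phyper(k - 1, m, n_uni - m, k_sel, lower.tail = FALSE))
  out <- out[out$m > 0, , drop = FALSE]
  out$q_value <- adjust_bh(out$p_value)
  out <- arrange(out, .data$p_value, .data$pathway_id)
  attr(out, "K") <- k_sel
  attr(out, "N") <- n_uni
  class(out) <- c("ora_result", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement;
#' order-preserving.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
adjust_bh <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}
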