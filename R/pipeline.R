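#' Specify one two-class comparison
#'
#' A comparison is data, not code: a name, a sample filter expressed as a
#' named list of allowed annotation values (e.g.
#' `list(timepoint = "RO")`), the class variable with its two levels, the
#' selection size `k`, and a seed for the stochastic rankers.
#'
#' @param name comparison label.
#' @param filter named list; a sample is kept when every listed annotation
#'   column takes one of the listed values.
#' @param class_var annotation column defining the two classes.
#' @param class_a,class_b the two class levels.
#' @param k consensus selection size.
#' @param seed integer seed.
#' @return list of class `comparison_spec`.
#' @export
comparison_spec <- function(name, filter, class_var, class_a, class_b,
                            k = 100, seed = 1L) {
  structure(list(name = name, filter = filter, class_var = class_var,
                 class_a = class_a, class_b = class_b, k = k,
                 seed = as.integer(seed)),
            class = "comparison_spec")
}

#' The three standard comparisons of a young/aged CLP study
#'
#' Aged vs young on pre-intervention (RO) samples; CLP vs sham within young
#' post-intervention samples; CLP vs sham within aged.
#'
#' @param k consensus selection size shared by all three.
#' @param seed base seed; comparisons get `seed`, `seed + 1`, `seed + 2`.
#' @return list of [comparison_spec()]s.
#' @export
default_comparisons <- function(k = 100, seed = 1L) {
  post <- c("0", "4", "8", "12")
  list(
    comparison_spec("baseline_aged_vs_young", list(timepoint = "RO"),
                    "age_group", "aged", "young", k = k, seed = seed),
    comparison_spec("young_clp_vs_sham",
                    list(age_group = "young", timepoint = post,
                         intervention = c("sham", "clp")),
                    "intervention", "clp", "sham", k = k, seed = seed + 1L),
    comparison_spec("aged_clp_vs_sham",
                    list(age_group = "aged", timepoint = post,
                         intervention = c("sham", "clp")),
                    "intervention", "clp", "sham", k = k, seed = seed + 2L))
}

filter_samples <- function(samples, filter) {
  keep <- rep(TRUE, nrow(samples))
  for (col in names(filter)) {
    if (!col %in% names(samples)) abort(sprintf("No annotation column `%s`.", col))
    keep <- keep & samples[[col]] %in% filter[[col]]
  }
  samples[keep, , drop = FALSE]
}

#' Run one comparison through the full consensus workflow
#'
#' Stages, in order: annotation filter, pooled-reference normalization,
#' subset to the comparison's samples, imputation, autoscaling, the four
#' rankers, median-rank consensus, top-K selection, superfamily chi-squared,
#' hypergeometric pathway over-representation against the annotated
#' universe. Row counts per stage are logged via messages.
#'
#' @param spec a [comparison_spec()].
#' @param matrix wide peak-area tibble (full experiment).
#' @param samples sample annotation tibble.
#' @param annotation metabolite annotation tibble.
#' @param pathways pathway tibble.
#' @param impute imputation method.
#' @param methods ranker subset (default all four).
#' @param quiet suppress stage logging.
#' @return `comparison_result` list: `name`, `consensus`, `selection`,
#'   `superfamily`, `enrichment`, `n_samples`, `universe`, `seed`.
#' @export
run_comparison <- function(spec, matrix, samples, annotation, pathways,
                           impute = "halfmin",
                           methods = c("pca", "plsda", "ebam", "rf"),
                           quiet = FALSE) {
  stopifnot(inherits(spec, "comparison_spec"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  sel_samples <- filter_samples(samples, spec$filter)
  labels <- class_labels(sel_samples, spec$class_var, spec$class_a, spec$class_b)
  n_a <- sum(labels$class == spec$class_a)
  n_b <- sum(labels$class == spec$class_b)
  if (min(n_a, n_b) < 2) {
    abort(sprintf("[%s] needs >= 2 samples per class (%s=%d, %s=%d).",
                  spec$name, spec$class_a, n_a, spec$class_b, n_b))
  }
  say("[%s] samples: %d (%s=%d, %s=%d)", spec$name, nrow(labels),
      spec$class_a, sum(labels$class == spec$class_a),
      spec$class_b, sum(labels$class == spec$class_b))
  filt <- filter_annotated(matrix, annotation)
  normed <- reference_normalize(filt, samples)
  sub <- normed[normed$sample_id %in% labels$sample_id, , drop = FALSE]
  attr(sub, "provenance") <- attr(normed, "provenance")
  scaled <- autoscale(impute_missing(sub, method = impute))
  universe <- metabolite_ids(scaled)
  say("[%s] universe: %d annotated metabolites", spec$name, length(universe))
  ranks <- rank_features(scaled, labels, methods = methods, seed = spec$seed)
  consensus <- median_rank_consensus(ranks, k = spec$k)
  selection <- select_top_k(consensus)
  say("[%s] selected top %d by median rank", spec$name, length(selection))
  superfamily <- superfamily_chisq(selection, annotation, universe)
  enrichment <- ora_hypergeometric(selection, pathways, universe)
  structure(list(name = spec$name, consensus = consensus, selection = selection,
                 superfamily = superfamily, enrichment = enrichment,
                 n_samples = nrow(labels), universe = universe,
                 seed = spec$seed),
            class = "comparison_result")
}

#' Intersect significantly enriched pathways across comparisons
#'
#' For each pathway, reports the set of comparisons in which its BH q-value
#' is at or below `q_threshold`, sorted by intersection size then minimum
#' q-value.
#'
#' @param enrichments named list of `ora_result` tables (>= 2).
#' @param q_threshold BH q cutoff (default 0.05).
#' @return tibble `pathway_id`, `n_significant`, `comparisons`
#'   (comma-separated), `min_q`.
#' @export
intersect_pathways <- function(enrichments, q_threshold = 0.05) {
  if (length(enrichments) < 2) abort("Need at least 2 enrichment tables.")
  if (is.null(names(enrichments)) || any(!nzchar(names(enrichments)))) {
    names(enrichments) <- paste0("comparison", seq_along(enrichments))
  }
  long <- bind_rows(lapply(names(enrichments), function(nm) {
    e <- enrichments[[nm]]
    tibble(comparison = nm, pathway_id = e$pathway_id, q_value = e$q_value)
  }))
  long |>
    group_by(.data$pathway_id) |>
    summarise(
      n_significant = sum(.data$q_value <= q_threshold),
      comparisons = paste(sort(.data$comparison[.data$q_value <= q_threshold]),
                          collapse = ","),
      min_q = min(.data$q_value), .groups = "drop") |>
    arrange(desc(.data$n_significant), .data$min_q, .data$pathway_id)
}

#' Run the full multi-comparison pipeline
#'
#' Executes every comparison, intersects their significantly enriched
#' pathways, and returns a reproducible bundle whose digest is stable
#' bit-for-bit under a fixed seed.
#'
#' @param matrix wide peak-area tibble.
#' @param samples sample annotation tibble.
#' @param annotation metabolite annotation tibble.
#' @param pathways pathway tibble.
#' @param comparisons list of [comparison_spec()]s (default
#'   [default_comparisons()]).
#' @param q_threshold BH q cutoff for the intersection report.
#' @param quiet suppress stage logging.
#' @return `run_bundle` list: `comparisons` (named `comparison_result`s),
#'   `intersection`, `q_threshold`, `digest`.
#' @export
run_pipeline <- function(matrix, samples, annotation, pathways,
                         comparisons = default_comparisons(),
                         q_threshold = 0.05, quiet = FALSE) {
  results <- lapply(comparisons, run_comparison, matrix = matrix,
                    samples = samples, annotation = annotation,
                    pathways = pathways, quiet = quiet)
  names(results) <- vapply(comparisons, `[[`, "", "name")
  intersection <- intersect_pathways(
    lapply(results, `[[`, "enrichment"), q_threshold = q_threshold)
  bundle <- list(comparisons = results, intersection = intersection,
                 q_threshold = q_threshold)
  bundle$digest <- bundle_digest(bundle)
  class(bundle) <- "run_bundle"
  bundle
}

#' Content digest of a run bundle
#'
#' Hash over the canonical numeric content (consensus tables, superfamily
#' tests, enrichment tables, intersection report); two runs from identical
#' inputs and seeds produce identical digests.
#'
#' @param bundle a `run_bundle` (the digest field itself is ignored).
#' @return character hash.
#' @export
bundle_digest <- function(bundle) {
  canon <- lapply(bundle$comparisons, function(r) {
    list(consensus = as.data.frame(r$consensus),
         selection = r$selection,
         superfamily = list(counts = as.data.frame(r$superfamily$counts),
                            statistic = r$superfamily$statistic,
                            p = r$superfamily$p_value),
         enrichment = as.data.frame(r$enrichment))
  })
  rlang::hash(list(canon, as.data.frame(bundle$intersection), bundle$q_threshold))
}

#' @export
print.run_bundle <- function(x, ...) {
  cat(sprintf("Consensus metabolomics run: %d comparison(s)\n",
              length(x$comparisons)))
  for (r in x$comparisons) {
    cat(sprintf("  %s: %d samples, %d selected, superfamily p = %s\n",
                r$name, r$n_samples, length(r$selection),
                format(r$superfamily$p_value, digits = 3)))
  }
  n_shared <- sum(x$intersection$n_significant >= 2)
  cat(sprintf("  pathways significant (q <= %g) in >= 2 comparisons: %d\n",
              x$q_threshold, n_shared))
  cat("  digest:", x$digest, "\n")
  invisible(x)
}
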