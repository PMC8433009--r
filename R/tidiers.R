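# broom-style tidiers for the package's result objects

#' @method tidy consensus_rank_tbl
#' @export
tidy.consensus_rank_tbl <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "consensus_rank_tbl")
  out
}

#' @method glance consensus_rank_tbl
#' @export
glance.consensus_rank_tbl <- function(x, ...) {
  tibble(n_metabolites = nrow(x), k = attr(x, "k") %||% sum(x$selected),
         n_selected = sum(x$selected),
         n_methods = sum(startsWith(names(x), "rank_")))
}

#' @method tidy ora_result
#' @export
tidy.ora_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "ora_result")
  out
}

#' @method glance ora_result
#' @export
glance.ora_result <- function(x, ...) {
  tibble(n_pathways = nrow(x), n_significant = sum(x$q_value <= 0.05),
         selection_size = attr(x, "K"), universe_size = attr(x, "N"),
         min_p = if (nrow(x)) min(x$p_value) else NA_real_)
}

#' @method tidy superfamily_test
#' @export
tidy.superfamily_test <- function(x, ...) x$counts

#' @method glance superfamily_test
#' @export
glance.superfamily_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         n_categories = nrow(x$counts), n_pooled = length(x$pooled),
         method = x$method)
}

#' @method tidy two_way_fit
#' @export
tidy.two_way_fit <- function(x, ...) x$anova

#' @method glance two_way_fit
#' @export
glance.two_way_fit <- function(x, ...) {
  g <- x$anova
  tibble(F_group = g$statistic[g$term == "group"],
         p_group = g$p_value[g$term == "group"],
         F_time = g$statistic[g$term == "time"],
         p_time = g$p_value[g$term == "time"],
         F_interaction = g$statistic[g$term == "group:time"],
         p_interaction = g$p_value[g$term == "group:time"],
         mse = x$mse, df_resid = x$df_resid,
         flags = paste(names(x$flags)[x$flags], collapse = ""))
}

#' @method tidy anova_tbl
#' @export
tidy.anova_tbl <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "anova_tbl")
  out
}

#' @method glance anova_tbl
#' @export
glance.anova_tbl <- function(x, ...) {
  tibble(n_metabolites = nrow(x), alpha = attr(x, "alpha") %||% 0.05,
         n_sig_group = sum(x$sig_group, na.rm = TRUE),
         n_sig_time = sum(x$sig_time, na.rm = TRUE),
         n_sig_interaction = sum(x$sig_interaction, na.rm = TRUE))
}

#' @method tidy comparison_result
#' @export
tidy.comparison_result <- function(x, ...) tidy(x$consensus)

#' @method glance comparison_result
#' @export
glance.comparison_result <- function(x, ...) {
  tibble(name = x$name, n_samples = x$n_samples,
         universe_size = length(x$universe),
         n_selected = length(x$selection),
         superfamily_p = x$superfamily$p_value,
         min_enrichment_p = if (nrow(x$enrichment)) min(x$enrichment$p_value) else NA_real_)
}

#' @method glance run_bundle
#' @export
glance.run_bundle <- function(x, ...) {
  bind_rows(lapply(x$comparisons, glance))
}
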