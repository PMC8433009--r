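# ggplot2 views of the result objects; plot-ready tables, not figure styling

#' @method autoplot consensus_rank_tbl
#' @export
autoplot.consensus_rank_tbl <- function(object, n = 25, ...) {
  top <- head(object, n)
  long <- top |>
    select("metabolite_id", dplyr::starts_with("rank_"), "consensus_rank") |>
    tidyr::pivot_longer(dplyr::starts_with("rank_"),
                        names_to = "method", values_to = "rank") |>
    mutate(method = sub("^rank_", "", .data$method),
           metabolite_id = factor(.data$metabolite_id,
                                  levels = rev(top$metabolite_id)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$metabolite_id)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$method), alpha = 0.8) +
    ggplot2::geom_point(ggplot2::aes(x = .data$consensus_rank), shape = 3,
                        size = 3, colour = "black") +
    ggplot2::labs(x = "rank (+ = median consensus)", y = NULL,
                  title = sprintf("Top %d consensus metabolites", nrow(top)))
}

#' @method autoplot ora_result
#' @export
autoplot.ora_result <- function(object, q_threshold = 0.05, ...) {
  d <- as_tibble(object) |>
    mutate(pathway_id = factor(.data$pathway_id, levels = rev(.data$pathway_id)),
           significant = .data$q_value <= q_threshold)
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_value), y = .data$pathway_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = -log10(.data$p_value),
                                       yend = .data$pathway_id), colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(size = .data$enrichment_ratio,
                                     colour = .data$significant)) +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  title = "Pathway over-representation")
}

#' @method autoplot superfamily_test
#' @export
autoplot.superfamily_test <- function(object, ...) {
  d <- object$counts |>
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "kind", values_to = "count")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$superfamily, y = .data$count,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "metabolite count",
                  title = sprintf("Superfamily distribution (p = %s)",
                                  format(object$p_value, digits = 3)))
}

#' @method autoplot two_way_fit
#' @export
autoplot.two_way_fit <- function(object, ...) {
  ggplot2::ggplot(object$cell_means,
                  ggplot2::aes(x = .data$time, y = .data$mean,
                               colour = .data$group, group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::labs(x = "time (h)", y = "abundance",
                  title = paste("flags:", paste(names(object$flags)[object$flags],
                                                collapse = "")))
}

#' Plot the time course of one metabolite
#'
#' Group-mean trajectories (+/- SE) over the post-intervention timepoints.
#'
#' @param matrix wide peak-area tibble.
#' @param samples sample annotation tibble.
#' @param metabolite_id metabolite to plot.
#' @param alpha significance level for the flag annotation.
#' @return a ggplot object.
#' @export
plot_timecourse <- function(matrix, samples, metabolite_id, alpha = 0.05) {
  design <- anova_design(samples)
  m <- pa_matrix(matrix)
  if (!metabolite_id %in% colnames(m)) {
    abort(sprintf("Metabolite `%s` not in matrix.", metabolite_id))
  }
  fit <- two_way_anova(tibble(value = m[design$sample_id, metabolite_id],
                              group = design$group, time = design$time),
                       alpha = alpha)
  autoplot(fit) + ggplot2::ggtitle(metabolite_id) +
    ggplot2::labs(subtitle = paste("flags:",
                                   paste(names(fit$flags)[fit$flags], collapse = "")))
}
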