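# Per-metabolite factorial time-course testing: two-way ANOVA over
# group x time with Tukey-corrected within-timepoint post-hoc contrasts.

#' Build the group-by-time ANOVA design from a sample annotation
#'
#' The group factor crosses age and intervention (`young_sham`, `young_clp`,
#' `aged_sham`, `aged_clp`); the time factor holds the post-intervention
#' sacrifice hours. Pre-intervention RO samples precede group assignment and
#' are excluded by default; `include_baseline = TRUE` adds them as the
#' earliest time level (labelled `"RO"`).
#'
#' @param samples sample annotation tibble.
#' @param include_baseline include RO samples as the earliest time level.
#' @return tibble `sample_id`, `group`, `time` (factors).
#' @export
anova_design <- function(samples, include_baseline = FALSE) {
  d <- samples[samples$intervention %in% c("sham", "clp"), ]
  if (!include_baseline) d <- d[d$timepoint != "RO", ]
  tp <- unique(d$timepoint)
  num <- suppressWarnings(as.numeric(tp))
  lv <- c(if ("RO" %in% tp) "RO", tp[!is.na(num)][order(num[!is.na(num)])])
  tibble(sample_id = d$sample_id,
         group = factor(paste(d$age_group, d$intervention, sep = "_")),
         time = factor(d$timepoint, levels = lv))
}

#' Two-way ANOVA for a single metabolite
#'
#' Fits `value ~ group * time` and tests both main effects and their
#' interaction with Type II sums of squares (nested model comparisons),
#' which reduce exactly to the classical balanced decomposition when the
#' design is balanced. If empty cells make the interaction inestimable, the
#' mains are tested in the additive model and the interaction is reported as
#' unavailable, with a warning.
#'
#' @param data tibble with columns `value`, `group`, `time`.
#' @param alpha significance level for the G/T/I flags.
#' @return object of class `two_way_fit`: `anova` tibble (term, df, sumsq,
#'   statistic, p_value), `cell_means`, `mse`, `df_resid`, significance
#'   flags, and the model data (for post-hoc contrasts).
#' @export
two_way_anova <- function(data, alpha = 0.05) {
  stopifnot(all(c("value", "group", "time") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("value", "group", "time")]), ]
  data$group <- droplevels(as.factor(data$group))
  data$time <- droplevels(as.factor(data$time))
  cells <- table(data$group, data$time)
  interaction_ok <- all(cells > 0) && nlevels(data$group) > 1 && nlevels(data$time) > 1
  if (!interaction_ok) {
    warn("Empty design cells: interaction inestimable; reporting additive mains.")
    fit <- lm(value ~ group + time, data = data)
  } else {
    fit <- lm(value ~ group * time, data = data)
  }
  a2 <- car::Anova(fit, type = 2)
  df_resid <- a2["Residuals", "Df"]
  if (df_resid < 2) abort("Fewer than 2 residual degrees of freedom.")
  mse <- a2["Residuals", "Sum Sq"] / df_resid
  pick <- function(term) {
    if (!term %in% rownames(a2)) {
      return(tibble(term = term, df = NA_integer_, sumsq = NA_real_,
                    statistic = NA_real_, p_value = NA_real_))
    }
    tibble(term = term, df = a2[term, "Df"], sumsq = a2[term, "Sum Sq"],
           statistic = a2[term, "F value"], p_value = a2[term, "Pr(>F)"])
  }
  tab <- bind_rows(pick("group"), pick("time"), pick("group:time"),
                   tibble(term = "residuals", df = df_resid,
                          sumsq = a2["Residuals", "Sum Sq"],
                          statistic = NA_real_, p_value = NA_real_))
  cell_means <- data |>
    group_by(.data$group, .data$time) |>
    summarise(n = n(), mean = mean(.data$value),
              se = sd(.data$value) / sqrt(n()), .groups = "drop")
  flags <- c(G = isTRUE(tab$p_value[tab$term == "group"] < alpha),
             T = isTRUE(tab$p_value[tab$term == "time"] < alpha),
             I = isTRUE(tab$p_value[tab$term == "group:time"] < alpha))
  structure(list(anova = tab, cell_means = cell_means, mse = mse,
                 df_resid = df_resid, flags = flags, alpha = alpha,
                 data = as_tibble(data)),
            class = "two_way_fit")
}

#' @export
print.two_way_fit <- function(x, ...) {
  cat("Two-way ANOVA (Type II SS)\n")
  print(x$anova)
  cat("flags:", paste(names(x$flags)[x$flags], collapse = ""), "\n")
  invisible(x)
}

#' Default post-hoc contrasts
#'
#' The two comparisons of primary interest in an aged/young sepsis design:
#' aged CLP vs young CLP, and aged CLP vs aged sham.
#' @return list of character pairs.
#' @export
default_contrast_pairs <- function() {
  list(c("aged_clp", "young_clp"), c("aged_clp", "aged_sham"))
}

#' Tukey-corrected post-hoc contrasts within timepoints
#'
#' For each timepoint, group means are compared with the studentized-range
#' statistic `q = |mean_i - mean_j| / sqrt(MSE (1/n_i + 1/n_j) / 2)` using
#' the residual mean square and degrees of freedom of the full two-way fit.
#' The family is all `k (k - 1) / 2` pairwise group comparisons within the
#' timepoint (`k` = number of group levels), but only the requested pairs
#' are emitted. Adjusted p comes from the studentized-range distribution.
#'
#' @param fit a `two_way_fit` from [two_way_anova()].
#' @param pairs list of 2-vectors of group levels; default
#'   [default_contrast_pairs()].
#' @return tibble `timepoint`, `group1`, `group2`, `diff`, `q`, `p_adj`
#'   (symmetric in pair order; `NA` when a group is absent at a timepoint).
#' @export
tukey_contrasts <- function(fit, pairs = default_contrast_pairs()) {
  stopifnot(inherits(fit, "two_way_fit"))
  lv <- levels(fit$data$group)
  for (pr in pairs) {
    bad <- setdiff(pr, lv)
    if (length(bad)) abort(sprintf("Group level(s) not in design: %s",
                                   paste(bad, collapse = ", ")))
  }
  k <- length(lv)
  cm <- fit$cell_means
  rows <- list()
  for (tp in levels(fit$data$time)) {
    for (pr in pairs) {
      a <- cm[cm$time == tp & cm$group == pr[1], ]
      b <- cm[cm$time == tp & cm$group == pr[2], ]
      if (nrow(a) == 0 || nrow(b) == 0) {
        rows[[length(rows) + 1]] <- tibble(timepoint = tp, group1 = pr[1],
                                           group2 = pr[2], diff = NA_real_,
                                           q = NA_real_, p_adj = NA_real_)
        next
      }
      d <- a$mean - b$mean
      q <- abs(d) / sqrt(fit$mse * (1 / a$n + 1 / b$n) / 2)
      rows[[length(rows) + 1]] <- tibble(
        timepoint = tp, group1 = pr[1], group2 = pr[2], diff = d, q = q,
        p_adj = ptukey(q, nmeans = k, df = fit$df_resid, lower.tail = FALSE))
    }
  }
  bind_rows(rows)
}

#' Two-way ANOVA across a peak-area table
#'
#' Runs [two_way_anova()] on every requested metabolite and assembles the
#' per-metabolite F statistics, p-values and G/T/I significance flags.
#' Values are typically reference-normalized but unscaled: F statistics are
#' scale-invariant, so flags are unaffected by the choice.
#'
#' @param matrix wide peak-area tibble.
#' @param samples sample annotation tibble.
#' @param metabolites metabolite ids to test (default: all columns).
#' @param alpha flag significance level.
#' @param include_baseline passed to [anova_design()].
#' @return an `anova_tbl` tibble, one row per metabolite.
#' @export
timecourse_anova <- function(matrix, samples, metabolites = NULL, alpha = 0.05,
                             include_baseline = FALSE) {
  assert_peak_tbl(matrix)
  design <- anova_design(samples, include_baseline = include_baseline)
  metabolites <- metabolites %||% metabolite_ids(matrix)
  m <- pa_matrix(matrix)
  rows <- lapply(metabolites, function(id) {
    vals <- m[design$sample_id, id]
    ft <- two_way_anova(tibble(value = vals, group = design$group,
                               time = design$time), alpha = alpha)
    g <- ft$anova[ft$anova$term == "group", ]
    t_ <- ft$anova[ft$anova$term == "time", ]
    i <- ft$anova[ft$anova$term == "group:time", ]
    tibble(metabolite_id = id,
           F_group = g$statistic, p_group = g$p_value,
           F_time = t_$statistic, p_time = t_$p_value,
           F_interaction = i$statistic, p_interaction = i$p_value,
           sig_group = unname(ft$flags["G"]), sig_time = unname(ft$flags["T"]),
           sig_interaction = unname(ft$flags["I"]),
           mse = ft$mse, df_resid = ft$df_resid)
  })
  out <- bind_rows(rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("anova_tbl", class(out))
  out
}

#' Time-course report for one pathway
#'
#' One row per pathway member detected in the matrix, carrying its cell
#' means +/- SE per (group, time), the G/T/I flags of the two-way ANOVA, and
#' the requested Tukey contrasts per timepoint (as nested list-columns).
#' Undetected members are listed in the `undetected` attribute, mirroring
#' the labelled-but-empty boxes convention of pathway figures.
#'
#' @param matrix wide peak-area tibble.
#' @param samples sample annotation tibble.
#' @param members character vector of pathway member metabolite ids.
#' @param pairs Tukey contrast pairs, see [tukey_contrasts()].
#' @param alpha flag significance level.
#' @return nested tibble, one row per detected member, with attribute
#'   `undetected`.
#' @export
pathway_timecourse_report <- function(matrix, samples, members,
                                      pairs = default_contrast_pairs(),
                                      alpha = 0.05) {
  assert_peak_tbl(matrix)
  detected <- intersect(members, metabolite_ids(matrix))
  undetected <- setdiff(members, detected)
  if (length(undetected)) {
    inform(sprintf("%d pathway member(s) undetected: %s", length(undetected),
                   paste(undetected, collapse = ", ")))
  }
  design <- anova_design(samples)
  m <- pa_matrix(matrix)
  rows <- lapply(detected, function(id) {
    ft <- two_way_anova(tibble(value = m[design$sample_id, id],
                               group = design$group, time = design$time),
                        alpha = alpha)
    tibble(metabolite_id = id,
           sig_group = unname(ft$flags["G"]), sig_time = unname(ft$flags["T"]),
           sig_interaction = unname(ft$flags["I"]),
           cell_stats = list(ft$cell_means),
           contrasts = list(tukey_contrasts(ft, pairs = pairs)))
  })
  out <- if (length(rows)) bind_rows(rows) else
    tibble(metabolite_id = character(), sig_group = logical(),
           sig_time = logical(), sig_interaction = logical(),
           cell_stats = list(), contrasts = list())
  attr(out, "undetected") <- undetected
  out
}
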