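worked_fit <- function() {
  two_way_anova(data.frame(
    value = c(1, 3, 5, 7, 2, 4, 10, 12),
    group = rep(c("g1", "g1", "g2", "g2"), each = 2),
    time = rep(rep(c("t1", "t2"), each = 2), 2)))
}

test_that("balanced 2x2x2 worked example reproduces the closed-form decomposition", {
  fit <- worked_fit()
  tab <- fit$anova
  expect_equal(tab$statistic[tab$term == "group"], 9)
  expect_equal(tab$statistic[tab$term == "time"], 36)
  expect_equal(tab$statistic[tab$term == "group:time"], 4)
  expect_equal(tab$df[1:3], c(1, 1, 1))
  expect_equal(fit$df_resid, 4)
  # SSA=18, SSB=72, SSAB=8, SSE=8; the decomposition is exact when balanced
  expect_equal(tab$sumsq, c(18, 72, 8, 8))
  total <- sum((worked_fit()$data$value - mean(worked_fit()$data$value))^2)
  expect_equal(sum(tab$sumsq), total, tolerance = 1e-8)
})

test_that("F statistics are location and scale invariant", {
  base <- worked_fit()$anova$statistic[1:3]
  d <- data.frame(value = c(1, 3, 5, 7, 2, 4, 10, 12),
                  group = rep(c("g1", "g1", "g2", "g2"), each = 2),
                  time = rep(rep(c("t1", "t2"), each = 2), 2))
  d_shift <- d; d_shift$value <- d$value + 100
  d_scale <- d; d_scale$value <- d$value * 3.7
  expect_equal(two_way_anova(d_shift)$anova$statistic[1:3], base)
  expect_equal(two_way_anova(d_scale)$anova$statistic[1:3], base)
})

test_that("empty cells drop the interaction with a warning; mains survive", {
  d <- data.frame(value = rnorm(10),
                  group = c(rep("g1", 6), rep("g2", 4)),
                  time = c(rep(c("t1", "t2"), 3), rep("t1", 4)))  # g2 never at t2
  expect_warning(fit <- two_way_anova(d), "interaction")
  expect_true(is.na(fit$anova$statistic[fit$anova$term == "group:time"]))
  expect_false(is.na(fit$anova$statistic[fit$anova$term == "group"]))
})

test_that("Tukey q and adjusted p agree with ptukey and the quadrature oracle", {
  fit <- worked_fit()
  tk <- tukey_contrasts(fit, pairs = list(c("g1", "g2")))
  # hand q at t2: |6 - 11| / sqrt(2 * (1/2 + 1/2) / 2) = 5
  expect_equal(tk$q[tk$timepoint == "t2"], 5)
  expect_equal(tk$p_adj[tk$timepoint == "t2"],
               ptukey(5, nmeans = 2, df = 4, lower.tail = FALSE))
  # studentized-range tail by numerical integration
  q95 <- qtukey(0.95, nmeans = 4, df = 12)
  expect_equal(ptukey_quadrature(q95, k = 4, df = 12), 0.95, tolerance = 1e-4)
  expect_equal(1 - ptukey_quadrature(tk$q[2], k = 2, df = 4),
               tk$p_adj[2], tolerance = 1e-4)
})

test_that("Tukey contrasts are symmetric and null at equal means", {
  withr::with_seed(40, {
    d <- data.frame(value = rnorm(16) + rep(c(0.5, -0.5, 0.2, 0), 4),
                    group = rep(c("g1", "g2", "g3", "g4"), 4),
                    time = rep(c("t1", "t2"), each = 8))
  })
  fit <- two_way_anova(d)
  ab <- tukey_contrasts(fit, pairs = list(c("g1", "g2")))
  ba <- tukey_contrasts(fit, pairs = list(c("g2", "g1")))
  expect_equal(abs(ab$diff), abs(ba$diff))
  expect_equal(ab$q, ba$q)
  expect_equal(ab$p_adj, ba$p_adj)
  # identical cell means -> q = 0, p = 1
  d0 <- data.frame(value = rep(1:4, times = 4),
                   group = rep(c("g1", "g2"), each = 8),
                   time = rep(rep(c("t1", "t2"), each = 4), 2))
  fit0 <- two_way_anova(d0)
  tk0 <- tukey_contrasts(fit0, pairs = list(c("g1", "g2")))
  expect_equal(tk0$q, c(0, 0))
  expect_equal(tk0$p_adj, c(1, 1))
  expect_error(tukey_contrasts(fit0, pairs = list(c("g1", "nope"))), "nope")
})

test_that("Tukey adjusted p is conservative relative to the pairwise t-test", {
  withr::with_seed(41, {
    d <- data.frame(value = rnorm(32),
                    group = rep(c("g1", "g2", "g3", "g4"), each = 8),
                    time = rep(rep(c("t1", "t2"), each = 4), 4))
  })
  fit <- two_way_anova(d)
  tk <- tukey_contrasts(fit, pairs = list(c("g1", "g2")))
  for (i in seq_len(nrow(tk))) {
    tp <- tk$timepoint[i]
    a <- d$value[d$group == "g1" & d$time == tp]
    b <- d$value[d$group == "g2" & d$time == tp]
    p_t <- t.test(a, b, var.equal = TRUE)$p.value
    expect_gte(tk$p_adj[i], p_t - 1e-9)
  }
})

test_that("timecourse_anova flags planted interactions and keeps RO out", {
  sim <- tiny_experiment(seed = 51, n_per_cell = 4, group_effect = 0,
                         interaction_effect = 3)
  normed <- sim$matrix |>
    filter_annotated(sim$annotation) |>
    reference_normalize(sim$samples)
  res <- timecourse_anova(normed, sim$samples)
  aff <- intersect(res$metabolite_id, sim$truth$affected_metabolite_ids)
  unaff <- setdiff(res$metabolite_id, aff)
  expect_gt(mean(res$sig_interaction[res$metabolite_id %in% aff]), 0.7)
  expect_lt(mean(res$sig_interaction[res$metabolite_id %in% unaff]), 0.3)
  # design excludes pre-intervention samples
  des <- anova_design(sim$samples)
  expect_false("RO" %in% des$time)
  des_ro <- anova_design(sim$samples, include_baseline = TRUE)
  expect_equal(levels(des_ro$time)[1], "RO")
})

test_that("pathway_timecourse_report keeps bookkeeping straight", {
  sim <- tiny_experiment(seed = 52)
  members <- c(sim$pathways$members[[1]], "GHOST1", "GHOST2")
  expect_message(rep_ <- pathway_timecourse_report(sim$matrix, sim$samples,
                                                   members),
                 "undetected")
  expect_equal(nrow(rep_), length(sim$pathways$members[[1]]))
  expect_setequal(attr(rep_, "undetected"), c("GHOST1", "GHOST2"))
  expect_true(all(c("cell_stats", "contrasts") %in% names(rep_)))
  # contrasts carry the two named comparisons per timepoint
  cts <- rep_$contrasts[[1]]
  expect_setequal(unique(paste(cts$group1, cts$group2)),
                  c("aged_clp young_clp", "aged_clp aged_sham"))
  empty <- pathway_timecourse_report(sim$matrix, sim$samples,
                                     c("GHOST1", "GHOST9"))
  expect_equal(nrow(empty), 0)
  expect_setequal(attr(empty, "undetected"), c("GHOST1", "GHOST9"))
})
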