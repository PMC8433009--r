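# Four per-metabolite importance rankings for a two-class comparison.
# Every ranker returns a tibble (method, metabolite_id, score, rank) whose
# rank column is a permutation of 1..p: rank 1 = most important, ties broken
# by higher secondary magnitude then lexicographic metabolite id.

#' Rank metabolites by variance-weighted PCA loadings
#'
#' Unsupervised ranker: class labels are never consulted. Principal
#' components are computed on the (already centered/scaled) matrix; the
#' smallest leading set of components whose cumulative explained variance
#' reaches `var_threshold` contributes, and each metabolite scores
#' `sqrt(sum_a lambda_a * loading_aj^2 / sum_a lambda_a)` over that set —
#' its variance-weighted loading magnitude.
#'
#' @param scaled complete `scaled_matrix` tibble (see [autoscale()]).
#' @param var_threshold cumulative explained-variance cutoff in (0, 1].
#' @return rank tibble (method `"pca"`).
#' @export
rank_pca <- function(scaled, var_threshold = 0.8) {
  m <- ranker_matrix(scaled)
  if (nrow(m) < 2) abort("Need at least 2 samples.")
  pc <- prcomp(m, center = FALSE, scale. = FALSE)
  lambda <- pc$sdev^2
  keep <- lambda > .Machine$double.eps * lambda[1]
  lambda <- lambda[keep]
  cum <- cumsum(lambda) / sum(lambda)
  a_star <- seq_len(which(cum >= var_threshold)[1])
  load2 <- pc$rotation[, a_star, drop = FALSE]^2
  score <- sqrt(as.vector(load2 %*% lambda[a_star]) / sum(lambda[a_star]))
  ids <- colnames(m)
  rank_tbl("pca", ids, score, score_ranks(score, ids))
}

#' Rank metabolites by PLS-DA variable importance in projection (VIP)
#'
#' Fits a univariate-response PLS model by NIPALS with class membership coded
#' +1/-1 (centered). With unit-norm weight vectors `w_a`, scores `t_a` and
#' y-loadings `q_a`, the explained-y sum of squares per component is
#' `SSY_a = q_a^2 * (t_a' t_a)`, and
#' `VIP_j = sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a)`, which satisfies
#' `sum_j VIP_j^2 = p`. Components beyond the point where the residual
#' X'y vanishes are dropped.
#'
#' @param scaled complete `scaled_matrix` tibble.
#' @param labels two-class labelling: `(sample_id, class)` tibble (see
#'   [class_labels()]) or named vector.
#' @param n_components number of latent components (truncated to
#'   `min(n - 1, p)`).
#' @return rank tibble (method `"plsda_vip"`).
#' @export
rank_plsda_vip <- function(scaled, labels, n_components = 2) {
  m <- ranker_matrix(scaled)
  cls <- align_classes(rownames(m), labels)
  if (any(table(cls) < 2)) abort("Both classes need >= 2 samples.")
  y <- ifelse(cls == levels(cls)[1], 1, -1)
  y <- y - mean(y)
  a_max <- min(n_components, nrow(m) - 1, ncol(m))
  E <- m
  f <- y
  W <- NULL; ssy <- numeric()
  for (a in seq_len(a_max)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # no covariance left to model
    w <- w / nw
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) abort(sprintf("NIPALS degenerate at component %d.", a))
    q <- sum(t_a * f) / tt
    p_load <- drop(crossprod(E, t_a)) / tt
    E <- E - tcrossprod(t_a, p_load)
    f <- f - t_a * q
    W <- cbind(W, w)
    ssy <- c(ssy, q^2 * tt)
  }
  if (is.null(W)) abort("NIPALS found no usable component (X'y is zero).")
  p <- ncol(m)
  vip <- sqrt(p * as.vector(W^2 %*% ssy) / sum(ssy))
  ids <- colnames(m)
  rank_tbl("plsda_vip", ids, vip, score_ranks(vip, ids))
}

#' EBAM parameters
#'
#' Knobs of the empirical Bayes ranker: the fudge factor `a0` is the
#' `a0_quantile` quantile of the per-metabolite pooled standard errors; the
#' marginal and null densities are estimated by Lindsey's method (Poisson
#' regression of bin counts on a natural-spline basis); the null comes from
#' label permutations (or the standard normal when `n_permutations = 0`).
#'
#' @param a0_quantile quantile of pooled standard errors for the fudge factor.
#' @param n_permutations label permutations for the null density; 0 uses a
#'   theoretical N(0, 1) null.
#' @param n_bins equal-width histogram bins for Lindsey's method (>= 10).
#' @param spline_df natural-spline degrees of freedom.
#' @param delta posterior threshold for flagging (in (0, 1)).
#' @param seed integer seed for the permutations.
#' @return list of class `ebam_params`.
#' @export
ebam_params <- function(a0_quantile = 0.5, n_permutations = 100, n_bins = 101,
                        spline_df = 5, delta = 0.9, seed = 1L) {
  if (delta <= 0 || delta >= 1) abort("`delta` must lie in (0, 1).")
  if (n_bins < 10) abort("`n_bins` must be >= 10.")
  structure(list(a0_quantile = a0_quantile, n_permutations = n_permutations,
                 n_bins = n_bins, spline_df = spline_df, delta = delta,
                 seed = as.integer(seed)),
            class = "ebam_params")
}

# moderated two-sample z statistics; a0 fixed across permutations
moderated_z <- function(m, cls, a0 = NULL, a0_quantile = 0.5) {
  a_rows <- cls == levels(cls)[1]
  A <- m[a_rows, , drop = FALSE]; B <- m[!a_rows, , drop = FALSE]
  na <- nrow(A); nb <- nrow(B)
  va <- (colSums(A^2) - na * colMeans(A)^2) / (na - 1)
  vb <- (colSums(B^2) - nb * colMeans(B)^2) / (nb - 1)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  s <- sp * sqrt(1 / na + 1 / nb)
  if (is.null(a0)) a0 <- unname(quantile(s, a0_quantile))
  list(z = (colMeans(A) - colMeans(B)) / (s + a0), s = s, a0 = a0)
}

# Lindsey density estimate evaluated at z_eval, fitted on z_fit
lindsey_density <- function(z_eval, z_fit, n_bins, spline_df) {
  rng <- range(z_fit)
  if (diff(rng) <= 0) abort("Degenerate z statistics: no spread to model.")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  width <- breaks[2] - breaks[1]
  mids <- breaks[-1] - width / 2
  bin <- findInterval(z_fit, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  fit <- glm(counts ~ splines::ns(mids, df = spline_df), family = poisson())
  z_cl <- pmin(pmax(z_eval, rng[1]), rng[2])
  lp <- predict(fit, newdata = data.frame(mids = z_cl))
  pmax(exp(lp) / (length(z_fit) * width), 1e-12)
}

#' Rank metabolites by EBAM posterior probability
#'
#' Empirical Bayes analysis in the microarray tradition applied to
#' metabolites: a moderated z statistic
#' `z_j = (mean_A - mean_B) / (s_j + a0)` is computed per metabolite, the
#' marginal density `f(z)` is estimated by Lindsey's method, a null density
#' `f0` is estimated from pooled label-permutation z statistics through the
#' identical estimator (or taken as N(0, 1)), the null proportion is
#' `p0 = min(1, min f(z) / f0(z))` over the central 50% z-interval, and the
#' posterior probability of differential abundance is
#' `max(0, 1 - p0 * f0(z_j) / f(z_j))`. Metabolites are ranked by descending
#' posterior, ties by descending `|z|`; those with posterior at or above
#' `delta` are flagged.
#'
#' @inheritParams rank_plsda_vip
#' @param params an [ebam_params()] list.
#' @return rank tibble (method `"ebam"`) with extra columns `z` and
#'   `flagged`.
#' @export
rank_ebam <- function(scaled, labels, params = ebam_params()) {
  m <- ranker_matrix(scaled)
  cls <- align_classes(rownames(m), labels)
  if (any(table(cls) < 2)) abort("Both classes need >= 2 samples.")
  obs <- moderated_z(m, cls, a0_quantile = params$a0_quantile)
  z <- obs$z
  if (diff(range(z)) <= 0) abort("All z statistics identical; EBAM undefined.")
  f_hat <- lindsey_density(z, z, params$n_bins, params$spline_df)
  if (params$n_permutations > 0) {
    z_null <- withr::with_seed(params$seed, {
      unlist(lapply(seq_len(params$n_permutations), function(b) {
        moderated_z(m, factor(sample(as.character(cls)), levels = levels(cls)),
                    a0 = obs$a0)$z
      }))
    })
    f0_fun <- function(at) lindsey_density(at, z_null, params$n_bins, params$spline_df)
  } else {
    f0_fun <- function(at) pmax(dnorm(at), 1e-12)
  }
  f0_hat <- f0_fun(z)
  ctr <- quantile(z, c(0.25, 0.75))
  central <- z >= ctr[1] & z <= ctr[2]
  p0 <- min(1, min(f_hat[central] / f0_hat[central]))
  posterior <- pmax(0, 1 - p0 * f0_hat / f_hat)
  ids <- colnames(m)
  rank_tbl("ebam", ids, posterior, score_ranks(posterior, ids, secondary = z),
           extra = tibble(z = unname(z), flagged = posterior >= params$delta))
}

#' Random-forest parameters
#'
#' @param n_trees number of trees (>= 1).
#' @param mtry candidate metabolites per split; default `floor(sqrt(p))`.
#' @param seed integer seed.
#' @return list of class `rf_params`.
#' @export
rf_params <- function(n_trees = 500, mtry = NULL, seed = 1L) {
  if (n_trees < 1) abort("`n_trees` must be >= 1.")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry, seed = as.integer(seed)),
            class = "rf_params")
}

#' Rank metabolites by random-forest permutation importance
#'
#' Grows a classification forest on bootstrap samples and scores each
#' metabolite by the mean out-of-bag accuracy decrease after permuting it
#' (unscaled permutation importance). Deterministic given the seed.
#'
#' @inheritParams rank_plsda_vip
#' @param params an [rf_params()] list.
#' @return rank tibble (method `"rf"`).
#' @export
rank_random_forest <- function(scaled, labels, params = rf_params()) {
  m <- ranker_matrix(scaled)
  cls <- align_classes(rownames(m), labels)
  mtry <- params$mtry %||% max(1, floor(sqrt(ncol(m))))
  fit <- withr::with_seed(params$seed, {
    randomForest::randomForest(x = m, y = cls, ntree = params$n_trees,
                               mtry = mtry, importance = TRUE)
  })
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  ids <- colnames(m)
  rank_tbl("rf", ids, unname(imp), score_ranks(unname(imp), ids))
}

#' Run all four rankers
#'
#' @inheritParams rank_plsda_vip
#' @param methods subset of `c("pca", "plsda", "ebam", "rf")`.
#' @param seed integer seed shared by the stochastic rankers (EBAM
#'   permutations, random forest).
#' @param var_threshold,n_components,ebam,rf per-method knobs.
#' @return long tibble binding the rank tibbles of the requested methods.
#' @export
rank_features <- function(scaled, labels,
                          methods = c("pca", "plsda", "ebam", "rf"),
                          seed = 1L,
                          var_threshold = 0.8, n_components = 2,
                          ebam = ebam_params(seed = seed),
                          rf = rf_params(seed = seed)) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  if ("pca" %in% methods) out$pca <- rank_pca(scaled, var_threshold)
  if ("plsda" %in% methods) out$plsda <- rank_plsda_vip(scaled, labels, n_components)
  if ("ebam" %in% methods) {
    out$ebam <- rank_ebam(scaled, labels, ebam) |> select(!dplyr::any_of(c("z", "flagged")))
  }
  if ("rf" %in% methods) out$rf <- rank_random_forest(scaled, labels, rf)
  bind_rows(out)
}
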