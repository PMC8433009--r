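# Independent oracles used to freeze or cross-check expected values.
# Each deliberately takes a different computational route from the package.

# Exhaustive hypergeometric upper tail: enumerate every K-subset of 1..N,
# with the pathway taken as {1..m}, and count subsets whose intersection
# with the pathway reaches k_obs.
enum_hyper_tail <- function(N, m, K, k_obs) {
  sels <- utils::combn(N, K)
  hits <- colSums(sels <= m)
  mean(hits >= k_obs)
}

# Studentized-range CDF by nested numerical integration:
# P(Q <= q) = E_s[ k * Int phi(u) (Phi(u) - Phi(u - q s))^(k-1) du ]
# where s = sqrt(chi2_df / df).
ptukey_quadrature <- function(q, k, df) {
  inner <- function(s) {
    f <- function(u) k * dnorm(u) * pmax(pnorm(u) - pnorm(u - q * s), 0)^(k - 1)
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
  }
  dens_s <- function(s) 2 * s * df * dchisq(s^2 * df, df)
  stats::integrate(function(s) vapply(s, function(si) inner(si) * dens_s(si), 0),
                   0, Inf, rel.tol = 1e-7)$value
}

# PCA variance-weighted loading scores via direct eigendecomposition of the
# sample covariance matrix (package path goes through prcomp's SVD).
pca_score_oracle <- function(X, var_threshold = 0.8) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  keep <- lambda > .Machine$double.eps * lambda[1]
  lambda <- lambda[keep]
  V <- ev$vectors[, keep, drop = FALSE]
  a_star <- seq_len(which(cumsum(lambda) / sum(lambda) >= var_threshold)[1])
  sqrt(as.vector(V[, a_star, drop = FALSE]^2 %*% lambda[a_star]) / sum(lambda[a_star]))
}

# Single-pass hand-rolled NIPALS PLS1 VIP for tiny fixtures (explicit loops).
nipals_vip_oracle <- function(X, y, n_components = 2) {
  E <- X; f <- y - mean(y)
  ws <- list(); ssy <- c()
  for (a in seq_len(n_components)) {
    w <- numeric(ncol(E))
    for (j in seq_len(ncol(E))) w[j] <- sum(E[, j] * f)
    if (sqrt(sum(w^2)) < 1e-12) break
    w <- w / sqrt(sum(w^2))
    t_a <- as.numeric(E %*% w)
    q <- sum(t_a * f) / sum(t_a^2)
    p_l <- as.numeric(t(E) %*% t_a) / sum(t_a^2)
    E <- E - outer(t_a, p_l)
    f <- f - q * t_a
    ws[[a]] <- w; ssy[a] <- q^2 * sum(t_a^2)
  }
  p <- ncol(X)
  vip2 <- numeric(p)
  for (j in seq_len(p)) {
    vip2[j] <- p * sum(ssy * vapply(ws, function(w) w[j]^2, 0)) / sum(ssy)
  }
  sqrt(vip2)
}

# scaled tibble from a plain matrix without going through autoscale()
as_scaled_tbl <- function(m, ids = NULL, samples = NULL) {
  colnames(m) <- ids %||% colnames(m) %||% sprintf("M%03d", seq_len(ncol(m)))
  rownames(m) <- samples %||% rownames(m) %||% sprintf("S%03d", seq_len(nrow(m)))
  out <- tibble::as_tibble(m)
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
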