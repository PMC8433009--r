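test_that("every ranker returns a permutation of 1..p", {
  d <- two_class_data(n_per_class = 8, p = 25, shift = 1, n_shifted = 5, seed = 2)
  ranks <- rank_features(d$scaled, d$labels, seed = 42,
                         ebam = ebam_params(n_permutations = 20, seed = 42))
  for (meth in unique(ranks$method)) {
    expect_setequal(ranks$rank[ranks$method == meth], seq_len(25))
  }
})

test_that("PCA scores match a direct eigendecomposition oracle to 1e-10", {
  withr::with_seed(31, {
    X <- matrix(rnorm(15), 5, 3)
  })
  Xc <- scale(X, center = TRUE, scale = FALSE)
  got <- rank_pca(as_scaled_tbl(Xc, ids = c("a", "b", "c")), var_threshold = 0.8)
  want <- pca_score_oracle(X, var_threshold = 0.8)
  expect_equal(got$score[match(c("a", "b", "c"), got$metabolite_id)], want,
               tolerance = 1e-10)
})

test_that("PCA ranking ignores labels and respects column permutation symmetry", {
  d <- two_class_data(n_per_class = 6, p = 12, seed = 3)
  r1 <- rank_pca(d$scaled)
  # shuffle columns: scores must follow their metabolites
  perm <- c(1, withr::with_seed(10, sample(2:13)))
  r2 <- rank_pca(d$scaled[, perm])
  expect_equal(r2$score[match(r1$metabolite_id, r2$metabolite_id)], r1$score)
  # a zero-variance column gets loading 0 on every PC and lands last
  m <- cbind(as.matrix(d$scaled[, -1]), flat = 0)
  r3 <- rank_pca(as_scaled_tbl(m))
  expect_equal(r3$rank[r3$metabolite_id == "flat"], 13L)
})

test_that("VIP matches the hand-rolled NIPALS oracle on the 4x2 toy", {
  X <- matrix(c(1, 1, -1, -1, 1, -1, 1, -1), ncol = 2,
              dimnames = list(NULL, c("M1", "M2")))
  y <- c(1, 1, -1, -1)
  labels <- tibble::tibble(sample_id = sprintf("S%03d", 1:4),
                           class = ifelse(y > 0, "a", "b"))
  got <- rank_plsda_vip(as_scaled_tbl(X), labels, n_components = 2)
  want <- nipals_vip_oracle(X, y, 2)
  expect_equal(got$score[match(c("M1", "M2"), got$metabolite_id)], want)
  # frozen closed form: all signal on M1 -> VIP = (sqrt(2), 0)
  expect_equal(sort(got$score, decreasing = TRUE), c(sqrt(2), 0))
  expect_gt(got$score[got$metabolite_id == "M1"], 1)
  expect_lt(got$score[got$metabolite_id == "M2"], 1)
})

test_that("VIP is exactly 1 for a single metabolite and sums to p in squares", {
  d1 <- two_class_data(n_per_class = 5, p = 1, seed = 4)
  expect_equal(rank_plsda_vip(d1$scaled, d1$labels)$score, 1)
  for (s in 1:5) {
    d <- two_class_data(n_per_class = 6, p = 17, shift = 0.5, n_shifted = 3,
                        seed = s)
    vip <- rank_plsda_vip(d$scaled, d$labels)$score
    expect_equal(sum(vip^2), 17, tolerance = 1e-8)
  }
})

test_that("exchangeable metabolites get equal VIP", {
  withr::with_seed(6, {
    x <- rnorm(12)
  })
  X <- cbind(M1 = x, M2 = x)  # identical columns are trivially exchangeable
  labels <- tibble::tibble(sample_id = sprintf("S%03d", 1:12),
                           class = rep(c("a", "b"), each = 6))
  vip <- rank_plsda_vip(as_scaled_tbl(X), labels)
  expect_equal(vip$score[1], vip$score[2])
})

test_that("EBAM posteriors live in [0,1]; identical z means identical posterior", {
  d <- two_class_data(n_per_class = 6, p = 30, shift = 1.5, n_shifted = 5, seed = 7)
  m <- as.matrix(d$scaled[, -1])
  m[, 2] <- m[, 1]  # duplicate column -> identical z
  r <- rank_ebam(as_scaled_tbl(m, ids = sprintf("M%03d", 1:30)), d$labels,
                 ebam_params(n_permutations = 25, seed = 7))
  expect_true(all(r$score >= 0 & r$score <= 1))
  expect_equal(r$score[r$metabolite_id == "M001"],
               r$score[r$metabolite_id == "M002"])
  rk <- sort(r$rank[r$metabolite_id %in% c("M001", "M002")])
  expect_equal(diff(rk), 1L)  # adjacent, tie broken deterministically by id
  expect_identical(r, rank_ebam(as_scaled_tbl(m, ids = sprintf("M%03d", 1:30)),
                                d$labels, ebam_params(n_permutations = 25, seed = 7)))
})

test_that("EBAM recovers planted large shifts", {
  hits <- 0L
  for (s in 1:10) {
    d <- two_class_data(n_per_class = 8, p = 200, shift = 2.5, n_shifted = 10,
                        seed = 100 + s)
    r <- rank_ebam(d$scaled, d$labels,
                   ebam_params(n_permutations = 50, seed = s))
    planted <- sprintf("M%03d", 1:10)
    top15 <- r$metabolite_id[r$rank <= 15]
    if (all(planted %in% top15)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("random forest is seed-deterministic and finds a perfect separator", {
  wins <- 0L
  for (s in 1:10) {
    d <- two_class_data(n_per_class = 6, p = 20, seed = 200 + s)
    m <- as.matrix(d$scaled[, -1])
    m[, 1] <- ifelse(d$labels$class == "a", 1, -1)  # perfect separator
    scaled <- as_scaled_tbl(m, ids = sprintf("M%03d", 1:20))
    r <- rank_random_forest(scaled, d$labels, rf_params(n_trees = 300, seed = s))
    if (r$rank[r$metabolite_id == "M001"] == 1L) wins <- wins + 1L
    if (s == 1) {
      expect_identical(r, rank_random_forest(scaled, d$labels,
                                             rf_params(n_trees = 300, seed = s)))
    }
  }
  expect_gte(wins, 9L)
  d <- two_class_data(n_per_class = 6, p = 20, seed = 5)
  one_class <- d$labels
  one_class$class <- "a"
  expect_error(rank_random_forest(d$scaled, one_class), "two classes")
})

test_that("rankers reject incomplete data and missing labels", {
  d <- two_class_data(n_per_class = 4, p = 5, seed = 9)
  m <- as.matrix(d$scaled[, -1])
  m[1, 1] <- NA
  expect_error(rank_pca(as_scaled_tbl(m)), "complete")
  expect_error(rank_plsda_vip(d$scaled, d$labels[-1, ]), "No class label")
})
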