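make_ranks <- function(mat, ids = rownames(mat)) {
  # mat: metabolites x methods integer ranks
  dplyr::bind_rows(lapply(seq_len(ncol(mat)), function(j) {
    tibble::tibble(method = paste0("m", j), metabolite_id = ids,
                   score = -mat[, j], rank = mat[, j])
  }))
}

test_that("median rank consensus matches the exhaustive hand-sorted fixture", {
  rk <- matrix(c(1, 1, 2, 5,
                 2, 3, 1, 1,
                 3, 2, 6, 2,
                 4, 5, 3, 3,
                 5, 4, 4, 6,
                 6, 6, 5, 4), ncol = 4, byrow = TRUE,
               dimnames = list(paste0("m", 1:6), NULL))
  out <- median_rank_consensus(make_ranks(rk), k = 3)
  # hand-computed: medians (1.5, 1.5, 2.5, 3.5, 4.5, 5.5); the m1/m2 tie at
  # 1.5 resolves by mean rank (2.25 vs 1.75) -> m2 first
  expect_equal(out$metabolite_id, c("m2", "m1", "m3", "m4", "m5", "m6"))
  expect_equal(out$consensus_rank, c(1.5, 1.5, 2.5, 3.5, 4.5, 5.5))
  expect_equal(out$selected, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(select_top_k(out, 3), c("m2", "m1", "m3"))
})

test_that("consensus of four identical rankings is that ranking", {
  rk <- matrix(rep(c(3, 1, 4, 2, 5), 4), ncol = 4,
               dimnames = list(paste0("x", 1:5), NULL))
  out <- median_rank_consensus(make_ranks(rk), k = 2)
  expect_equal(out$consensus_rank, 1:5)
  expect_equal(out$metabolite_id, c("x2", "x4", "x1", "x3", "x5"))
})

test_that("ranks (1,2,3,4) give consensus 2.5; unanimous rank 1 comes first", {
  rk <- matrix(c(1, 2, 3, 4,
                 2, 1, 2, 3,
                 3, 3, 1, 1,
                 4, 4, 4, 2), ncol = 4, byrow = TRUE,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  out <- median_rank_consensus(make_ranks(rk))
  expect_equal(out$consensus_rank[out$metabolite_id == "a"], 2.5)
  rk1 <- matrix(c(1, 1, 1, 1, 2, 3, 4, 2, 3, 2, 2, 4, 4, 4, 3, 3),
                ncol = 4, byrow = TRUE,
                dimnames = list(c("top", "b", "c", "d"), NULL))
  out1 <- median_rank_consensus(make_ranks(rk1))
  expect_equal(out1$metabolite_id[1], "top")
  expect_equal(out1$consensus_rank[1], 1)
})

test_that("mismatched metabolite sets error with the symmetric difference", {
  r1 <- tibble::tibble(method = "m1", metabolite_id = c("a", "b"), rank = 1:2)
  r2 <- tibble::tibble(method = "m2", metabolite_id = c("a", "c"), rank = 1:2)
  expect_error(median_rank_consensus(dplyr::bind_rows(r1, r2)), "b.*c|c.*b")
})

test_that("consensus is monotone in any single method's rank", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      p <- 8
      rk <- sapply(1:4, function(j) sample(p))
      rownames(rk) <- paste0("m", seq_len(p))
      out1 <- median_rank_consensus(make_ranks(rk))
      # improve one metabolite in one method by swapping with a better rank
      j <- sample(4, 1)
      i <- which(rk[, j] > 1)[1]
      better <- which(rk[, j] == rk[i, j] - 1)
      rk2 <- rk
      rk2[c(i, better), j] <- rk[c(better, i), j]
      out2 <- median_rank_consensus(make_ranks(rk2))
      id <- rownames(rk)[i]
      expect_lte(out2$consensus_rank[out2$metabolite_id == id],
                 out1$consensus_rank[out1$metabolite_id == id])
    }
  })
})

test_that("selection size and stability behave at the boundaries", {
  rk <- matrix(rep(1:5, 4), ncol = 4, dimnames = list(paste0("m", 1:5), NULL))
  tab <- median_rank_consensus(make_ranks(rk), k = 100)
  expect_equal(length(select_top_k(tab)), 5)          # k > p -> all ids
  expect_identical(select_top_k(tab, 3), select_top_k(tab, 3))
  expect_error(select_top_k(tab, 0), "k")
})

test_that("superfamily chi-squared matches the closed form and pools small cells", {
  ann <- tibble::tibble(metabolite_id = paste0("m", 1:200),
                        superfamily = rep(c("lipid", "amino_acid"), each = 100))
  sel <- c(paste0("m", 1:60), paste0("m", 101:140))  # observed (60, 40)
  res <- superfamily_chisq(sel, ann, ann$metabolite_id)
  expect_equal(res$statistic, 4)        # ((60-50)^2 + (40-50)^2) / 50
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(4, 1, lower.tail = FALSE))
  expect_equal(res$p_value, 0.0455, tolerance = 1e-3)

  # equal proportions -> chi2 = 0, p = 1
  sel_eq <- c(paste0("m", 1:50), paste0("m", 101:150))
  res_eq <- superfamily_chisq(sel_eq, ann, ann$metabolite_id)
  expect_equal(res_eq$statistic, 0)
  expect_equal(res_eq$p_value, 1)

  # pooling: two rare families with expected < 5 merge into "other"
  ann2 <- tibble::tibble(
    metabolite_id = paste0("m", 1:100),
    superfamily = c(rep("lipid", 60), rep("amino_acid", 30),
                    rep("rare1", 6), rep("rare2", 4)))
  sel2 <- paste0("m", seq(1, 100, by = 2))  # K = 50; expected rare1 = 3, rare2 = 2
  res2 <- superfamily_chisq(sel2, ann2, ann2$metabolite_id)
  expect_setequal(res2$pooled, c("rare1", "rare2"))
  expect_equal(res2$df, 2)  # lipid, amino_acid, other
  expect_equal(sum(res2$counts$expected), 50)
  expect_equal(sum(res2$counts$observed), 50)

  # invariance to category ordering
  shuffled <- ann[sample(nrow(ann)), ]
  expect_equal(superfamily_chisq(sel, shuffled, ann$metabolite_id)$statistic,
               res$statistic)
})

test_that("chi-squared degenerates are reported, not computed", {
  ann <- tibble::tibble(metabolite_id = paste0("m", 1:10), superfamily = "lipid")
  res <- superfamily_chisq(paste0("m", 1:3), ann, ann$metabolite_id)
  expect_true(is.na(res$statistic))
  expect_match(res$method, "undefined")
  expect_error(superfamily_chisq("zz", ann, ann$metabolite_id), "universe")
})
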