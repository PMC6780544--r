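# Ratio tables built directly from value matrices keep the statistics tests
# independent of the detection stages.

ratio_tbl_from_matrix <- function(values, groups) {
  # values: metabolites x samples, on the ratio scale
  n_s <- ncol(values)
  tibble::tibble(
    row_id = rep(sprintf("M%04d", seq_len(nrow(values))), each = n_s),
    sample_id = rep(sprintf("S%02d", seq_len(n_s)), nrow(values)),
    group = rep(groups, nrow(values)),
    ratio = as.vector(t(values)),
    observed = TRUE, quantifiable = TRUE, imputed = FALSE
  )
}

groups44 <- rep(c("treatment", "control"), each = 4)

test_that("the pooled t statistic matches the hand-computed worked case", {
  # log2 ratios {0, .1, -.1, 0} vs {1, 1.1, .9, 1}: t = -17.32, df = 6
  tbl <- ratio_tbl_from_matrix(
    matrix(2^c(0, 0.1, -0.1, 0, 1, 1.1, 0.9, 1), nrow = 1), groups44)
  res <- unpaired_t_test(tbl)
  expect_equal(res$t, -17.32051, tolerance = 1e-6)
  expect_equal(res$df, 6)
  expect_equal(res$estimate, -1)
  # agrees with the stats oracle on the same numbers
  ref <- t.test(c(0, 0.1, -0.1, 0), c(1, 1.1, 0.9, 1), var.equal = TRUE)
  expect_equal(res$p, ref$p.value)
  expect_lt(res$p, 1e-5)
})

test_that("identical groups give t = 0, p = 1 and degenerate variance is flagged", {
  same <- ratio_tbl_from_matrix(matrix(2, 1, 8), groups44)
  res <- unpaired_t_test(same)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_true(res$degenerate)
  split <- ratio_tbl_from_matrix(matrix(rep(c(4, 2), each = 4), 1), groups44)
  res2 <- unpaired_t_test(split)
  expect_true(res2$degenerate)
  expect_equal(res2$p, 0)
  expect_identical(res2$t, Inf)
})

test_that("t sign follows the direction of the mean difference", {
  set.seed(1)
  vals <- matrix(2^rnorm(50 * 8, rep(c(1, 0), each = 4)[col(matrix(0, 50, 8))]),
                 50, 8)
  res <- unpaired_t_test(ratio_tbl_from_matrix(vals, groups44))
  expect_true(all(sign(res$t[res$estimate != 0]) ==
                    sign(res$estimate[res$estimate != 0])))
  expect_true(all(res$p > 0 & res$p <= 1))
})

test_that("the null rejection rate at alpha = 0.001 sits inside the binomial band", {
  set.seed(2026)
  n_rows <- 10000
  vals <- matrix(2^rnorm(n_rows * 8), n_rows, 8)
  res <- unpaired_t_test(ratio_tbl_from_matrix(vals, groups44))
  rejections <- sum(res$p < 0.001)
  ci <- qbinom(c(0.005, 0.995), n_rows, 0.001)
  expect_gte(rejections, ci[1])
  expect_lte(rejections, ci[2])
})

test_that("PCA returns ordered variance fractions and separates shifted groups", {
  set.seed(3)
  base <- matrix(2^rnorm(60 * 8, sd = 0.2), 60, 8)
  base[1:30, 5:8] <- base[1:30, 5:8] * 2^1.5   # 30 shifted metabolites
  tbl <- ratio_tbl_from_matrix(base, rep(c("control", "treatment"), each = 4))
  pca <- pca_samples(tbl)
  expect_true(all(diff(pca$var_frac) <= 1e-9))
  expect_lte(sum(pca$var_frac), 1 + 1e-9)
  sc <- tidy(pca)
  m_t <- mean(sc$PC1[sc$group == "treatment"])
  m_c <- mean(sc$PC1[sc$group == "control"])
  expect_true(sign(m_t) != sign(m_c))
})

test_that("PCA reconstructs the scaled data at full rank", {
  set.seed(4)
  vals <- matrix(2^rnorm(12 * 6), 12, 6)
  tbl <- ratio_tbl_from_matrix(vals, rep(c("treatment", "control"), each = 3))
  pca <- pca_samples(tbl)
  X <- log2(t(vals))
  Xs <- scale(X, center = TRUE, scale = TRUE)
  recon <- as.matrix(tidy(pca)[-(1:2)]) %*% t(pca$loadings)
  expect_equal(unname(recon), unname(Xs)[, , drop = TRUE], tolerance = 1e-8)
})

test_that("a single varying metabolite carries all the variance", {
  vals <- matrix(1, 5, 6)
  vals[3, ] <- 2^c(0, 0.5, 1, 1.5, 2, 2.5)
  tbl <- ratio_tbl_from_matrix(vals, rep(c("treatment", "control"), each = 3))
  pca <- suppressMessages(pca_samples(tbl))  # constant rows dropped
  expect_equal(pca$var_frac[1], 1, tolerance = 1e-9)
  expect_identical(length(pca$dropped), 4L)
})

test_that("a perfectly separating metabolite dominates RF importance with zero OOB error", {
  set.seed(5)
  vals <- matrix(2^rnorm(5 * 20, sd = 0.05), 5, 20)
  vals[2, ] <- 2^c(rep(2, 10), rep(-2, 10))    # the separator
  tbl <- ratio_tbl_from_matrix(vals, rep(c("treatment", "control"), each = 10))
  # every split considers all five metabolites, so each tree roots on the
  # separator and the out-of-bag vote is exact
  rf <- rf_classify(tbl, n_trees = 500, seed = 99, mtry = 5)
  expect_equal(rf$oob_error, 0)
  expect_identical(tidy(rf)$row_id[1], "M0002")
  expect_error(rf_classify(tbl, n_trees = 50), ">= 100")
})

test_that("pure-noise metabolites have importance centred at zero", {
  set.seed(6)
  vals <- matrix(2^rnorm(40 * 8), 40, 8)
  rf <- rf_classify(ratio_tbl_from_matrix(vals, groups44),
                    n_trees = 300, seed = 1)
  expect_lt(abs(mean(rf$importance$mda)), 0.05)
})

test_that("RF results are deterministic given the seed and proximity is well-formed", {
  set.seed(7)
  vals <- matrix(2^rnorm(20 * 8, rep(c(0.8, 0), each = 4)[col(matrix(0, 20, 8))]),
                 20, 8)
  tbl <- ratio_tbl_from_matrix(vals, groups44)
  rf1 <- rf_classify(tbl, n_trees = 200, seed = 123)
  rf2 <- rf_classify(tbl, n_trees = 200, seed = 123)
  expect_identical(rf1$oob_error, rf2$oob_error)
  expect_identical(rf1$importance, rf2$importance)
  expect_identical(rf1$proximity, rf2$proximity)
  P <- rf1$proximity
  expect_equal(P, t(P))
  expect_equal(unname(diag(P)), rep(1, 8))
  expect_true(all(P >= 0 & P <= 1))
  expect_identical(dim(rf1$mds), c(8L, 4L))
})

test_that("top_importance ranks by MDA with deterministic ties and annotates direction", {
  set.seed(8)
  vals <- matrix(2^rnorm(30 * 8, rep(c(1, 0), each = 4)[col(matrix(0, 30, 8))]),
                 30, 8)
  rf <- rf_classify(ratio_tbl_from_matrix(vals, groups44),
                    n_trees = 200, seed = 11)
  top <- top_importance(rf, 10)
  expect_identical(nrow(top), 10L)
  expect_true(all(diff(top$mda) <= 0))
  expect_identical(nrow(top_importance(rf, 0)), 0L)
  expect_error(top_importance(rf, 1000))
  expect_true(all(top$direction %in% c("increase", "decrease")))
})
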