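test_that("every patient is held out exactly once", {
  co <- make_null_cohort(3, 5L)
  res <- cl1ocv(co, "ltle", mrmr_config(2, 3),
                mlp_hyper(hidden_layout = 2L, epochs = 50L), seed = 1)
  expect_equal(nrow(res), 10L)
  expect_setequal(res$id, co$id)
  expect_false(anyDuplicated(res$id) > 0)
})

test_that("compiled and reference fold paths are identical", {
  pl <- make_planted_cohort(17, n_nes = 12L, n_ltle = 12L)
  hy <- mlp_hyper(hidden_layout = 3L, epochs = 100L)
  fast <- cl1ocv(pl$cohort, "ltle", mrmr_config(4, 4), hy, seed = 23)
  ref <- cl1ocv(pl$cohort, "ltle", mrmr_config(4, 4), hy, seed = 23,
                engine = "reference")
  expect_identical(fast$predicted, ref$predicted)
  expect_identical(fast$confidence, ref$confidence)
  expect_identical(fast$features, ref$features)
})

test_that("fold feature ranking never sees the held-out patient", {
  pl <- make_planted_cohort(29, n_nes = 10L, n_ltle = 10L)
  co <- pl$cohort
  mc <- mrmr_config(3, 4)
  res <- cl1ocv(co, "ltle", mc, mlp_hyper(hidden_layout = 2L, epochs = 60L),
                seed = 7)
  feats <- assemble_features(co)
  for (i in c(2, 9, 14, 20)) {
    explicit <- mrmr_rank(feats$x[-i, ], feats$labels[-i], mc)
    expect_identical(res$features[i], paste(explicit$feature, collapse = ","))
  }
})

test_that("metrics reproduce hand arithmetic on a fixed confusion table", {
  truth <- c(rep("LTLE", 39), rep("NES", 32))
  pred <- c(rep("LTLE", 30), rep("NES", 9),    # 30 TP, 9 FN
            rep("LTLE", 6), rep("NES", 26))    # 6 FP, 26 TN
  m <- compute_metrics(data.frame(truth = truth, predicted = pred))
  expect_equal(m$sensitivity, 30 / 39)
  expect_equal(m$specificity, 26 / 32)
  expect_equal(m$balanced_accuracy, (30 / 39 + 26 / 32) / 2, tolerance = 1e-12)
  expect_equal(round(m$balanced_accuracy, 3), 0.791)
  expect_equal(m$odds_ratio, (30 * 26) / (6 * 9))
  expect_false(m$odds_ratio_corrected)
  expect_true(m$accuracy_ci["lower"] <= m$accuracy &&
                m$accuracy <= m$accuracy_ci["upper"])
})

test_that("degenerate prediction patterns are handled", {
  truth <- rep(c("LTLE", "NES"), each = 10)
  perfect <- compute_metrics(data.frame(truth = truth, predicted = truth))
  expect_equal(perfect$accuracy, 1)
  expect_true(perfect$odds_ratio_corrected)
  expect_true(is.finite(perfect$odds_ratio))
  inverted <- compute_metrics(data.frame(
    truth = truth, predicted = rev(truth)))
  expect_equal(inverted$accuracy, 0)
  expect_error(compute_metrics(data.frame(truth = truth, predicted = truth),
                               positive_class = "RTLE"), "unknown positive")
})

test_that("trinary metrics include lateralization among detected epilepsy", {
  truth <- c("LTLE", "LTLE", "LTLE", "RTLE", "RTLE", "NES", "NES")
  pred <- c("LTLE", "RTLE", "NES", "RTLE", "LTLE", "NES", "LTLE")
  m <- compute_metrics(data.frame(truth = truth, predicted = pred))
  # detected epilepsy: LTLE->LTLE, LTLE->RTLE, RTLE->RTLE, RTLE->LTLE
  expect_equal(m$lateralization_accuracy, 2 / 4)
  expect_equal(m$balanced_accuracy, mean(c(1 / 3, 1 / 2, 1 / 2)))
})

test_that("accuracy decomposes into sensitivity and specificity exactly", {
  set.seed(77)
  for (rep in 1:25) {
    P <- sample(5:40, 1); N <- sample(5:40, 1)
    truth <- c(rep("LTLE", P), rep("NES", N))
    pred <- sample(c("LTLE", "NES"), P + N, replace = TRUE)
    m <- compute_metrics(data.frame(truth = truth, predicted = pred))
    expect_equal(m$accuracy,
                 (m$sensitivity * P + m$specificity * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("the naive baseline is the largest class share", {
  expect_equal(as.numeric(naive_baseline(c(rep("LTLE", 39), rep("NES", 32)))),
               39 / 71)
  bal <- naive_baseline(rep(c("NES", "LTLE"), 10))
  expect_equal(as.numeric(bal), 0.5)
  expect_equal(attr(bal, "class_label"), "NES")  # canonical-order tie-break
  expect_equal(as.numeric(naive_baseline(rep("RTLE", 4))), 1)
  expect_error(naive_baseline(character(0)), "empty")
})

test_that("squared correlation behaves algebraically and under independence", {
  a <- c(0, 1, 0, 1, 1, 0)
  expect_equal(squared_correlation(a, a, n_boot = 50)$r2, 1)
  expect_equal(squared_correlation(a, 1 - a, n_boot = 50)$r2, 1)
  set.seed(12)
  x <- rbinom(1000, 1, 0.5); y <- rbinom(1000, 1, 0.5)
  r <- squared_correlation(x, y, n_boot = 200, seed = 2)
  expect_lt(r$r2, 0.01)
  expect_true(r$lower <= r$r2 + 1e-12 && r$r2 <= r$upper + 1e-12)
  expect_warning(rc <- squared_correlation(rep(1, 5), c(0, 1, 0, 1, 0)),
                 "constant")
  expect_equal(rc$r2, 0)
  expect_true(rc$degenerate)
  # trinary one-hot averaging: identical trinary streams give 1
  tri <- c("NES", "LTLE", "RTLE", "LTLE", "NES", "RTLE")
  expect_equal(squared_correlation(tri, tri, n_boot = 20)$r2, 1)
})

test_that("cross-validated accuracy beats the naive baseline on planted signal", {
  pl <- make_planted_cohort(55, n_nes = 16L, n_ltle = 20L)
  res <- cl1ocv(pl$cohort, "ltle", mrmr_config(4, 4),
                mlp_hyper(hidden_layout = 3L, epochs = 200L), seed = 5)
  acc <- mean(res$predicted == res$truth)
  naive <- as.numeric(naive_baseline(res$truth))
  expect_gt(acc, naive)
})
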