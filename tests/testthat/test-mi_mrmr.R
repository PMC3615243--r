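test_that("equal-width quantization follows the histogram rule", {
  expect_equal(quantize(c(0, 0.5, 1), 2)$levels, c(0L, 1L, 1L))
  expect_equal(quantize(c(1, 1, 1, 1), 4)$levels, rep(0L, 4))
  expect_equal(quantize(1:6, 3)$levels, c(0L, 0L, 1L, 1L, 2L, 2L))
  # hand-computed edges at 1 + k*5/3
  expect_equal(quantize(1:6, 3)$edges, 1 + (0:3) * 5 / 3)
  expect_error(quantize(numeric(0), 2), "empty")
  expect_error(quantize(c(1, NA), 2), "finite")
  # held-out values clamp to end bins against stored edges
  q <- quantize(c(2, 4), 2)
  expect_equal(quantize(c(1, 5, 3.5), 2, edges = q$edges)$levels, c(0L, 1L, 1L))
})

test_that("quantization agrees with an independent oracle on random draws", {
  set.seed(404)
  for (rep in 1:50) {
    v <- rnorm(sample(3:40, 1))
    Q <- sample(2:8, 1)
    expect_identical(quantize(v, Q)$levels, quantize_oracle(v, Q))
  }
})

test_that("mutual information matches its definition on canonical cases", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(mutual_information(c(0, 0, 0, 1), c(0, 0, 1, 1)),
               mi_oracle(c(0, 0, 0, 1), c(0, 0, 1, 1)), tolerance = 1e-14)
  expect_equal(mutual_information(c(0, 0, 0, 1), c(0, 0, 1, 1)), 0.3112781,
               tolerance = 1e-6)
  expect_error(mutual_information(0:1, 0:2), "length")
})

test_that("mutual information satisfies symmetry, self-information and bounds", {
  set.seed(11)
  entropy <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log2(p))
  }
  for (rep in 1:200) {
    n <- sample(3:25, 1)
    x <- sample(0:3, n, replace = TRUE)
    y <- sample(0:2, n, replace = TRUE)
    i_xy <- mutual_information(x, y)
    expect_equal(i_xy, mutual_information(y, x), tolerance = 1e-12)
    expect_equal(mutual_information(x, x), entropy(x), tolerance = 1e-12)
    expect_gte(i_xy, 0)
    expect_lte(i_xy, min(entropy(x), entropy(y)) + 1e-12)
    expect_equal(i_xy, mi_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("mRMR ranks a label copy first and scores match the MID oracle", {
  set.seed(21)
  n <- 60
  y <- factor(rep(c("NES", "LTLE"), each = n / 2), levels = c("NES", "LTLE"))
  x <- cbind(noise1 = rnorm(n),
             label_copy = as.numeric(y == "LTLE"),
             weak = as.numeric(y == "LTLE") + rnorm(n, sd = 2),
             noise2 = rnorm(n))
  r <- mrmr_rank(x, y, mrmr_config(3, 4))
  expect_equal(r$feature[1], "label_copy")
  expect_equal(nrow(r), 3L)
  expect_false(anyDuplicated(r$feature) > 0)
  # rank-1 relevance is maximal among all candidates
  rels <- vapply(colnames(x), function(j)
    mi_oracle(quantize_oracle(x[, j], 4), y), numeric(1))
  expect_equal(r$relevance_bits[1], unname(max(rels)), tolerance = 1e-12)
  # greedy scores agree with a brute-force MID evaluation
  Xq <- vapply(colnames(x), function(j) quantize_oracle(x[, j], 4),
               integer(n))
  sel <- match(r$feature[1], colnames(x))
  for (k in 2:3) {
    cand <- setdiff(seq_len(ncol(x)), sel)
    scores <- vapply(cand, function(j)
      mid_score_oracle(Xq, as.integer(y), j, sel), numeric(1))
    expect_equal(match(r$feature[k], colnames(x)), cand[which.max(scores)])
    expect_equal(r$mrmr_score_bits[k], max(scores), tolerance = 1e-12)
    sel <- c(sel, cand[which.max(scores)])
  }
})

test_that("a duplicated top feature is penalized into lower ranks", {
  set.seed(31)
  n <- 80
  y <- factor(rep(c("NES", "LTLE"), each = n / 2))
  strong <- as.numeric(y == "LTLE") + rnorm(n, sd = 0.3)
  x <- cbind(strong = strong, duplicate = strong,
             weaker = as.numeric(y == "LTLE") + rnorm(n, sd = 1.2))
  r <- mrmr_rank(x, y, mrmr_config(2, 4))
  expect_equal(r$feature[1], "strong")
  expect_equal(r$feature[2], "weaker")
})

test_that("ranking is invariant to positive affine rescaling of a feature", {
  set.seed(41)
  n <- 50
  y <- factor(rep(c("NES", "LTLE"), each = n / 2))
  x <- cbind(a = rnorm(n) + as.numeric(y == "LTLE"),
             b = rnorm(n), c = rnorm(n) - 0.5 * as.numeric(y == "LTLE"))
  r1 <- mrmr_rank(x, y, mrmr_config(3, 5))
  x2 <- x
  x2[, "a"] <- 100 + 7 * x2[, "a"]  # bins rescale with the range
  r2 <- mrmr_rank(x2, y, mrmr_config(3, 5))
  expect_equal(r1$feature, r2$feature)
  expect_equal(r1$relevance_bits, r2$relevance_bits, tolerance = 1e-12)
})

test_that("F larger than the candidate count is rejected", {
  x <- cbind(a = rnorm(10), b = rnorm(10))
  expect_error(mrmr_rank(x, rep(0:1, 5), mrmr_config(3, 2)), "exceeds")
})
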