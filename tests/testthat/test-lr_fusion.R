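test_that("pattern likelihood ratios follow their definition", {
  tab <- pattern_lr(data.frame(pattern = c("iPET+", "iPET-"),
                               k_E = c(30, 9), k_N = c(6, 26)), 39, 32)
  expect_equal(tab$lr[1], (30 / 39) / (6 / 32))
  expect_equal(round(tab$lr[1], 2), 4.10)
  same <- pattern_lr(data.frame(pattern = c("p", "q"),
                                k_E = c(10, 30), k_N = c(8, 24)), 40, 32)
  expect_equal(same$lr, c(1, 1))
  inf <- pattern_lr(data.frame(pattern = c("p", "q"),
                               k_E = c(5, 34), k_N = c(0, 32)), 39, 32)
  expect_true(inf$infinite[1])
  expect_equal(inf$lr[1], Inf)
  undef <- pattern_lr(data.frame(pattern = c("p", "q"),
                                 k_E = c(0, 39), k_N = c(0, 32)), 39, 32)
  expect_true(undef$undefined[1])
  expect_error(pattern_lr(data.frame(pattern = "p", k_E = 5, k_N = 3), 6, 3),
               "sum")
})

test_that("the plug-in LR conserves probability over finite patterns", {
  set.seed(14)
  for (rep in 1:40) {
    npat <- sample(2:8, 1)
    k_E <- as.vector(rmultinom(1, sample(20:60, 1), rep(1, npat)))
    k_N <- as.vector(rmultinom(1, sample(20:60, 1), rep(1, npat))) + 1L
    tab <- pattern_lr(data.frame(pattern = paste0("p", seq_len(npat)),
                                 k_E = k_E, k_N = k_N), sum(k_E), sum(k_N))
    expect_equal(sum((tab$k_N / tab$n_N) * tab$lr), 1, tolerance = 1e-12)
  }
})

test_that("the chance LR distribution reproduces the worked example", {
  ch <- chance_lr_interval(39, 32, 35)
  expect_equal(signif(ch$median, 2), 1.2)
  # symmetric prior centers the chance LR at one
  expect_equal(chance_lr_interval(25, 25, 10)$median, 1)
  # ordering of the interval
  expect_true(ch$lower <= ch$median && ch$median <= ch$upper)
  expect_error(chance_lr_interval(39, 32, 0), "m must be")
})

test_that("chance quantiles equal exhaustive binomial enumeration", {
  n_pos <- 3; n_neg <- 3; m <- 4
  p <- n_pos / (n_pos + n_neg)
  mass <- dbinom(0:m, m, p)
  cdf <- cumsum(mass)
  q_oracle <- function(prob) (0:m)[which(cdf >= prob - 1e-12)[1]]
  lr_of <- function(k) ifelse(k == 0, 0, ifelse(k == m, Inf, k / (m - k)))
  ch <- chance_lr_interval(n_pos, n_neg, m)
  expect_equal(ch$lower, lr_of(q_oracle(0.025)))
  expect_equal(ch$median, lr_of(q_oracle(0.5)))
  expect_equal(ch$upper, lr_of(q_oracle(0.975)))
})

test_that("the chance median approaches the prior odds for large m", {
  # same prior, ever larger outcome groups
  ch <- chance_lr_interval(39000, 32000, 50000)
  expect_equal(ch$median, 39 / 32, tolerance = 0.01)
  ch2 <- chance_lr_interval(390, 320, 500)
  expect_lt(abs(ch2$median - 39 / 32), abs(chance_lr_interval(39, 32, 35)$median - 39 / 32) + 0.05)
  expect_error(chance_lr_interval(39, 32, 100), "exceeds")
})

test_that("single-stream fusion reproduces pattern_lr and respects availability", {
  co <- generate_cohort(default_table1_spec(seed = 33))
  rep1 <- fusion_report(co, "ltle", "MA_iPET")
  tab <- rep1[["MA_iPET"]]
  keep <- co$diagnosis %in% c("NES", "LTLE") & !is.na(co$reads$ipet)
  pos <- co$reads$ipet[keep] != "negative"
  epi <- co$diagnosis[keep] == "LTLE"
  manual <- pattern_lr(data.frame(pattern = c("MA_iPET+", "MA_iPET-"),
                                  k_E = c(sum(pos & epi), sum(!pos & epi)),
                                  k_N = c(sum(pos & !epi), sum(!pos & !epi))),
                       sum(epi), sum(!epi))
  expect_equal(sort(tab$lr), sort(manual$lr))
  expect_equal(attr(tab, "n_used"), sum(keep))
  expect_equal(sum(tab$k_E), sum(epi))
})

test_that("conditionally independent streams multiply their positive LRs", {
  co <- generate_cohort(cohort_spec(
    n_per_class = c(NES = 2000L, LTLE = 2000L, RTLE = 0L),
    ma_missing = list(ipet = tlecad:::pc(0, 0, 0), smri = tlecad:::pc(0, 0, 0)),
    seed = 44))
  rep2 <- fusion_report(co, "ltle", c("MA_iPET", "MA_sMRI"))
  lr_i <- rep2[["MA_iPET"]]$lr[rep2[["MA_iPET"]]$pattern == "MA_iPET+"]
  lr_s <- rep2[["MA_sMRI"]]$lr[rep2[["MA_sMRI"]]$pattern == "MA_sMRI+"]
  both <- rep2[["MA_iPET+MA_sMRI"]]
  lr_b <- both$lr[both$pattern == "MA_iPET+ MA_sMRI+"]
  expect_equal(lr_b, lr_i * lr_s, tolerance = 0.15)
})

test_that("a three-stream agreement exceeds any single stream on strong signal", {
  co <- generate_cohort(default_table1_spec(seed = 55))
  # fabricate an accurate CAD stream (85% concordant with truth)
  set.seed(5)
  truth <- as.character(co$diagnosis)
  cad <- ifelse(runif(length(truth)) < 0.85, truth,
                ifelse(truth == "NES", "LTLE", "NES"))
  names(cad) <- co$id
  rep3 <- fusion_report(co, "ltle", c("CAD", "MA_iPET", "MA_sMRI"), cad = cad)
  all3 <- rep3[["CAD+MA_iPET+MA_sMRI"]]
  agree_pos <- all3$lr[all3$pattern == "CAD+ MA_iPET+ MA_sMRI+"]
  singles <- c(rep3[["CAD"]]$lr[rep3[["CAD"]]$pattern == "CAD+"],
               rep3[["MA_iPET"]]$lr[rep3[["MA_iPET"]]$pattern == "MA_iPET+"],
               rep3[["MA_sMRI"]]$lr[rep3[["MA_sMRI"]]$pattern == "MA_sMRI+"])
  expect_gt(agree_pos, max(singles))
  expect_error(fusion_report(co, "ltle", "CAD"), "no CAD calls")
})
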