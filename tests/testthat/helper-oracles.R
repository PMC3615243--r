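# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's compiled routines.

# plug-in mutual information in bits from the explicit joint table
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  pxy <- tab / sum(tab)
  px <- rowSums(pxy); py <- colSums(pxy)
  s <- 0
  for (a in seq_along(px)) for (b in seq_along(py)) {
    p <- pxy[a, b]
    if (p > 0) s <- s + p * log2(p / (px[a] * py[b]))
  }
  as.numeric(s)
}

# equal-width quantization done independently
quantize_oracle <- function(v, Q) {
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(rep(0L, length(v)))
  lev <- floor((v - lo) / ((hi - lo) / Q))
  as.integer(pmin(lev, Q - 1L))
}

# mRMR MID score of candidate j given selected set S (columns of Xq)
mid_score_oracle <- function(Xq, y, j, S) {
  rel <- mi_oracle(Xq[, j], y)
  if (!length(S)) return(rel)
  rel - mean(vapply(S, function(s) mi_oracle(Xq[, j], Xq[, s]), numeric(1)))
}

# small well-separated two-class dataset
make_separable <- function(n = 20, seed = 1) {
  set.seed(seed)
  half <- n / 2
  x <- rbind(cbind(rnorm(half, -2, 0.3), rnorm(half, -2, 0.3)),
             cbind(rnorm(half, 2, 0.3), rnorm(half, 2, 0.3)))
  colnames(x) <- c("f1", "f2")
  list(x = x, labels = factor(rep(c("NES", "LTLE"), each = half),
                              levels = c("NES", "LTLE")))
}

# cohort with a strong planted LTLE-vs-NES effect, small n for speed
make_planted_cohort <- function(seed, n_nes = 32L, n_ltle = 39L,
                                shift = -0.12) {
  planted <- c("L ilp temporal C", "L ila temporal C", "L sl temporal C",
               "L pm temporal C", "L hippocampus")
  spec <- cohort_spec(
    n_per_class = c(NES = n_nes, LTLE = n_ltle, RTLE = 0L),
    effect = effect_spec(list(LTLE = setNames(rep(shift, length(planted)),
                                              planted))),
    seed = seed)
  list(cohort = generate_cohort(spec), planted = planted)
}

# a null binary cohort: no metabolic effect anywhere
make_null_cohort <- function(seed, n_per_class = 20L) {
  generate_cohort(cohort_spec(
    n_per_class = c(NES = n_per_class, LTLE = n_per_class, RTLE = 0L),
    effect = effect_spec(list()), seed = seed))
}

# hand-built single-layer binary model (weights chosen directly)
manual_model <- function(classes, bias0, bias1, positive = classes[2]) {
  structure(list(weights = list(matrix(c(0, bias0, 0, bias1), nrow = 2)),
                 classes = classes, positive_class = positive,
                 features = "f1", center = c(f1 = 0), halfwidth = c(f1 = 1),
                 hidden = integer(0),
                 diagnostics = list(restarts = 0L)),
            class = "cad_model")
}

# smooth a matrix with a Gaussian kernel of the given FWHM (grid units)
smooth_field <- function(m, fwhm) {
  sigma <- fwhm / sqrt(8 * log(2))
  half <- ceiling(3 * sigma)
  k <- dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  out <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
  t(apply(out, 1, function(row) stats::filter(row, k, circular = TRUE)))
}
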