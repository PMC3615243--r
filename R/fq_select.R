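#' Cross-validated balanced-accuracy map over the (F, Q) grid
#'
#' Runs a full cyclical leave-one-out cross-validation ([cl1ocv()]) for
#' every combination of mRMR feature count `F` and quantal level `Q`,
#' and standardizes each cell against the naive classifier:
#' `z = (balanced_accuracy - naive) / sqrt(naive (1 - naive) / n)`,
#' a binomial normal approximation at the evaluated n.  Cell seeds are
#' derived from the master seed by a counter, so cells are independent
#' yet reproducible.  A cell whose cross-validation fails is flagged
#' `NA` and excluded from smoothness estimation downstream.
#'
#' @param cohort a `cad_cohort`.
#' @param task see [cl1ocv()].
#' @param F_grid,Q_grid ordered integer grids.
#' @param hyper an [mlp_hyper()].
#' @param seed master seed.
#' @param ... further arguments passed to [cl1ocv()].
#' @return an `fq_field` list with matrices `balanced_accuracy` and `z`
#'   (rows = F, cols = Q), the grids, `naive`, and `n`.
#' @export
accuracy_map <- function(cohort, task, F_grid, Q_grid, hyper = mlp_hyper(),
                         seed = 1L, ...) {
  stopifnot(length(F_grid) >= 1, length(Q_grid) >= 1)
  feats <- task_features(cohort, task, FALSE, FALSE)
  naive <- as.numeric(naive_baseline(feats$labels))
  n <- nrow(feats$x)
  se <- sqrt(naive * (1 - naive) / n)
  ba <- matrix(NA_real_, length(F_grid), length(Q_grid),
               dimnames = list(F = F_grid, Q = Q_grid))
  cell <- 0L
  for (fi in seq_along(F_grid)) for (qi in seq_along(Q_grid)) {
    cell <- cell + 1L
    res <- tryCatch(
      cl1ocv(cohort, task, mrmr_config(F_grid[fi], Q_grid[qi]), hyper,
             seed = derive_seed(seed, 100000L + cell), ...),
      error = function(e) NULL)
    if (!is.null(res))
      ba[fi, qi] <- compute_metrics(res)$balanced_accuracy
  }
  structure(list(F_grid = F_grid, Q_grid = Q_grid, balanced_accuracy = ba,
                 naive = naive, n = n, z = (ba - naive) / se),
            class = "fq_field")
}

#' Estimate field smoothness (FWHM) from first differences
#'
#' Kiebel-style estimator: the field is standardized to zero mean and
#' unit variance, the variance `v` of its first differences along an axis
#' estimates the derivative variance, and
#' `FWHM = sqrt(4 log(2) / v)` in grid units, clipped below at 1 grid
#' unit.  A (near-)constant field has no estimable roughness and returns
#' `Inf` with a flag.
#'
#' @param z numeric matrix (at least 2 x 2), `NA` cells allowed (their
#'   differences are dropped).
#' @return list with `fwhm` (length 2: rows axis, cols axis) and
#'   `degenerate`.
#' @export
estimate_fwhm <- function(z) {
  if (is.list(z) && !is.null(z$z)) z <- z$z
  if (nrow(z) < 2L || ncol(z) < 2L) stop("field must be at least 2 x 2")
  s <- stats::sd(z, na.rm = TRUE)
  if (!is.finite(s) || s < .Machine$double.eps^0.5)
    return(list(fwhm = c(Inf, Inf), degenerate = TRUE))
  zc <- (z - mean(z, na.rm = TRUE)) / s
  vdiff <- function(m) {
    d <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
    d <- d[!is.na(d)]
    if (length(d) < 2L) return(NA_real_)
    mean(d^2)
  }
  v_rows <- vdiff(zc)          # differences along the row (F) axis
  v_cols <- vdiff(t(zc))       # along the column (Q) axis
  fwhm <- sqrt(4 * log(2) / c(v_rows, v_cols))
  fwhm <- pmax(fwhm, 1)
  list(fwhm = fwhm, degenerate = FALSE)
}

# Gaussian-field Euler characteristic densities (2-D)
ec_density0 <- function(u) stats::pnorm(u, lower.tail = FALSE)
ec_density1 <- function(u) sqrt(4 * log(2)) / (2 * pi) * exp(-u^2 / 2)
ec_density2 <- function(u) 4 * log(2) / (2 * pi)^1.5 * u * exp(-u^2 / 2)

#' Random-field-theory corrected z threshold
#'
#' Solves `E[EC(u)] = alpha` for a 2-D Gaussian field via the expected
#' Euler characteristic `R0 rho0(u) + R1 rho1(u) + R2 rho2(u)`, with
#' resel counts `R2 = area / (fwhm_F * fwhm_Q)`,
#' `R1 = (LF / fwhm_F) + (LQ / fwhm_Q)` (half-perimeter terms) and
#' `R0 = 1`, where the search region is the `(nF - 1) x (nQ - 1)` grid
#' rectangle in grid units.  The returned threshold never falls below the
#' pointwise `z_(1 - alpha)`.
#'
#' @param fwhm length-2 per-axis FWHM in grid units (>= 1); `Inf` is
#'   allowed and collapses the field to a single effective test.
#' @param grid_shape `c(nF, nQ)`.
#' @param alpha family-wise error level in `(0, 0.5)`.
#' @return list with the threshold `u`, resel counts and the inputs.
#' @export
rft_threshold <- function(fwhm, grid_shape, alpha = 0.05) {
  stopifnot(length(fwhm) == 2L, all(fwhm >= 1), alpha > 0, alpha < 0.5)
  LF <- max(grid_shape[1] - 1, 0); LQ <- max(grid_shape[2] - 1, 0)
  R0 <- 1
  R1 <- LF / fwhm[1] + LQ / fwhm[2]
  R2 <- (LF * LQ) / (fwhm[1] * fwhm[2])
  expected_ec <- function(u)
    R0 * ec_density0(u) + R1 * ec_density1(u) + R2 * ec_density2(u)
  lo <- stats::qnorm(1 - alpha)
  if (expected_ec(10) > alpha)
    stop("no root in [z_(1-alpha), 10]; field too rough for this alpha")
  u <- if (expected_ec(lo) <= alpha) lo
  else stats::uniroot(function(u) expected_ec(u) - alpha, c(lo, 10),
                      tol = 1e-10)$root
  list(u = max(u, lo), resels = c(R0 = R0, R1 = R1, R2 = R2),
       fwhm = fwhm, alpha = alpha, grid_shape = grid_shape)
}

#' Significance mask and representative operating point
#'
#' Thresholds the standardized (F, Q) field at the RFT-corrected `u`,
#' then returns the significant cell nearest (Euclidean distance in grid
#' indices) to the mask centroid — a representative, rather than
#' extreme, operating point.  Ties resolve to smaller F, then smaller Q.
#'
#' @param field an `fq_field` from [accuracy_map()].
#' @param rft result of [rft_threshold()] for this field, or `NULL` to
#'   compute it from [estimate_fwhm()] at `alpha`.
#' @param alpha used only when `rft` is `NULL`.
#' @param fallback_pointwise when the corrected mask is empty, fall back
#'   (with a warning) to the pointwise maximum-z cell instead of
#'   declaring non-significance.
#' @return an `rft_result` list: `u`, `fwhm`, `resels`, logical
#'   `significant_mask`, `significant` flag, and `chosen` (named vector
#'   `c(F =, Q =)`, or `NULL` when non-significant without fallback).
#' @export
select_operating_point <- function(field, rft = NULL, alpha = 0.05,
                                   fallback_pointwise = FALSE) {
  stopifnot(inherits(field, "fq_field"))
  sm <- estimate_fwhm(field$z)
  if (is.null(rft)) {
    fw <- if (sm$degenerate) c(Inf, Inf) else sm$fwhm
    rft <- rft_threshold(fw, dim(field$z), alpha)
  }
  mask <- !is.na(field$z) & field$z > rft$u
  pick <- function(cells) {
    # cells: matrix of (row, col); ties -> smaller F then smaller Q
    ctr <- colMeans(cells)
    d <- sqrt((cells[, 1] - ctr[1])^2 + (cells[, 2] - ctr[2])^2)
    ord <- order(d, cells[, 1], cells[, 2])
    cells[ord[1L], ]
  }
  chosen <- NULL; significant <- any(mask)
  if (significant) {
    idx <- pick(which(mask, arr.ind = TRUE))
    chosen <- c(F = field$F_grid[idx[1]], Q = field$Q_grid[idx[2]])
  } else if (fallback_pointwise) {
    warning("no cell survives the corrected threshold; falling back to the pointwise maximum")
    idx <- which(field$z == max(field$z, na.rm = TRUE), arr.ind = TRUE)[1, ]
    chosen <- c(F = field$F_grid[idx[1]], Q = field$Q_grid[idx[2]])
  }
  structure(list(u = rft$u, fwhm = rft$fwhm, resels = rft$resels,
                 alpha = rft$alpha, significant_mask = mask,
                 significant = significant, chosen = chosen,
                 smoothness_degenerate = sm$degenerate),
            class = "rft_result")
}

#' Write an (F, Q) field and its mask as TSV plus a JSON summary
#' @param field an `fq_field`.
#' @param rft an `rft_result` (optional).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fq_field <- function(field, rft = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wm <- function(m, f) utils::write.table(m, file.path(dir, f), sep = "\t",
                                          row.names = TRUE, col.names = NA,
                                          quote = FALSE)
  wm(field$balanced_accuracy, "fq_balanced_accuracy.tsv")
  wm(field$z, "fq_z.tsv")
  summ <- list(F_grid = field$F_grid, Q_grid = field$Q_grid,
               naive = field$naive, n = field$n)
  if (!is.null(rft)) {
    wm(rft$significant_mask * 1, "fq_significant_mask.tsv")
    summ <- c(summ, list(u = rft$u, fwhm = rft$fwhm, resels = as.list(rft$resels),
                         alpha = rft$alpha, significant = rft$significant,
                         chosen = as.list(rft$chosen)))
  }
  jsonlite::write_json(summ, file.path(dir, "fq_summary.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
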