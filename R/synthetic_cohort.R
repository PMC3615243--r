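#' Metabolic effect specification for the synthetic generator
#'
#' Describes how each diagnostic class perturbs the ROI vector: every
#' value is `baseline_mean + shift + noise`, where the noise is a
#' zero-mean Gaussian with standard deviation `noise_sd` and an
#' exchangeable within-patient correlation `roi_correlation` (a shared
#' patient-level component plus independent ROI components).  Shifts are
#' additive on the whole-brain-normalized scale, negative for
#' hypometabolism.  Generated values are floored at `floor` to keep them
#' positive.
#'
#' @param shifts named list, one element per diagnosis, each a named
#'   numeric vector `ROI name -> shift` (missing ROIs shift 0).
#' @param noise_sd per-ROI noise standard deviation.
#' @param baseline_mean baseline normalized metabolism (about 1).
#' @param roi_correlation exchangeable correlation in `[0, 1)`.
#' @param floor small positive lower truncation for generated values.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(shifts = list(), noise_sd = 0.08, baseline_mean = 1,
                        roi_correlation = 0.3, floor = 0.05) {
  stopifnot(baseline_mean > 0, noise_sd > 0,
            roi_correlation >= 0, roi_correlation < 1, floor > 0)
  structure(list(shifts = shifts, noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 roi_correlation = roi_correlation, floor = floor),
            class = "effect_spec")
}

default_effect_shifts <- function() {
  ltle <- c("L ilp temporal C" = -0.08, "L ila temporal C" = -0.08,
            "L sl temporal C" = -0.06, "L pm temporal C" = -0.06,
            "L hippocampus" = -0.06,
            # distributed secondary effects along connected regions
            "Midbrain" = -0.04, "R ilp temporal C" = -0.03,
            "R hippocampus" = -0.03, "L Broca's Region" = -0.03,
            "L s frontal C" = -0.02, "L associative visual C" = -0.02)
  rtle <- c("R ila temporal C" = -0.08, "R ilp temporal C" = -0.08,
            "R sl temporal C" = -0.06, "R pm temporal C" = -0.06,
            "R hippocampus" = -0.06,
            "R thalamus" = -0.04, "L ilp temporal C" = -0.03,
            "L hippocampus" = -0.03, "R i frontal C" = -0.03,
            "L sensorimotor C" = -0.02)
  list(NES = numeric(0), LTLE = ltle, RTLE = rtle)
}

#' Cohort specification for the synthetic generator
#'
#' @param n_per_class named integer vector `c(NES=, LTLE=, RTLE=)`.
#' @param effect an [effect_spec()].
#' @param clinical_params list with per-class (NES, LTLE, RTLE) vectors:
#'   `female_frac`, `age_mean`, `age_sd`, `duration_mean`, `duration_sd`
#'   (years), `frequency_mean`, `frequency_sd` (events/month).  Duration
#'   and frequency are drawn log-normally matched to mean/SD (skewed,
#'   positive); age is normal truncated to `[16, 90]`.
#' @param ma_rates list with `ipet` and `smri`, each a per-class
#'   positivity probability vector.
#' @param ma_missing list like `ma_rates` with per-class probabilities of
#'   a missing (unavailable) report.
#' @param lat_concordance probability that a positive MA call in an
#'   epilepsy class is lateralized to the true side; the remainder is
#'   split evenly between bilateral and contralateral.  Positive calls in
#'   NES pick left/right at random.
#' @param atlas ROI names.
#' @param seed integer seed making generation deterministic.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_class = c(NES = 32L, LTLE = 39L, RTLE = 34L),
                        effect = effect_spec(default_effect_shifts()),
                        clinical_params = NULL, ma_rates = NULL,
                        ma_missing = NULL, lat_concordance = 0.9,
                        atlas = default_atlas(), seed = 1L) {
  n_per_class <- n_per_class[DIAGNOSIS_LEVELS]
  names(n_per_class) <- DIAGNOSIS_LEVELS
  stopifnot(all(n_per_class >= 0), lat_concordance >= 0, lat_concordance <= 1)
  if (is.null(clinical_params)) clinical_params <- default_clinical_params()
  if (is.null(ma_rates)) ma_rates <- default_ma_rates()
  if (is.null(ma_missing)) ma_missing <- default_ma_missing()
  for (m in names(ma_rates))
    stopifnot(all(ma_rates[[m]] >= 0 & ma_rates[[m]] <= 1))
  structure(list(n_per_class = n_per_class, effect = effect,
                 clinical_params = clinical_params, ma_rates = ma_rates,
                 ma_missing = ma_missing, lat_concordance = lat_concordance,
                 atlas = atlas, seed = as.integer(seed)),
            class = "cohort_spec")
}

pc <- function(...) {
  v <- c(...)
  names(v) <- DIAGNOSIS_LEVELS
  v
}

default_clinical_params <- function() {
  list(female_frac = pc(0.781, 0.538, 0.353),
       age_mean = pc(37, 38, 36), age_sd = pc(14, 12, 13),
       duration_mean = pc(12, 22, 20), duration_sd = pc(12, 15, 13),
       # events/month: 3.2/d, 1.2/d, 1.5/w converted at 30.44 d and
       # 4.348 w per month
       frequency_mean = pc(97.4, 36.5, 6.5),
       frequency_sd = pc(179.6, 73.1, 7.4))
}

default_ma_rates <- function() {
  list(ipet = pc(0.188, 0.769, 0.879), smri = pc(0.345, 0.737, 0.875))
}

default_ma_missing <- function() {
  list(ipet = pc(0, 0, 1 / 34), smri = pc(3 / 32, 1 / 39, 2 / 34))
}

#' Reference synthetic-study specification
#'
#' A [cohort_spec()] whose class sizes (32 NES, 39 LTLE, 34 RTLE),
#' clinical covariate distributions, manual-read positivity rates and
#' report-availability rates match the published study-population table,
#' with the default lateralized temporal hypometabolism effects.
#'
#' @param seed integer seed.
#' @return a `cohort_spec`.
#' @export
default_table1_spec <- function(seed = 1L) cohort_spec(seed = seed)

rlnorm_ms <- function(n, m, s) {
  # log-normal parameterized by arithmetic mean and SD
  sdlog2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

draw_ma_calls <- function(n, cls, true_side, rate, missing_p, concordance) {
  call <- rep("negative", n)
  pos <- stats::runif(n) < rate
  if (cls == "NES") {
    call[pos] <- sample(c("left_abnormal", "right_abnormal"), sum(pos),
                        replace = TRUE)
  } else {
    correct <- paste0(true_side, "_abnormal")
    other <- paste0(setdiff(c("left", "right"), true_side), "_abnormal")
    u <- stats::runif(n)
    call[pos & u < concordance] <- correct
    call[pos & u >= concordance & u < concordance + (1 - concordance) / 2] <-
      "bilateral_abnormal"
    call[pos & u >= concordance + (1 - concordance) / 2] <- other
  }
  call[stats::runif(n) < missing_p] <- NA_character_
  call
}

#' Generate a synthetic cohort
#'
#' Deterministic given `spec$seed`.  ROI values are baseline + class
#' shift + exchangeably correlated Gaussian noise, floored at a small
#' positive constant; clinical covariates and manual reads are drawn from
#' the per-class distributions in the spec (see [cohort_spec()]).
#'
#' @param spec a [cohort_spec()].
#' @return a `cad_cohort`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    atlas <- spec$atlas
    p <- length(atlas)
    eff <- spec$effect
    rho <- eff$roi_correlation
    cp <- spec$clinical_params
    roi_blocks <- list(); cl_blocks <- list()
    diag <- character(0); ipet <- character(0); smri <- character(0)
    for (cls in DIAGNOSIS_LEVELS) {
      n <- spec$n_per_class[[cls]]
      if (n == 0) next
      shift <- rep(0, p); names(shift) <- atlas
      sh <- eff$shifts[[cls]]
      if (length(sh)) {
        unknown <- setdiff(names(sh), atlas)
        if (length(unknown)) stop("shift names ROI not in atlas: ",
                                  paste(unknown, collapse = ", "))
        shift[names(sh)] <- sh
      }
      shared <- stats::rnorm(n)
      noise <- eff$noise_sd * (sqrt(rho) * shared +
                                 sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p))
      block <- pmax(rep(eff$baseline_mean + shift, each = n) + noise, eff$floor)
      colnames(block) <- atlas
      roi_blocks[[cls]] <- block
      cl_blocks[[cls]] <- data.frame(
        age = pmin(pmax(stats::rnorm(n, cp$age_mean[[cls]], cp$age_sd[[cls]]), 16), 90),
        sex = ifelse(stats::runif(n) < cp$female_frac[[cls]], "female", "male"),
        duration = rlnorm_ms(n, cp$duration_mean[[cls]], cp$duration_sd[[cls]]),
        frequency = rlnorm_ms(n, cp$frequency_mean[[cls]], cp$frequency_sd[[cls]]))
      true_side <- if (cls == "LTLE") "left" else "right"
      ipet <- c(ipet, draw_ma_calls(n, cls, true_side, spec$ma_rates$ipet[[cls]],
                                    spec$ma_missing$ipet[[cls]], spec$lat_concordance))
      smri <- c(smri, draw_ma_calls(n, cls, true_side, spec$ma_rates$smri[[cls]],
                                    spec$ma_missing$smri[[cls]], spec$lat_concordance))
      diag <- c(diag, rep(cls, n))
    }
    roi <- do.call(rbind, roi_blocks)
    rownames(roi) <- NULL
    id <- sprintf("P%03d", seq_along(diag))
    new_cohort(id, diag, roi, do.call(rbind, cl_blocks),
               data.frame(ipet = ipet, smri = smri), atlas = atlas)
  })
}
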