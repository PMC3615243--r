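#' Likelihood ratios for outcome patterns
#'
#' For each pattern of per-stream positive/negative calls, the
#' likelihood ratio is the probability of the pattern given epilepsy
#' divided by its probability given NES:
#' `LR = (k_E / n_E) / (k_N / n_N)`.  `k_N = 0` with `k_E > 0` yields a
#' flagged infinite LR; `k_E = k_N = 0` is flagged undefined.
#'
#' @param counts data.frame with one row per pattern: a `pattern`
#'   label column plus integer `k_E` and `k_N`.
#' @param n_E,n_N class totals; pattern counts must sum to them.
#' @return an `lr_table` data.frame with `lr`, `infinite`, `undefined`.
#' @export
pattern_lr <- function(counts, n_E, n_N) {
  if (sum(counts$k_E) != n_E || sum(counts$k_N) != n_N)
    stop("pattern counts do not sum to the class totals")
  if (any(counts$k_E < 0 | counts$k_N < 0)) stop("negative pattern count")
  lr <- (counts$k_E / n_E) / (counts$k_N / n_N)
  undefined <- counts$k_E == 0 & counts$k_N == 0
  infinite <- counts$k_N == 0 & counts$k_E > 0
  lr[undefined] <- NA_real_
  out <- data.frame(counts, n_E = n_E, n_N = n_N, lr = lr,
                    infinite = infinite, undefined = undefined,
                    stringsAsFactors = FALSE)
  class(out) <- c("lr_table", "data.frame")
  out
}

#' Exact-binomial chance interval for a likelihood ratio
#'
#' Models a chance classifier that assigns the outcome of interest to
#' `m` patients according to the prior alone: the number of true
#' positives among them is `k ~ Binomial(m, n_pos / (n_pos + n_neg))`,
#' and the induced likelihood ratio is encoded as the posterior odds
#' among the outcome-holders, `LR(k) = k / (m - k)`.  Returns the median
#' and the `alpha/2`, `1 - alpha/2` quantiles of that induced
#' distribution (exact binomial quantiles).  `k = 0` or `k = m` at a
#' quantile gives a one-sided unbounded bound, reported as 0 or `Inf`.
#'
#' @param n_pos,n_neg class sizes (epilepsy, NES).
#' @param m number of patients holding the outcome of interest (>= 1).
#' @param alpha two-sided level (default 0.05 for a 95% interval).
#' @return list with `median`, `lower`, `upper`, and the binomial
#'   parameters.
#' @export
chance_lr_interval <- function(n_pos, n_neg, m, alpha = 0.05) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  if (m < 1) stop("m must be >= 1")
  if (m > n_pos + n_neg) stop("m exceeds the cohort size")
  p <- n_pos / (n_pos + n_neg)
  lr_of <- function(k) ifelse(k == 0, 0, ifelse(k == m, Inf, k / (m - k)))
  ks <- stats::qbinom(c(alpha / 2, 0.5, 1 - alpha / 2), m, p)
  list(median = lr_of(ks[2]), lower = lr_of(ks[1]), upper = lr_of(ks[3]),
       m = m, p = p, k_quantiles = ks)
}

stream_calls <- function(cohort, stream, task, cad) {
  pos_level <- switch(task, ltle = "LTLE", rtle = "RTLE")
  if (stream == "CAD") {
    if (is.null(cad)) stop("CAD stream requested but no CAD calls supplied")
    calls <- cad[cohort$id]
    return(ifelse(is.na(calls), NA, calls == pos_level))
  }
  col <- switch(stream, MA_iPET = cohort$reads$ipet, MA_sMRI = cohort$reads$smri)
  ifelse(is.na(col), NA, col != "negative")
}

#' Likelihood-ratio fusion report across analysis streams
#'
#' Enumerates every subset of the requested analysis streams (CAD,
#' manual iPET, manual sMRI) of size 1..k for a binary task; within each
#' subset, cross-tabulates the `2^size` positive/negative outcome
#' patterns against the gold-standard diagnosis, computes the pattern
#' likelihood ratios, and attaches the exact-binomial chance median and
#' 95% interval ([chance_lr_interval()]) conditioned on the number of
#' patients showing each pattern.  Patients missing any stream of a
#' subset are excluded from that subset only, so n varies by subset and
#' is reported.  A pattern is flagged significant when its chance
#' interval lies entirely on the opposite side of the observed LR's side
#' of 1 excluded — i.e. observed LR > 1 with chance upper bound below it,
#' or observed LR < 1 with chance lower bound above it.
#'
#' @param cohort a `cad_cohort` (binary task subset is taken internally).
#' @param task `"ltle"` or `"rtle"`.
#' @param streams character subset of `c("CAD", "MA_iPET", "MA_sMRI")`.
#' @param cad named vector (patient id -> predicted class) of CAD calls,
#'   e.g. from [cl1ocv()]; required when `"CAD"` is included.
#' @param alpha chance-interval level.
#' @return list of `lr_table`s keyed by subset (names like
#'   `"CAD+MA_iPET"`), each with chance columns and attribute `n_used`.
#' @export
fusion_report <- function(cohort, task = c("ltle", "rtle"), streams,
                          cad = NULL, alpha = 0.05) {
  task <- match.arg(task)
  streams <- match.arg(streams, c("CAD", "MA_iPET", "MA_sMRI"),
                       several.ok = TRUE)
  if (!length(streams)) stop("empty stream subset")
  pos_level <- switch(task, ltle = "LTLE", rtle = "RTLE")
  keep <- cohort$diagnosis %in% c("NES", pos_level)
  sub <- cohort_subset(cohort, which(keep))
  truth_pos <- sub$diagnosis == pos_level
  calls <- lapply(stats::setNames(streams, streams), stream_calls,
                  cohort = sub, task = task, cad = cad)
  out <- list()
  for (size in seq_along(streams)) {
    for (subset in utils::combn(streams, size, simplify = FALSE)) {
      mat <- do.call(cbind, calls[subset])
      ok <- !apply(is.na(mat), 1L, any)
      m_truth <- truth_pos[ok]
      m_calls <- mat[ok, , drop = FALSE]
      n_E <- sum(m_truth); n_N <- sum(!m_truth)
      grid <- expand.grid(rep(list(c(TRUE, FALSE)), size))
      names(grid) <- subset
      lab <- apply(grid, 1L, function(r)
        paste(ifelse(unlist(r), paste0(subset, "+"), paste0(subset, "-")),
              collapse = " "))
      kE <- kN <- integer(nrow(grid))
      for (g in seq_len(nrow(grid))) {
        hit <- apply(m_calls, 1L, function(r) all(r == unlist(grid[g, ])))
        kE[g] <- sum(hit & m_truth); kN[g] <- sum(hit & !m_truth)
      }
      tab <- pattern_lr(data.frame(pattern = lab, k_E = kE, k_N = kN,
                                   stringsAsFactors = FALSE), n_E, n_N)
      tab$agreement <- apply(grid, 1L, function(r) length(unique(unlist(r))) == 1L)
      m_tot <- kE + kN
      ch <- lapply(m_tot, function(m)
        if (m >= 1) chance_lr_interval(n_E, n_N, m, alpha)
        else list(median = NA_real_, lower = NA_real_, upper = NA_real_))
      tab$m <- m_tot
      tab$chance_median <- vapply(ch, `[[`, numeric(1), "median")
      tab$chance_lower <- vapply(ch, `[[`, numeric(1), "lower")
      tab$chance_upper <- vapply(ch, `[[`, numeric(1), "upper")
      tab$significant <- !tab$undefined & !is.na(tab$chance_median) &
        ((!tab$infinite & tab$lr > 1 & tab$chance_upper < tab$lr) |
           (tab$infinite & tab$chance_upper < Inf) |
           (!tab$infinite & tab$lr < 1 & tab$chance_lower > tab$lr))
      attr(tab, "n_used") <- sum(ok)
      out[[paste(subset, collapse = "+")]] <- tab
    }
  }
  out
}

#' Write fusion LR tables as TSV and JSON
#' @param report result of [fusion_report()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_lr_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    f <- gsub("[^A-Za-z0-9_+-]", "_", nm)
    utils::write.table(as.data.frame(report[[nm]]),
                       file.path(dir, paste0("lr_", f, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(lapply(report, as.data.frame),
                       file.path(dir, "lr_tables.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}
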