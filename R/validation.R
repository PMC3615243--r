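task_features <- function(cohort, task, include_clinical, include_ma) {
  task <- match.arg(task, c("ltle", "rtle", "trinary"))
  keep_levels <- switch(task,
                        ltle = c("NES", "LTLE"),
                        rtle = c("NES", "RTLE"),
                        trinary = DIAGNOSIS_LEVELS)
  idx <- which(cohort$diagnosis %in% keep_levels)
  if (!length(idx)) stop("cohort has no patients for task ", task)
  sub <- cohort_subset(cohort, idx)
  assemble_features(sub, include_clinical = include_clinical,
                    include_ma = include_ma,
                    trinary_ma_split = include_ma && task == "trinary")
}

#' Cyclical leave-one-out cross-validation
#'
#' Each patient is held out once.  Within every fold the mRMR feature
#' ranking is recomputed on the remaining n - 1 patients only, the top
#' `F` features kept, ranges for \[-1, 1\] normalization and
#' misclassification costs derived from the training fold, the
#' (cost-sensitive) MLP trained, and the held-out patient predicted.
#' Classification uses the unquantized features; quantization enters only
#' the mutual-information ranking.  Deterministic given `seed` (fold
#' seeds are derived from it).
#'
#' @param cohort a `cad_cohort`.
#' @param task `"ltle"` (LTLE vs NES), `"rtle"` (RTLE vs NES) or
#'   `"trinary"`.
#' @param mrmr an [mrmr_config()].
#' @param hyper an [mlp_hyper()] (its `seed` field is overridden
#'   per fold).
#' @param seed master seed.
#' @param include_clinical,include_ma feature augmentation flags (see
#'   [assemble_features()]); patients with missing augmented features are
#'   excluded before folding.
#' @param engine `"auto"` runs binary folds with a fixed topology in
#'   compiled code; `"reference"` forces the plain R fold loop.  The two
#'   share every numerical primitive and give identical results (asserted
#'   in the test suite).
#' @return a `cl1ocv_result` data.frame with one row per patient: `id`,
#'   `truth`, `predicted`, `confidence`, `tie`, and `features` (the
#'   fold's selected features, comma-separated).  Attributes: `task`,
#'   `ties` (count), `n`.
#' @export
cl1ocv <- function(cohort, task, mrmr, hyper = mlp_hyper(), seed = 1L,
                   include_clinical = FALSE, include_ma = FALSE,
                   engine = c("auto", "reference")) {
  engine <- match.arg(engine)
  feats <- task_features(cohort, task, include_clinical, include_ma)
  x <- feats$x; labels <- feats$labels
  n <- nrow(x)
  if (nlevels(labels) < 2L) stop("fold with a missing class")
  rows <- vector("list", n)
  # binary tasks with a fixed topology run each fold in compiled code;
  # the routine uses the same quantize/mRMR/normalize/train primitives as
  # the R path below, so both give identical folds
  if (engine == "auto" && task != "trinary" && !is.null(hyper$hidden_layout)) {
    y01 <- as.integer(labels) - 1L
    if (min(table(y01)) < 2L) stop("a class has fewer than two patients")
    pred_i <- integer(n); conf <- numeric(n); featsel <- character(n)
    hid <- as.integer(hyper$hidden_layout)
    miq <- mrmr$variant == "MIQ"
    cn <- colnames(x)
    for (i in seq_len(n)) {
      fd <- cpp_fold_binary(x, y01, i, mrmr$F, mrmr$Q, miq, hid,
                            hyper$learning_rate, hyper$momentum,
                            hyper$epochs, derive_seed(seed, i),
                            hyper$max_consecutive_errors, hyper$max_restarts)
      pred_i[i] <- fd$predicted
      conf[i] <- fd$confidence
      featsel[i] <- paste(cn[fd$order], collapse = ",")
    }
    out <- data.frame(id = feats$id, truth = as.character(labels),
                      predicted = levels(labels)[pred_i + 1L],
                      confidence = conf, tie = FALSE, features = featsel,
                      stringsAsFactors = FALSE)
    attr(out, "task") <- task
    attr(out, "ties") <- 0L
    attr(out, "n") <- n
    class(out) <- c("cl1ocv_result", "data.frame")
    return(out)
  }
  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]
    tr_lab <- droplevels(labels[-i])
    if (nlevels(tr_lab) < (if (task == "trinary") 3L else 2L))
      stop("fold ", i, " lost a class; cannot train")
    ranked <- mrmr_rank(tr_x, tr_lab, mrmr)
    sel <- ranked$feature
    hy <- hyper; hy$seed <- derive_seed(seed, i)
    if (task == "trinary") {
      model <- train_trinary(tr_x[, sel, drop = FALSE], tr_lab, hy)
    } else {
      model <- train_binary(tr_x[, sel, drop = FALSE], tr_lab, hy)
    }
    pred <- predict(model, x[i, sel, drop = FALSE])
    rows[[i]] <- data.frame(id = feats$id[i],
                            truth = as.character(labels[i]),
                            predicted = pred$class,
                            confidence = pred$confidence,
                            tie = if ("tie" %in% names(pred)) pred$tie else FALSE,
                            features = paste(sel, collapse = ","),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "task") <- task
  attr(out, "ties") <- sum(out$tie)
  attr(out, "n") <- n
  class(out) <- c("cl1ocv_result", "data.frame")
  out
}

#' Binomial standard error of a proportion, in percent
#'
#' The reporting convention for proportions is `100 p +/- 100
#' sqrt(p (1 - p) / n)`.
#'
#' @param p proportion in `[0, 1]`.
#' @param n sample size.
#' @param digits rounding of the returned SE (default 1 decimal).
#' @return the SE in percentage points.
#' @export
prop_se <- function(p, n, digits = 1L) {
  round(100 * sqrt(p * (1 - p) / n), digits)
}

clopper_pearson <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Performance metrics from per-patient predictions
#'
#' For binary tasks: accuracy, sensitivity (recall of the epilepsy
#' class), specificity, balanced accuracy (their mean), and the
#' diagnostic odds ratio from the 2x2 table (Haldane 0.5 correction when
#' a cell is empty, flagged).  Exact Clopper-Pearson 95% intervals
#' accompany each proportion.  For the trinary task balanced accuracy is
#' the mean of the three per-class recalls, and the lateralization
#' accuracy is the fraction of true-epilepsy patients predicted as
#' epilepsy whose side was called correctly.
#'
#' @param results a `cl1ocv_result`, or any data.frame with `truth` and
#'   `predicted` columns.
#' @param positive_class epilepsy label for binary tasks (default
#'   inferred as the non-NES class present).
#' @param conf confidence level for the intervals.
#' @return a `cad_metrics` list.
#' @export
compute_metrics <- function(results, positive_class = NULL, conf = 0.95) {
  truth <- as.character(results$truth)
  pred <- as.character(results$predicted)
  n <- length(truth)
  classes <- sort(unique(truth))
  acc_k <- sum(truth == pred)
  out <- list(n = n, accuracy = acc_k / n,
              accuracy_ci = clopper_pearson(acc_k, n, conf))
  trinary <- length(classes) > 2L
  if (!trinary) {
    if (is.null(positive_class))
      positive_class <- setdiff(classes, "NES")[1L]
    if (!positive_class %in% classes) stop("unknown positive class: ", positive_class)
    negative_class <- setdiff(classes, positive_class)
    P <- sum(truth == positive_class); N <- n - P
    tp <- sum(truth == positive_class & pred == positive_class)
    tn <- sum(truth != positive_class & pred != positive_class)
    fp <- N - tn; fn <- P - tp
    or_corrected <- any(c(tp, tn, fp, fn) == 0)
    h <- if (or_corrected) 0.5 else 0
    out$positive_class <- positive_class
    out$sensitivity <- tp / P
    out$sensitivity_ci <- clopper_pearson(tp, P, conf)
    out$specificity <- tn / N
    out$specificity_ci <- clopper_pearson(tn, N, conf)
    out$balanced_accuracy <- (out$sensitivity + out$specificity) / 2
    out$odds_ratio <- ((tp + h) * (tn + h)) / ((fp + h) * (fn + h))
    out$odds_ratio_corrected <- or_corrected
    out$table <- c(TP = tp, FN = fn, TN = tn, FP = fp)
  } else {
    recalls <- vapply(classes, function(cl) {
      mean(pred[truth == cl] == cl)
    }, numeric(1))
    out$per_class_recall <- recalls
    out$balanced_accuracy <- mean(recalls)
    epi <- truth %in% EPILEPSY_LEVELS
    detected <- epi & pred %in% EPILEPSY_LEVELS
    if (any(detected)) {
      k <- sum(truth[detected] == pred[detected])
      out$lateralization_accuracy <- k / sum(detected)
      out$lateralization_ci <- clopper_pearson(k, sum(detected), conf)
    } else {
      out$lateralization_accuracy <- NA_real_
    }
  }
  structure(out, class = "cad_metrics")
}

#' @export
print.cad_metrics <- function(x, ...) {
  fmt <- function(v, ci) sprintf("%.3f (%.3f-%.3f)", v, ci[1], ci[2])
  cat("n =", x$n, " accuracy", fmt(x$accuracy, x$accuracy_ci), "\n")
  if (!is.null(x$sensitivity))
    cat(" sensitivity", fmt(x$sensitivity, x$sensitivity_ci),
        " specificity", fmt(x$specificity, x$specificity_ci),
        sprintf(" balanced %.3f  OR %.2f%s", x$balanced_accuracy, x$odds_ratio,
                if (isTRUE(x$odds_ratio_corrected)) " (Haldane-corrected)" else ""),
        "\n")
  else
    cat(sprintf(" balanced %.3f  lateralization %.3f\n",
                x$balanced_accuracy, x$lateralization_accuracy))
  invisible(x)
}

#' Naive-classifier accuracy
#'
#' The naive classifier labels every case with the most common class;
#' its accuracy is the largest class share.  Ties resolve to the first
#' class in canonical (NES, LTLE, RTLE) order, reported via attribute
#' `class`.
#'
#' @param labels vector of class labels.
#' @return the accuracy, with the majority class as attribute `class`.
#' @export
naive_baseline <- function(labels) {
  if (!length(labels)) stop("empty labels")
  lv <- intersect(DIAGNOSIS_LEVELS, unique(as.character(labels)))
  if (!length(lv)) lv <- unique(as.character(labels))
  tab <- table(factor(as.character(labels), levels = lv))
  structure(max(tab) / length(labels), class_label = names(tab)[which.max(tab)])
}

#' Squared correlation between two analysis streams
#'
#' Square of the Pearson correlation between per-patient calls of two
#' streams (e.g. CAD vs manual iPET).  Binary calls are encoded 0/1; for
#' trinary calls each stream is one-hot encoded over the shared label set
#' and the r-squared values of the indicator pairs are averaged.  The
#' 95% interval is a seeded nonparametric bootstrap over patients.
#'
#' @param stream_a,stream_b equal-length call vectors over the same
#'   patients (numeric, or factor/character labels).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return list with `r2`, `lower`, `upper`, and `degenerate` (TRUE with
#'   a warning when a stream is constant; `r2` is then flagged 0).
#' @export
squared_correlation <- function(stream_a, stream_b, n_boot = 2000L,
                                seed = 1L, conf = 0.95) {
  if (length(stream_a) != length(stream_b)) stop("streams must cover the same patients")
  encode <- function(a, b) {
    if (is.numeric(a) && is.numeric(b)) return(list(cbind(a), cbind(b)))
    a <- as.character(a); b <- as.character(b)
    labs <- sort(unique(c(a, b)))
    if (length(labs) <= 2L) {
      return(list(cbind(as.numeric(a == labs[length(labs)])),
                  cbind(as.numeric(b == labs[length(labs)]))))
    }
    onehot <- function(v) vapply(labs, function(l) as.numeric(v == l),
                                 numeric(length(v)))
    list(onehot(a), onehot(b))
  }
  enc <- encode(stream_a, stream_b)
  r2_of <- function(idx) {
    vals <- vapply(seq_len(ncol(enc[[1]])), function(j) {
      x <- enc[[1]][idx, j]; y <- enc[[2]][idx, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
      stats::cor(x, y)^2
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }
  point <- r2_of(seq_along(stream_a))
  if (is.na(point)) {
    warning("constant stream: r-squared undefined, returning flagged 0")
    return(list(r2 = 0, lower = NA_real_, upper = NA_real_, degenerate = TRUE))
  }
  boots <- with_seed(seed, {
    n <- length(stream_a)
    vapply(seq_len(n_boot), function(b) r2_of(sample.int(n, n, replace = TRUE)),
           numeric(1))
  })
  a <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(r2 = point, lower = qs[1], upper = qs[2], degenerate = FALSE)
}
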