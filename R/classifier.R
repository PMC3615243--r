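#' Multilayer-perceptron hyperparameters
#'
#' Defaults follow the study protocol: learning rate 0.3, momentum 0.2,
#' 500 training epochs.  `hidden_layout = NULL` requests the bounded
#' topology search (single hidden layer sized from
#' `{ceil((d + c) / 2), d, 2d}` by inner 5-fold balanced accuracy within
#' the training data, ties to the smallest); an explicit integer vector
#' fixes the hidden layers; `integer(0)` means no hidden layer.
#'
#' @param learning_rate SGD step size in `(0, 1)`.
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param epochs training passes over the data (>= 1).
#' @param hidden_layout hidden layer sizes, or `NULL` for the search.
#' @param seed integer seed for weight initialization.
#' @param max_consecutive_errors divergence guard: a trained model whose
#'   longest run of consecutive training errors exceeds this is retrained
#'   from a derived seed.
#' @param max_restarts retry cap for the divergence guard.
#' @return an `mlp_hyper` list.
#' @export
mlp_hyper <- function(learning_rate = 0.3, momentum = 0.2, epochs = 500L,
                      hidden_layout = NULL, seed = 1L,
                      max_consecutive_errors = 20L, max_restarts = 5L) {
  stopifnot(learning_rate > 0, learning_rate < 1,
            momentum >= 0, momentum < 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), hidden_layout = hidden_layout,
                 seed = as.integer(seed),
                 max_consecutive_errors = as.integer(max_consecutive_errors),
                 max_restarts = as.integer(max_restarts)),
            class = "mlp_hyper")
}

#' Range-normalize features to \[-1, 1\]
#'
#' Maps each training column linearly onto `[-1, 1]` using the training
#' minimum and maximum; held-out rows are scaled with the *training*
#' ranges and clipped to `[-1, 1]`.  A constant training column maps to
#' 0 everywhere.
#'
#' @param train_matrix numeric training matrix.
#' @param test_rows optional matrix (or single row) of held-out data with
#'   the same columns.
#' @return list with `train`, `test` (or `NULL`) and the per-column
#'   `center`/`halfwidth` used.
#' @export
normalize_features <- function(train_matrix, test_rows = NULL) {
  lo <- apply(train_matrix, 2L, min)
  hi <- apply(train_matrix, 2L, max)
  center <- (hi + lo) / 2
  halfwidth <- (hi - lo) / 2
  scale1 <- function(m, clip) {
    out <- sweep(m, 2L, center, "-")
    w <- ifelse(halfwidth > 0, halfwidth, 1)
    out <- sweep(out, 2L, w, "/")
    out[, halfwidth == 0] <- 0
    if (clip) out <- pmin(pmax(out, -1), 1)
    out
  }
  test <- NULL
  if (!is.null(test_rows)) {
    if (is.null(dim(test_rows)))
      test_rows <- matrix(test_rows, nrow = 1,
                          dimnames = list(NULL, colnames(train_matrix)))
    test <- scale1(test_rows[, colnames(train_matrix), drop = FALSE], TRUE)
  }
  list(train = scale1(train_matrix, FALSE), test = test,
       center = center, halfwidth = halfwidth)
}

# Misclassification-cost weights per instance for a binary task:
# a false positive (an NES case called epilepsy) costs n_plus, so NES
# instances get weight n_plus; epilepsy instances get n_minus.  Weights
# are normalized to sum to the number of training instances.
cost_weights_binary <- function(labels, positive_class) {
  pos <- labels == positive_class
  n_plus <- sum(pos); n_minus <- sum(!pos)
  if (n_plus == 0 || n_minus == 0) stop("both classes must be present")
  w <- ifelse(pos, n_minus, n_plus)
  w * length(w) / sum(w)
}

# Trinary pairwise costs: misclassifying a class costs the sum of the
# sizes of the other two classes, sizes taken from the full three-class
# training tally.
cost_weights_pair <- function(labels, class_sizes) {
  total <- sum(class_sizes)
  cost <- vapply(levels(labels), function(cl) total - class_sizes[[cl]],
                 numeric(1))
  w <- cost[as.character(labels)]
  unname(w * length(w) / sum(w))
}

pick_hidden <- function(x, y01, w, hyper, nclass) {
  if (!is.null(hyper$hidden_layout)) return(as.integer(hyper$hidden_layout))
  d <- ncol(x)
  cands <- sort(unique(c(ceiling((d + nclass) / 2), d, 2L * d)))
  if (nrow(x) < 10L) return(cands[1L])
  folds <- rep_len(seq_len(5L), nrow(x))
  folds <- with_seed(derive_seed(hyper$seed, 777L), sample(folds))
  best <- cands[1L]; best_ba <- -Inf
  for (h in cands) {
    preds <- integer(nrow(x))
    for (f in 1:5) {
      tr <- folds != f
      if (length(unique(y01[tr])) < nclass) next
      fit <- cpp_mlp_train(x[tr, , drop = FALSE], y01[tr], w[tr], as.integer(h),
                           nclass, hyper$learning_rate, hyper$momentum,
                           hyper$epochs, derive_seed(hyper$seed, 1000L + h),
                           hyper$max_consecutive_errors, hyper$max_restarts)
      act <- cpp_mlp_forward(fit$weights, x[!tr, , drop = FALSE])
      preds[!tr] <- max.col(act, ties.method = "first") - 1L
    }
    recalls <- vapply(0:(nclass - 1L),
                      function(k) mean(preds[y01 == k] == k), numeric(1))
    ba <- mean(recalls)
    if (ba > best_ba + 1e-12) { best_ba <- ba; best <- h }
  }
  as.integer(best)
}

#' Train a cost-sensitive binary MLP
#'
#' Trains a sigmoid MLP by per-instance stochastic gradient descent with
#' momentum for exactly `hyper$epochs` passes, weighting each instance by
#' the cost of misclassifying it (control-class instances by the epilepsy
#' count and vice versa, normalized to sum to n) so that balanced
#' accuracy is optimized.  Features are range-normalized internally;
#' training is deterministic given `hyper$seed`.  Runs whose trained
#' model shows more than `hyper$max_consecutive_errors` consecutive
#' training errors are restarted from a derived seed.
#'
#' @param x numeric feature matrix (rows = patients) or `cad_features`.
#' @param labels two-level factor/character labels; ignored for
#'   `cad_features` input.
#' @param hyper an [mlp_hyper()].
#' @param positive_class the epilepsy class label (default: the non-NES
#'   level).
#' @param weights optional explicit instance weights overriding the cost
#'   weighting (`NULL` = cost weights; `"none"` = unweighted).
#' @return a `cad_model` object.
#' @export
train_binary <- function(x, labels = NULL, hyper = mlp_hyper(),
                         positive_class = NULL, weights = NULL) {
  if (inherits(x, "cad_features")) { labels <- x$labels; x <- x$x }
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2L) stop("train_binary needs exactly two classes, got ",
                                  nlevels(labels))
  if (is.null(positive_class))
    positive_class <- setdiff(levels(labels), "NES")[1L]
  w <- if (is.null(weights)) cost_weights_binary(labels, positive_class)
  else if (identical(weights, "none")) rep(1, length(labels))
  else weights * length(weights) / sum(weights)
  nrm <- normalize_features(x)
  y01 <- as.integer(labels) - 1L
  hidden <- pick_hidden(nrm$train, y01, w, hyper, 2L)
  fit <- cpp_mlp_train(nrm$train, y01, w, hidden, 2L, hyper$learning_rate,
                       hyper$momentum, hyper$epochs, hyper$seed,
                       hyper$max_consecutive_errors, hyper$max_restarts)
  if (!fit$converged)
    stop("training did not satisfy the divergence guard after ",
         fit$restarts, " restarts (seeds up to ", fit$seed_used, ")")
  structure(list(weights = fit$weights, classes = levels(labels),
                 positive_class = positive_class,
                 features = colnames(x), center = nrm$center,
                 halfwidth = nrm$halfwidth, hidden = hidden,
                 diagnostics = fit[c("restarts", "longest_error_run", "seed_used")]),
            class = "cad_model")
}

#' Predict from a trained binary MLP
#'
#' @param object a `cad_model`.
#' @param newdata matrix/row(s) containing the model's feature subset.
#' @param ... unused.
#' @return data.frame with `class` and `confidence` (winning activation
#'   normalized by the activation sum, in `[0, 1]`).
#' @export
predict.cad_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1, dimnames = list(NULL, object$features))
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) stop("missing feature: ", paste(miss, collapse = ", "))
  m <- newdata[, object$features, drop = FALSE]
  m <- sweep(m, 2L, object$center, "-")
  w <- ifelse(object$halfwidth > 0, object$halfwidth, 1)
  m <- sweep(m, 2L, w, "/")
  m[, object$halfwidth == 0] <- 0
  m <- pmin(pmax(m, -1), 1)
  act <- cpp_mlp_forward(object$weights, m)
  win <- max.col(act, ties.method = "first")
  data.frame(class = object$classes[win],
             confidence = act[cbind(seq_len(nrow(act)), win)] / rowSums(act),
             stringsAsFactors = FALSE)
}

#' Train the one-against-one trinary ensemble
#'
#' Decomposes LTLE vs RTLE vs NES into the three pairwise problems, each
#' trained only on its two classes with pairwise costs (each class costs
#' the sum of the sizes of the other two classes).  Prediction is by
#' majority vote; a three-way tie is broken by the highest summed
#' pairwise confidence, and tie events are counted.
#'
#' @param x feature matrix or `cad_features`.
#' @param labels three-level labels; ignored for `cad_features` input.
#' @param hyper an [mlp_hyper()]; pairwise model seeds are derived from
#'   `hyper$seed`.
#' @return a `cad_ensemble` object.
#' @export
train_trinary <- function(x, labels = NULL, hyper = mlp_hyper()) {
  if (inherits(x, "cad_features")) { labels <- x$labels; x <- x$x }
  labels <- factor(as.character(labels), levels = DIAGNOSIS_LEVELS)
  sizes <- table(labels)
  if (any(sizes == 0)) stop("all three classes must be present; missing: ",
                            paste(names(sizes)[sizes == 0], collapse = ", "))
  pairs <- utils::combn(DIAGNOSIS_LEVELS, 2L, simplify = FALSE)
  models <- lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    keep <- labels %in% pr
    lab <- droplevels(labels[keep])
    w <- cost_weights_pair(lab, sizes)
    hy <- hyper; hy$seed <- derive_seed(hyper$seed, k)
    train_binary(x[keep, , drop = FALSE], lab, hy,
                 positive_class = setdiff(pr, "NES")[1L], weights = w)
  })
  structure(list(models = models, pairs = pairs, classes = DIAGNOSIS_LEVELS,
                 features = colnames(x)),
            class = "cad_ensemble")
}

#' Predict from the trinary ensemble
#'
#' @param object a `cad_ensemble`.
#' @param newdata matrix/row(s) with the ensemble's features.
#' @param ... unused.
#' @return data.frame with `class`, `confidence` (summed pairwise
#'   confidence of the winner over the total) and logical `tie` flagging
#'   rows decided by the three-way tie-break.
#' @export
predict.cad_ensemble <- function(object, newdata, ...) {
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1, dimnames = list(NULL, object$features))
  per <- lapply(object$models, predict, newdata = newdata)
  n <- nrow(newdata)
  cls <- character(n); conf <- numeric(n); tie <- logical(n)
  for (i in seq_len(n)) {
    votes <- vapply(per, function(p) p$class[i], character(1))
    confs <- vapply(per, function(p) p$confidence[i], numeric(1))
    tallies <- table(factor(votes, levels = object$classes))
    csum <- tapply(confs, factor(votes, levels = object$classes), sum,
                   default = 0)
    if (max(tallies) == 1L) {  # 1-1-1 cycle
      tie[i] <- TRUE
      cls[i] <- names(which.max(csum))
    } else {
      cls[i] <- names(tallies)[which.max(tallies)]
    }
    conf[i] <- csum[[cls[i]]] / sum(confs)
  }
  data.frame(class = cls, confidence = conf, tie = tie,
             stringsAsFactors = FALSE)
}

#' Serialize a trained model to JSON
#' @param model a `cad_model` or `cad_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor", force = TRUE)
  invisible(path)
}
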