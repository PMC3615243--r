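#' Equal-width histogram quantization
#'
#' Discretizes a numeric vector into `Q` equal-width bins spanning the
#' observed `[min, max]` range.  The right-most edge is inclusive, so the
#' maximum maps to level `Q - 1`; values supplied later against stored
#' edges (held-out data) are clamped to the end bins.  A constant vector
#' maps entirely to level 0.
#'
#' @param values finite numeric vector.
#' @param Q number of quantal levels (>= 2).
#' @param edges optional previously computed bin edges (length `Q + 1`);
#'   when given, `values` are binned against them with clamping.
#' @return list with integer `levels` in `[0, Q - 1]` and numeric `edges`.
#' @export
quantize <- function(values, Q, edges = NULL) {
  if (length(values) == 0L) stop("empty vector")
  if (!all(is.finite(values))) stop("values must be finite")
  Q <- as.integer(Q)
  if (Q < 2L) stop("Q must be >= 2")
  if (is.null(edges)) return(cpp_quantize(values, Q))
  width <- edges[2L] - edges[1L]
  lev <- floor((values - edges[1L]) / width)
  lev <- pmin(pmax(lev, 0), Q - 1L)  # right-inclusive top bin + clamping
  list(levels = as.integer(lev), edges = edges)
}

#' Plug-in mutual information of two discrete vectors
#'
#' Computes the histogram plug-in estimate
#' `I = sum p(x, y) log2( p(x, y) / (p(x) p(y)) )` over observed cells,
#' in bits, with the `0 log 0 := 0` convention.
#'
#' @param x,y equal-length vectors of non-negative integer levels (or
#'   factors, which are converted).
#' @return mutual information in bits (non-negative).
#' @export
mutual_information <- function(x, y) {
  x <- discrete_levels(x); y <- discrete_levels(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  cpp_mi(x, y)
}

discrete_levels <- function(v) {
  if (is.factor(v)) return(as.integer(v) - 1L)
  if (!is.numeric(v)) v <- as.integer(factor(v)) - 1L
  as.integer(v)
}

#' mRMR feature-selection configuration
#'
#' @param F number of features to select (>= 1).
#' @param Q number of quantal levels used to histogram-quantize each
#'   feature before mutual-information estimation (>= 2).
#' @param variant `"MID"` (relevance minus mean redundancy, the default)
#'   or `"MIQ"` (relevance divided by mean redundancy).
#' @return an `mrmr_config` list.
#' @export
mrmr_config <- function(F, Q, variant = c("MID", "MIQ")) {
  variant <- match.arg(variant)
  F <- as.integer(F); Q <- as.integer(Q)
  stopifnot(F >= 1L, Q >= 2L)
  structure(list(F = F, Q = Q, variant = variant), class = "mrmr_config")
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Quantizes every feature column with `config$Q` equal-width bins (the
#' class labels stay categorical), then greedily selects `config$F`
#' features: the first maximizes relevance `I(f; c)`; each later pick
#' maximizes `I(f; c) - mean_{s in S} I(f; s)` (MID) over the unselected
#' candidates, where `S` is the already-selected set.  Deterministic;
#' ties resolve to the earlier column.
#'
#' @param x numeric feature matrix with column names, or a
#'   `cad_features` object (its labels are then used).
#' @param labels class labels (factor/character); ignored when `x` is a
#'   `cad_features` object.
#' @param config an [mrmr_config()].
#' @return a `ranked_features` data.frame with columns `rank`, `feature`,
#'   `relevance_bits`, `mrmr_score_bits`, and attribute `edges` (list of
#'   bin edges per selected feature).
#' @export
mrmr_rank <- function(x, labels = NULL, config) {
  if (inherits(x, "cad_features")) { labels <- x$labels; x <- x$x }
  stopifnot(inherits(config, "mrmr_config"))
  if (is.null(colnames(x))) stop("feature matrix must have column names")
  if (config$F > ncol(x))
    stop("F = ", config$F, " exceeds the ", ncol(x), " candidate features")
  y <- discrete_levels(if (is.factor(labels)) droplevels(labels) else factor(labels))
  qz <- lapply(seq_len(ncol(x)), function(j) quantize(x[, j], config$Q))
  Xq <- vapply(qz, `[[`, integer(nrow(x)), "levels")
  if (is.null(dim(Xq))) Xq <- matrix(Xq, nrow = nrow(x))
  res <- cpp_mrmr(Xq, y, config$F, config$variant == "MIQ")
  out <- data.frame(rank = seq_len(config$F),
                    feature = colnames(x)[res$order],
                    relevance_bits = res$relevance,
                    mrmr_score_bits = res$score,
                    stringsAsFactors = FALSE)
  attr(out, "edges") <- stats::setNames(lapply(res$order, function(j) qz[[j]]$edges),
                                        colnames(x)[res$order])
  attr(out, "config") <- config
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Write a ranked feature list as TSV
#' @param ranked a `ranked_features` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranked_features <- function(ranked, path) {
  utils::write.table(as.data.frame(ranked), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
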