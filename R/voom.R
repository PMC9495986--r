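# Count support: counts are transformed to log2 counts-per-million and
# given per-observation precision weights from a mean-variance trend, after
# which they flow through the ordinary moderated-t arm.

#' Validate a count matrix
#'
#' Non-negative integers with unique ids and strictly positive library
#' sizes (column sums).
#'
#' @param counts matrix of counts.
#' @return `counts`, invisibly.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts need unique entry ids as rownames", call. = FALSE)
  }
  if (any(colSums(counts) == 0)) {
    bad <- colnames(counts)[colSums(counts) == 0]
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(counts)
}

#' Log2 counts per million
#'
#' value = log2( (count + 0.5) / (library_size + 1) * 1e6 ). The half-count
#' offset keeps zeros finite; the library offset keeps the transform
#' bounded.
#'
#' @param counts count matrix (entries x samples).
#' @return expression matrix of log2-cpm values.
#' @export
log_cpm <- function(counts) {
  validate_count_matrix(counts)
  lib <- colSums(counts)
  log2(sweep(counts + 0.5, 2, lib + 1, "/") * 1e6)
}

# linear interpolation with linear extrapolation beyond the fitted range,
# using the slope of the first/last trend segment
interp_extrap <- function(x, y, xout) {
  n <- length(x)
  out <- stats::approx(x, y, xout = xout, rule = 2, ties = mean)$y
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    slope <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + slope * (xout[lo] - x[1])
  }
  if (any(hi)) {
    slope <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + slope * (xout[hi] - x[n])
  }
  out
}

#' Precision weights from the count mean-variance trend
#'
#' Per-gene linear models are fitted to the log2-cpm values; the square
#' root of each gene's residual standard deviation is regressed on its mean
#' log2 count with a locally weighted (lowess) trend, span 0.5, 3
#' robustness iterations. The trend is evaluated at every cell's fitted
#' log2 count (linear extrapolation past the ends) and the weight is the
#' predicted value to the power -4 (i.e. an inverse predicted variance).
#'
#' @param counts count matrix (>= 50 genes).
#' @param mm model matrix for the design.
#' @return genes x samples matrix of positive finite weights, with the
#'   fitted trend (`x` = mean log2 count, `y` = sqrt residual s.d.)
#'   attached as attribute `"trend"`.
#' @export
voom_weights <- function(counts, mm) {
  validate_count_matrix(counts)
  if (nrow(counts) < 50) {
    stop("mean-variance trend needs at least 50 genes", call. = FALSE)
  }
  y <- log_cpm(counts)
  lib <- colSums(counts)
  df <- ncol(y) - ncol(mm)
  if (df <= 0) stop("no residual degrees of freedom", call. = FALSE)
  fit <- stats::lm.fit(mm, t(y))
  sigma <- sqrt(colSums(fit$residuals^2) / df)
  if (all(sigma == 0)) {
    stop("degenerate mean-variance trend: all residual s.d. are zero",
         call. = FALSE)
  }
  # mean log2 count: shift log2-cpm back to the count scale
  offset <- mean(log2(lib + 1)) - log2(1e6)
  sx <- rowMeans(y) + offset
  sy <- sqrt(sigma)
  trend <- stats::lowess(sx, sy, f = 0.5, iter = 3)
  fitted_count <- t(fit$fitted.values) +
    matrix(log2(lib + 1), nrow(y), ncol(y), byrow = TRUE) - log2(1e6)
  pred <- interp_extrap(trend$x, trend$y, as.vector(fitted_count))
  pred <- pmax(pred, 1e-6)  # guard against a trend crossing zero
  w <- matrix(pred^-4, nrow(y), ncol(y), dimnames = dimnames(y))
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("non-finite precision weights", call. = FALSE)
  }
  attr(w, "trend") <- trend
  w
}

#' Read a count matrix from CSV
#'
#' Same layout as the expression CSV (ids first, samples across), but the
#' values must be non-negative integers.
#'
#' @param path CSV path.
#' @return validated count matrix.
#' @export
read_count_matrix <- function(path) {
  m <- read_expression_matrix(path)
  validate_count_matrix(m)
  m
}
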