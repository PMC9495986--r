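# Quality-control statistics. Everything here is pure: the input matrix is
# never modified and repeated calls give identical results. Figures are
# rendered separately (see cli.R) from these data.

#' MA statistics against the leave-one-out median profile
#'
#' For each entry, the reference is the median of the entry's values over
#' all other samples; M = sample - reference (log ratio) and
#' A = (sample + reference) / 2 (average log intensity).
#'
#' @param m expression matrix with >= 3 samples.
#' @param sample sample name or column index.
#' @return data.frame with `entry_id`, `A`, `M`.
#' @export
ma_statistics <- function(m, sample) {
  if (ncol(m) < 3) {
    stop("MA statistics need at least 3 samples", call. = FALSE)
  }
  j <- if (is.character(sample)) match(sample, colnames(m)) else sample
  if (is.na(j) || j < 1 || j > ncol(m)) {
    stop("unknown sample: ", sample, call. = FALSE)
  }
  ref <- apply(m[, -j, drop = FALSE], 1, stats::median)
  data.frame(entry_id = rownames(m), A = (m[, j] + ref) / 2, M = m[, j] - ref,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Order samples by MA non-linearity
#'
#' Per sample, a lowess curve (span 0.3) of M on A is fitted; the score is
#' the root-mean-square deviation of the curve from its own least-squares
#' straight line. Samples are ordered by descending score (least linear
#' first), ties broken by sample name, so the worst-behaved arrays surface
#' first.
#'
#' @param m expression matrix with >= 3 samples.
#' @return data.frame with `sample` and `score`, in plot order.
#' @export
order_by_loess_linearity <- function(m) {
  scores <- vapply(colnames(m), function(s) {
    ma <- ma_statistics(m, s)
    lw <- stats::lowess(ma$A, ma$M, f = 0.3)
    line <- stats::lm.fit(cbind(1, lw$x), lw$y)$fitted.values
    sqrt(mean((lw$y - line)^2))
  }, numeric(1))
  ord <- order(-scores, colnames(m))
  data.frame(sample = colnames(m)[ord], score = unname(scores[ord]),
             stringsAsFactors = FALSE)
}

#' Principal-component coordinates of the samples
#'
#' Samples are the observations; each entry (gene) is centered, and the
#' coordinates come from the singular value decomposition. The sign of each
#' component is fixed by making its largest-magnitude gene loading
#' positive. Explained-variance fractions are reported for all components
#' and sum to 1.
#'
#' @param m expression matrix.
#' @param n_components number of components to return.
#' @return list with `coords` (samples x n_components) and `explained`
#'   (fractions for every component).
#' @export
pca_coords <- function(m, n_components = 2) {
  x <- t(m)
  n <- nrow(x)
  if (n_components > min(n - 1, ncol(x))) {
    stop("n_components must be <= min(samples - 1, entries)", call. = FALSE)
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  for (k in seq_along(sv$d)) {
    i <- which.max(abs(sv$v[, k]))
    if (sv$v[i, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  coords <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  rownames(coords) <- colnames(m)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  list(coords = coords, explained = sv$d^2 / sum(sv$d^2))
}

#' Hierarchical clustering of samples
#'
#' Euclidean distance on the expression profiles, complete linkage. Returns
#' the standard nested-merge structure (an `hclust` object) whose merge
#' heights are monotone non-decreasing.
#'
#' @param m expression matrix with >= 2 samples.
#' @return `hclust` object over the samples.
#' @export
hierarchical_tree <- function(m) {
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  stats::hclust(stats::dist(t(m), method = "euclidean"), method = "complete")
}

#' Per-sample distribution summaries
#'
#' Five-number summary (min, q1, median, q3, max; linear-interpolation
#' quantiles) per sample plus Gaussian kernel densities evaluated on a
#' shared 512-point grid (global range extended by three bandwidths so the
#' kernels' mass is captured), Silverman bandwidth per sample.
#'
#' @param m expression matrix.
#' @return list with `summary` (data.frame) and `density` (list: `grid`,
#'   `height` samples x 512 matrix).
#' @export
distribution_summary <- function(m) {
  qs <- t(apply(m, 2, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1),
                names = FALSE))
  summary <- data.frame(sample = colnames(m), min = qs[, 1], q1 = qs[, 2],
                        median = qs[, 3], q3 = qs[, 4], max = qs[, 5],
                        row.names = NULL, stringsAsFactors = FALSE)
  bws <- apply(m, 2, function(x) max(stats::bw.nrd0(x), 1e-6))
  pad <- 3 * max(bws)
  grid <- seq(min(m) - pad, max(m) + pad, length.out = 512)
  height <- t(vapply(seq_len(ncol(m)), function(j) {
    vapply(grid, function(g) mean(stats::dnorm(g - m[, j], sd = bws[j])),
           numeric(1))
  }, numeric(512)))
  rownames(height) <- colnames(m)
  list(summary = summary, density = list(grid = grid, height = height))
}

write_distribution_summary <- function(ds, path) {
  write_table_csv(ds$summary, path)
}

#' Per-group mean-variance points
#'
#' Sample mean and unbiased variance per entry within each experimental
#' group; every group must have at least two samples.
#'
#' @param m expression matrix.
#' @param groups group label per sample.
#' @return named list of data.frames (`entry_id`, `mean`, `variance`).
#' @export
mean_variance_points <- function(m, groups) {
  stopifnot(length(groups) == ncol(m))
  out <- list()
  for (g in unique(groups)) {
    cols <- groups == g
    if (sum(cols) < 2) {
      stop("group '", g, "' has fewer than 2 samples", call. = FALSE)
    }
    sub <- m[, cols, drop = FALSE]
    out[[g]] <- data.frame(entry_id = rownames(m), mean = rowMeans(sub),
                           variance = apply(sub, 1, stats::var),
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Venn overlap counts of two id sets
#'
#' @param set_a,set_b character vectors (duplicates ignored).
#' @return named integer vector `(only_a, shared, only_b)`.
#' @export
overlap_counts <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  c(only_a = length(setdiff(a, b)), shared = length(intersect(a, b)),
    only_b = length(setdiff(b, a)))
}
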