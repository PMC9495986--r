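# Conservative low-expression filtering, applied before the statistics to
# increase power. The fold-change threshold theta_F is deliberately NOT a
# row filter: genes failing it stay in the computation and are only marked
# non-differentially-expressed at the end.

#' Filter entries by group-wise expression presence
#'
#' An entry is retained iff there is at least one experimental group in
#' which the fraction of samples with expression strictly above `theta_E`
#' is at least `kappa`. The fraction comparison is exact (integer counts
#' against `kappa * group size`), with no floating rounding.
#'
#' @param m expression matrix.
#' @param groups group label per sample (length = sample count).
#' @param kappa minimum group-wise presence fraction in `[0, 1]`.
#' @param theta_E log2 expression threshold (strict `>`).
#' @return list with `retained` (filtered matrix) and `dropped`
#'   (character vector of dropped entry ids).
#' @export
filter_by_expression <- function(m, groups, kappa, theta_E) {
  if (length(groups) != ncol(m)) {
    stop("group labels (", length(groups), ") != sample count (", ncol(m), ")",
         call. = FALSE)
  }
  if (!is.numeric(kappa) || length(kappa) != 1 || is.na(kappa) ||
      kappa < 0 || kappa > 1) {
    stop("kappa must lie in [0, 1]", call. = FALSE)
  }
  above <- m > theta_E
  keep <- rep(FALSE, nrow(m))
  for (g in unique(groups)) {
    cols <- groups == g
    # exact rational comparison: count >= kappa * n  <=>  count/n >= kappa
    keep <- keep | (rowSums(above[, cols, drop = FALSE]) >= kappa * sum(cols))
  }
  list(retained = m[keep, , drop = FALSE],
       dropped = rownames(m)[!keep])
}

#' Default expression threshold
#'
#' When no negative-control estimate is available, theta_E defaults to the
#' 20th percentile (linear interpolation) of all expression values.
#'
#' @param m expression matrix.
#' @return scalar log2 threshold.
#' @export
default_expression_threshold <- function(m) {
  stats::quantile(as.vector(m), 0.20, names = FALSE)
}
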