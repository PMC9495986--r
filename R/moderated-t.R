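# The parametric arm: per-gene linear models, empirical-Bayes variance
# moderation and a moderated t-test. The gene variance s2_g is shrunk toward
# a prior value s0^2 with prior weight d0 (prior degrees of freedom),
# estimated from the whole collection of genes by moment matching on
# log s2_g through the digamma/trigamma functions.

#' Fit per-gene linear models
#'
#' Ordinary (or, given per-cell weights, weighted) least squares of every
#' gene's expression on the model matrix. Residual variance is the
#' (weighted) residual sum of squares over the residual degrees of freedom
#' d = n - rank(X), identical for all genes.
#'
#' @param m expression matrix (genes x samples).
#' @param mm model matrix from [build_design_matrix()] (samples x
#'   coefficients, full rank).
#' @param weights optional genes x samples matrix of positive observation
#'   weights (e.g. voom precision weights).
#' @return object of class `gene_fit`: `coefficients` (genes x p),
#'   `sigma2`, `df`, `cov_unscaled` (p x p, or p x p x genes when
#'   weighted).
#' @export
fit_linear_models <- function(m, mm, weights = NULL) {
  n <- ncol(m)
  p <- ncol(mm)
  df <- n - p
  if (df <= 0) {
    stop("no residual degrees of freedom: ", p, " coefficients for ", n,
         " samples", call. = FALSE)
  }
  G <- nrow(m)
  if (is.null(weights)) {
    fit <- stats::lm.fit(mm, t(m))
    coefs <- t(fit$coefficients)
    res <- t(fit$residuals)
    sigma2 <- rowSums(res^2) / df
    cov_unscaled <- chol2inv(chol(crossprod(mm)))
    dimnames(cov_unscaled) <- list(colnames(mm), colnames(mm))
  } else {
    if (!identical(dim(weights), dim(m)) || any(weights <= 0) ||
        any(!is.finite(weights))) {
      stop("weights must be a positive genes x samples matrix", call. = FALSE)
    }
    coefs <- matrix(NA_real_, G, p, dimnames = list(rownames(m), colnames(mm)))
    sigma2 <- numeric(G)
    cov_unscaled <- array(NA_real_, c(p, p, G))
    for (g in seq_len(G)) {
      w <- weights[g, ]
      xw <- mm * w
      xtwx <- crossprod(mm, xw)
      ci <- chol2inv(chol(xtwx))
      beta <- ci %*% crossprod(xw, m[g, ])
      r <- m[g, ] - as.vector(mm %*% beta)
      coefs[g, ] <- beta
      sigma2[g] <- sum(w * r^2) / df
      cov_unscaled[, , g] <- ci
    }
  }
  rownames(coefs) <- rownames(m)
  structure(list(coefficients = coefs, sigma2 = unname(sigma2), df = df,
                 cov_unscaled = cov_unscaled, weighted = !is.null(weights)),
            class = "gene_fit")
}

# monotone inversion of the trigamma function by bisection on d0
invert_trigamma <- function(target, lower = 1e-6, upper = 1e8) {
  if (target <= trigamma(upper / 2)) return(Inf)
  if (target >= trigamma(lower / 2)) return(lower)
  for (i in 1:200) {
    mid <- (lower + upper) / 2
    if (trigamma(mid / 2) > target) lower <- mid else upper <- mid
    if ((upper - lower) < 1e-10 * upper) break
  }
  (lower + upper) / 2
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Closed-form moment estimator on the log variances: with
#' e_g = log s2_g - digamma(d_g/2) + log(d_g/2), solve
#' trigamma(d0/2) = max( var(e) - mean(trigamma(d_g/2)), 0 )
#' for d0 by monotone inversion; a non-positive right-hand side means no
#' excess dispersion and d0 = Inf. Then
#' s0^2 = exp( mean(e) + digamma(d0/2) - log(d0/2) ) (d0 = Inf:
#' s0^2 = exp(mean(e))). Genes with zero variance are excluded (log of zero
#' undefined); they still take part in testing through the moderated
#' variance.
#'
#' @param s_sq per-gene residual variances.
#' @param d per-gene residual degrees of freedom (scalar or vector).
#' @return list with `d0` (> 0, possibly `Inf`) and `s0_sq` (> 0).
#' @export
estimate_eb_hyperparams <- function(s_sq, d) {
  d <- rep_len(as.numeric(d), length(s_sq))
  use <- is.finite(s_sq) & s_sq > 0 & d > 0
  s_sq <- s_sq[use]
  d <- d[use]
  G <- length(s_sq)
  if (G < 10) {
    stop("need at least 10 genes with positive variance to estimate ",
         "hyperparameters (got ", G, ")", call. = FALSE)
  }
  e <- log(s_sq) - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  target <- mean((e - ebar)^2) * G / (G - 1) - mean(trigamma(d / 2))
  if (target <= 0) {
    return(list(d0 = Inf, s0_sq = exp(ebar)))
  }
  d0 <- invert_trigamma(target)
  if (!is.finite(d0)) {
    return(list(d0 = Inf, s0_sq = exp(ebar)))
  }
  list(d0 = d0, s0_sq = exp(ebar + digamma(d0 / 2) - log(d0 / 2)))
}

#' Moderated t-test for one contrast
#'
#' Posterior (moderated) variance s~2_g = (d0 s0^2 + d s2_g) / (d0 + d);
#' t~_g = c'beta_g / sqrt(s~2_g v_g) with v_g = c' (X'WX)^-1 c; two-sided
#' p-value from Student's t with d0 + d degrees of freedom (d0 = Inf gives
#' the normal reference; d0 = 0 recovers the ordinary t-test exactly).
#'
#' @param fit a [fit_linear_models()] result.
#' @param hyper list with `d0` and `s0_sq` (see
#'   [estimate_eb_hyperparams()]); use `d0 = 0` for the unmoderated test.
#' @param contrast numeric contrast vector over the model-matrix columns.
#' @return data.frame with `log2_fc`, `stat` and `p_value`, one row per
#'   gene, in input gene order.
#' @export
moderated_t_test <- function(fit, hyper, contrast) {
  stopifnot(inherits(fit, "gene_fit"))
  d0 <- hyper$d0
  s0 <- hyper$s0_sq
  G <- nrow(fit$coefficients)
  lfc <- as.vector(fit$coefficients %*% contrast)
  if (fit$weighted) {
    v <- vapply(seq_len(G), function(g) {
      as.numeric(contrast %*% fit$cov_unscaled[, , g] %*% contrast)
    }, numeric(1))
  } else {
    v <- rep(as.numeric(contrast %*% fit$cov_unscaled %*% contrast), G)
  }
  if (any(v <= 0)) stop("non-positive contrast variance", call. = FALSE)
  if (is.infinite(d0)) {
    s2_post <- rep(s0, G)
    tstat <- lfc / sqrt(s2_post * v)
    p <- 2 * stats::pnorm(-abs(tstat))
  } else {
    s2_post <- (d0 * s0 + fit$df * fit$sigma2) / (d0 + fit$df)
    tstat <- lfc / sqrt(s2_post * v)
    p <- 2 * stats::pt(-abs(tstat), df = d0 + fit$df)
  }
  data.frame(log2_fc = lfc, stat = tstat, p_value = p,
             row.names = rownames(fit$coefficients))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q for the i-th smallest p-value is `min over j >= i of p_(j) * m / j`,
#' clipped to 1 and mapped back to the input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Three-state DEG marking
#'
#' marking = sign(log2FC) iff q < alpha (strict) AND |log2FC| > theta_F
#' (strict); otherwise 0. Works identically with BH q-values (moderated-t
#' arm) and permutation PFP values (rank-product arm).
#'
#' @param q q-values or PFP values.
#' @param log2_fc log2 fold changes.
#' @param theta_F fold-change threshold (>= 0).
#' @param alpha significance level.
#' @return integer vector in `{-1, 0, 1}`.
#' @export
mark_degs <- function(q, log2_fc, theta_F, alpha) {
  if (theta_F < 0) stop("theta_F must be >= 0", call. = FALSE)
  stopifnot(length(q) == length(log2_fc))
  marking <- integer(length(q))
  hit <- q < alpha & abs(log2_fc) > theta_F
  marking[hit] <- as.integer(sign(log2_fc[hit]))
  marking
}

#' Assemble a DEG table
#'
#' One row per retained entry, in input order, with the fixed column set
#' `entry_id, avg_expr, log2_fc, stat, p_value, q_value, marking`.
#'
#' @param entry_ids entry identifiers.
#' @param avg_expr average log2 expression (grand mean over all samples).
#' @param log2_fc log2 fold changes.
#' @param stat test statistics.
#' @param p_value p-values.
#' @param q_value BH q-values or PFP values.
#' @param marking integer markings in `{-1, 0, 1}`.
#' @return data.frame (the DEG table).
#' @export
build_deg_table <- function(entry_ids, avg_expr, log2_fc, stat, p_value,
                            q_value, marking) {
  n <- length(entry_ids)
  args <- list(avg_expr = avg_expr, log2_fc = log2_fc, stat = stat,
               p_value = p_value, q_value = q_value, marking = marking)
  for (nm in names(args)) {
    if (length(args[[nm]]) != n) {
      stop("length mismatch: '", nm, "' has ", length(args[[nm]]),
           " values for ", n, " entries", call. = FALSE)
    }
  }
  if (!all(marking %in% c(-1L, 0L, 1L))) {
    stop("markings must be -1, 0 or 1", call. = FALSE)
  }
  data.frame(entry_id = as.character(entry_ids), avg_expr = avg_expr,
             log2_fc = log2_fc, stat = stat, p_value = p_value,
             q_value = q_value, marking = as.integer(marking),
             stringsAsFactors = FALSE)
}
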