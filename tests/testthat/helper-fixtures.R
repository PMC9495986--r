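# Shared test helpers: all fixtures are built in code at test time.

rand_matrix <- function(genes, samples, seed, mean = 7, sd = 1) {
  set.seed(seed)
  matrix(rnorm(genes * samples, mean, sd), genes, samples,
         dimnames = list(sprintf("g%03d", seq_len(genes)),
                         sprintf("s%02d", seq_len(samples))))
}

two_group_design <- function(n_per_group,
                             contrast = list(c("treated", "control")),
                             ...) {
  design_spec(rep(c("control", "treated"), each = n_per_group), contrast, ...)
}

file_bytes <- function(path) readBin(path, "raw", file.info(path)$size)

# independent numerical-integration oracle for the normexp posterior mean
# E[S | X = x] under X = S + B, S ~ Exp(alpha), B ~ N(mu, sigma^2)
normexp_oracle <- function(x, mu, sigma, alpha) {
  # integrate over the finite window that carries the posterior mass (the
  # Gaussian factor is centered at x - mu with s.d. sigma); an infinite
  # upper limit makes adaptive quadrature miss the narrow peak
  lo <- max(0, x - mu - 12 * sigma)
  hi <- max(0, x - mu) + 12 * sigma
  num <- stats::integrate(function(s) s * exp(-s / alpha) *
                            stats::dnorm(x - s, mu, sigma),
                          lo, hi, rel.tol = 1e-12)$value
  den <- stats::integrate(function(s) exp(-s / alpha) *
                            stats::dnorm(x - s, mu, sigma),
                          lo, hi, rel.tol = 1e-12)$value
  num / den
}

# classical pooled-variance two-sample t-test p-values, computed directly
classical_t_p <- function(m, groups, test, ref) {
  apply(m, 1, function(y) {
    a <- y[groups == test]
    b <- y[groups == ref]
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2)
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    2 * stats::pt(-abs(tt), df = length(a) + length(b) - 2)
  })
}

# run the moderated-t arm end to end on a matrix, returning p, q, lfc, marks
run_modt_arm <- function(m, groups, contrast = c("treated", "control"),
                         batch_labels = NULL, d0 = NULL, theta_f = 0.5,
                         alpha = 0.05) {
  ds <- design_spec(groups, list(contrast), batch_labels = batch_labels)
  mm <- build_design_matrix(ds, colnames(m))
  fit <- fit_linear_models(m, mm)
  hp <- if (is.null(d0)) {
    estimate_eb_hyperparams(fit$sigma2, fit$df)
  } else {
    list(d0 = d0, s0_sq = 1)
  }
  tt <- moderated_t_test(fit, hp, contrast_vector(contrast, mm))
  q <- bh_adjust(tt$p_value)
  list(p = tt$p_value, q = q, lfc = tt$log2_fc, hp = hp,
       marking = mark_degs(q, tt$log2_fc, theta_f, alpha))
}
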