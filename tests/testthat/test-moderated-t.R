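test_that("least-squares fits match hand arithmetic and a normal-equations oracle", {
  m <- matrix(c(1, 1, 3, 3), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  mm <- build_design_matrix(design_spec(c("A", "A", "B", "B"),
                                        list(c("B", "A"))), colnames(m))
  fit <- fit_linear_models(m, mm)
  expect_equal(unname(fit$coefficients[1, ]), c(1, 3))
  expect_equal(fit$sigma2, 0)
  expect_equal(fit$df, 2L)

  # constant weights leave coefficients unchanged
  w <- matrix(3.7, 1, 4)
  fitw <- fit_linear_models(m, mm, weights = w)
  expect_equal(fitw$coefficients, fit$coefficients)

  # 50 random genes vs brute-force normal equations
  d <- generate_expression_dataset(genes = 50, n_per_group = 4,
                                   batch_shift = 0.5, seed = 112)
  ds <- design_spec(d$groups, list(c("treated", "control")),
                    batch_labels = d$truth$batch_labels)
  mm2 <- build_design_matrix(ds, colnames(d$matrix))
  fit2 <- fit_linear_models(d$matrix, mm2)
  x <- unclass(mm2)
  for (g in seq_len(50)) {
    beta <- solve(t(x) %*% x, t(x) %*% d$matrix[g, ])
    expect_lt(max(abs(fit2$coefficients[g, ] - as.vector(beta))), 1e-10)
  }

  expect_error(fit_linear_models(d$matrix[, 1:3], mm2[1:3, ]), "degrees")
})

test_that("hyperparameter estimation handles degenerate and permuted input", {
  expect_equal(estimate_eb_hyperparams(rep(0.05, 100), 4)$d0, Inf)

  set.seed(113)
  s2 <- 0.05 * 4 / rchisq(500, 4) * rchisq(500, 4) / 4
  hp <- estimate_eb_hyperparams(s2, 4)
  perm <- sample(500)
  expect_equal(estimate_eb_hyperparams(s2[perm], 4), hp)

  expect_error(estimate_eb_hyperparams(rep(0, 50), 4), "10 genes")
})

test_that("moderated t limits: d0 = 0 is the classical t, d0 = Inf pins the variance", {
  d <- generate_expression_dataset(genes = 200, n_per_group = 5,
                                   de_fraction = 0.1, seed = 114)
  mm <- build_design_matrix(two_group_design(5), colnames(d$matrix))
  fit <- fit_linear_models(d$matrix, mm)
  cv <- contrast_vector(c("treated", "control"), mm)

  t0 <- moderated_t_test(fit, list(d0 = 0, s0_sq = 1), cv)
  classical <- classical_t_p(d$matrix, d$groups, "treated", "control")
  expect_lt(max(abs(t0$p_value - classical)), 1e-10)

  tinf <- moderated_t_test(fit, list(d0 = Inf, s0_sq = 0.05), cv)
  v <- as.numeric(cv %*% fit$cov_unscaled %*% cv)
  expect_equal(tinf$stat, tinf$log2_fc / sqrt(0.05 * v))
})

test_that("the moderated-t arm reproduces the established EB implementation", {
  skip_if_not_installed("limma")
  d <- generate_expression_dataset(genes = 300, n_per_group = 4,
                                   de_fraction = 0.1, seed = 115)
  mm <- build_design_matrix(two_group_design(4), colnames(d$matrix))
  fit <- fit_linear_models(d$matrix, mm)
  hp <- estimate_eb_hyperparams(fit$sigma2, fit$df)
  cv <- contrast_vector(c("treated", "control"), mm)
  tt <- moderated_t_test(fit, hp, cv)

  lf <- limma::lmFit(d$matrix, unclass(mm))
  sq <- limma::squeezeVar(lf$sigma^2, lf$df.residual)
  eb <- limma::eBayes(limma::contrasts.fit(lf, cv))
  expect_equal(hp$d0, sq$df.prior, tolerance = 1e-8)
  expect_equal(hp$s0_sq, sq$var.prior, tolerance = 1e-8)
  expect_lt(max(abs(tt$p_value - as.vector(eb$p.value))), 1e-10)
})

test_that("BH adjustment matches hand computations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(c(0.1, 0.005)), c(0.1, 0.01))  # order preserved
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG marking applies strict double thresholds", {
  expect_equal(mark_degs(0.049, 0.6, 0.5, 0.05), 1L)
  expect_equal(mark_degs(0.05, 2.0, 0.5, 0.05), 0L)   # strict on q
  expect_equal(mark_degs(0.001, 0.5, 0.5, 0.05), 0L)  # strict on |lfc|
  expect_equal(mark_degs(0.001, -0.9, 0.5, 0.05), -1L)
  expect_equal(mark_degs(c(0.01, 0.2), c(1, 1), 0.5, 0.05), c(1L, 0L))
})

test_that("DEG tables keep input order and reject misaligned inputs", {
  ids <- sprintf("g%03d", 1:100)
  tab <- build_deg_table(ids, rnorm(100), rnorm(100), rnorm(100),
                         runif(100), runif(100),
                         sample(c(-1L, 0L, 1L), 100, TRUE))
  expect_equal(nrow(tab), 100L)
  expect_identical(tab$entry_id, ids)
  expect_true(all(tab$marking %in% c(-1L, 0L, 1L)))
  expect_error(build_deg_table(ids, rnorm(99), rnorm(100), rnorm(100),
                               runif(100), runif(100), integer(100)),
               "length mismatch")
})

test_that("modeling the batch restores the t-test's calibration", {
  d <- generate_expression_dataset(genes = 3000, n_per_group = 10,
                                   de_fraction = 0, batch_shift = 1,
                                   seed = 116)
  ignore <- run_modt_arm(d$matrix, d$groups, d0 = 0)
  model <- run_modt_arm(d$matrix, d$groups, d0 = 0,
                        batch_labels = d$truth$batch_labels)
  # without the batch column the inflated residual variance wrecks
  # calibration (far too conservative); with it, nominal level is back
  expect_lt(mean(ignore$p < 0.05), 0.03)
  expect_gt(mean(model$p < 0.05), 0.03)
  expect_lt(mean(model$p < 0.05), 0.07)
})
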