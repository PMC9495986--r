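write_raw_fixture <- function(dir, n_samples = 3, features = NULL) {
  dir.create(dir, showWarnings = FALSE)
  if (is.null(features)) {
    features <- data.frame(
      feature_id = c("f1", "f2", "f3", "neg1"),
      control_class = c("none", "none", "none", "negative"),
      replicate_key = c("k1", "k1", "k2", "neg1"),
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(n_samples)) {
    features$intensity <- 100 + 10 * seq_len(nrow(features)) + i
    utils::write.csv(features[, c("feature_id", "intensity", "control_class",
                                  "replicate_key")],
                     file.path(dir, sprintf("arr%02d.csv", i)),
                     row.names = FALSE)
  }
  invisible(dir)
}

test_that("raw batch loading merges files and enforces a shared feature universe", {
  dir <- withr::local_tempdir()
  write_raw_fixture(dir, 3)
  batch <- load_raw_batch(dir, "\\.csv$")
  expect_equal(ncol(batch$intensity), 3L)
  expect_equal(nrow(batch$intensity), 4L)

  expect_error(load_raw_batch(dir, "arr01"), "at least 2")

  # a file with a divergent feature set names the offender
  bad <- utils::read.csv(file.path(dir, "arr01.csv"),
                         stringsAsFactors = FALSE)
  bad$feature_id[1] <- "rogue_feature"
  utils::write.csv(bad, file.path(dir, "arr04.csv"), row.names = FALSE)
  expect_error(load_raw_batch(dir, "\\.csv$"), "rogue_feature")
})

test_that("normexp estimation from negative controls follows the control moments", {
  fg <- rep(600, 60)  # foreground mean exactly 600
  p <- estimate_normexp_params(fg, negative_controls = c(90, 100, 110))
  expect_equal(p$mu, 100)
  expect_equal(p$sigma, 10)
  expect_equal(p$alpha, 500)

  # constant controls: sigma floored, not zero
  p2 <- estimate_normexp_params(fg, negative_controls = rep(100, 20))
  expect_gt(p2$sigma, 0)
})

test_that("normexp maximum likelihood recovers simulated parameters", {
  set.seed(505)
  n <- 1e5  # sigma is the hardest parameter; 5% needs this many draws
  x <- pmax(rnorm(n, 100, 10) + rexp(n, 1 / 500), 1e-6)
  p <- estimate_normexp_params(x)
  expect_lt(abs(p$mu - 100) / 100, 0.05)
  expect_lt(abs(p$sigma - 10) / 10, 0.05)
  expect_lt(abs(p$alpha - 500) / 500, 0.05)
  expect_error(estimate_normexp_params(c(x[1:60], -1)), "> 0")
})

test_that("normexp correction matches the integration oracle and is monotone positive", {
  p <- normexp_params(5, 1, 10)
  expect_equal(normexp_correct(10, p), normexp_oracle(10, 5, 1, 10),
               tolerance = 1e-9)

  # grid kept inside the numerically representable range of the
  # integration oracle (the closed form itself is fine for any x)
  grid <- seq(1, 60, length.out = 25)
  got <- normexp_correct(grid, p)
  oracle <- vapply(grid, normexp_oracle, numeric(1), mu = 5, sigma = 1,
                   alpha = 10)
  expect_lt(max(abs(got - oracle) / oracle), 1e-6)
  expect_true(all(got > 0))
  expect_true(all(diff(got) >= 0))

  # sigma -> 0 limit: correction tends to x - mu - sigma^2/alpha
  p_small <- normexp_params(5, 1e-4, 10)
  expect_equal(normexp_correct(10, p_small), 10 - 5 - 1e-8 / 10,
               tolerance = 1e-10)
})

test_that("quantile normalization: hand example, fixed point, equal distributions", {
  m <- cbind(s1 = c(5, 3, 1), s2 = c(2, 4, 6))
  rownames(m) <- paste0("g", 1:3)
  got <- quantile_normalize(m)
  expect_equal(unname(got[, "s1"]), c(5.5, 3.5, 1.5))
  expect_equal(unname(got[, "s2"]), c(1.5, 3.5, 5.5))

  same <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(quantile_normalize(same), same)

  expect_error(quantile_normalize(matrix(1:3, 3, 1)), "2 samples")

  # ties share the mean of their rank span
  tied <- cbind(x = c(2, 2, 5), y = c(1, 3, 9))
  qn <- quantile_normalize(tied)
  expect_equal(qn[1, "x"], qn[2, "x"])
  expect_equal(sort(qn[, "y"]), sort(rowMeans(cbind(sort(tied[, 1]),
                                                    sort(tied[, 2])))))
})

test_that("median polish summarization: hand case, single probe, equivariance", {
  expect_equal(unname(median_polish_summarize(rbind(c(1, 3), c(2, 4)))),
               c(1.5, 3.5))
  single <- matrix(c(4.4, 2.2, 9.9), 1, 3)
  expect_equal(unname(median_polish_summarize(single)), c(4.4, 2.2, 9.9))

  set.seed(606)
  for (i in 1:5) {
    x <- matrix(rnorm(8 * 4, 8), 8, 4)
    base <- median_polish_summarize(x)
    expect_equal(median_polish_summarize(x + 2.5), base + 2.5,
                 tolerance = 1e-10)
    perm <- sample(4)
    expect_equal(unname(median_polish_summarize(x[, perm])),
                 unname(base[perm]), tolerance = 1e-12)
  }
})

test_that("replicate collapsing averages by key in first-appearance order", {
  m <- matrix(c(2, 4, 10), 3, 1, dimnames = list(c("a1", "a2", "b1"), "s1"))
  got <- collapse_replicates(m, c("A", "A", "B"))
  expect_equal(got["A", "s1"], 3)
  expect_equal(rownames(got), c("A", "B"))

  m2 <- rand_matrix(6, 2, seed = 707)
  expect_equal(unname(collapse_replicates(m2, rownames(m2))), unname(m2))

  m3 <- rand_matrix(100, 2, seed = 708)
  keys <- rep(sprintf("k%02d", 1:10), each = 10)
  expect_equal(nrow(collapse_replicates(m3, keys)), 10L)
})

test_that("control splitting retains negatives for thresholding", {
  batch <- list(
    features = data.frame(
      feature_id = paste0("f", 1:5),
      control_class = c("none", "negative", "none", "other", "none"),
      replicate_key = paste0("f", 1:5), stringsAsFactors = FALSE),
    intensity = matrix(2^(1:10), 5, 2,
                       dimnames = list(paste0("f", 1:5), c("s1", "s2")))
  )
  sp <- split_controls(batch)
  expect_equal(nrow(sp$batch$intensity), 3L)
  expect_equal(sort(sp$negative_log2), c(2, 7))  # log2 of feature f2 only

  none <- batch
  none$features$control_class <- rep("none", 5)
  sp2 <- split_controls(none)
  expect_equal(nrow(sp2$batch$intensity), 5L)
  expect_length(sp2$negative_log2, 0L)

  all_ctl <- batch
  all_ctl$features$control_class <- rep("negative", 5)
  expect_error(split_controls(all_ctl), "control")
})

test_that("unexpressed threshold is the 95th percentile of control log2 values", {
  set.seed(808)
  x <- runif(100, 2, 4)
  expected <- sort(x)[95] + 0.05 * (sort(x)[96] - sort(x)[95])  # type-7 by hand
  expect_equal(estimate_unexpressed_threshold(x), expected)
  expect_gt(estimate_unexpressed_threshold(x), median(x))
  expect_equal(estimate_unexpressed_threshold(rep(3, 50)), 3)
  expect_warning(got <- estimate_unexpressed_threshold(c(1, 2, 3)), "10")
  expect_equal(got, 3)
})

test_that("prepare pipeline: shapes, no controls, finite values, determinism", {
  dir <- withr::local_tempdir()
  generate_raw_batch(dir, probesets = 50, probes_per_set = 4, samples = 4,
                     seed = 11)
  out1 <- file.path(dir, "expr1.csv")
  out2 <- file.path(dir, "expr2.csv")
  res <- prepare_pipeline(dir, platform = "probeset", pattern = "sample_.*\\.csv$",
                          output = out1, qc_dir = file.path(dir, "qc"))
  expect_equal(dim(res$matrix), c(50L, 4L))
  expect_true(all(is.finite(res$matrix)))
  expect_false(any(grepl("^neg_", rownames(res$matrix))))
  expect_true(is.finite(res$threshold))
  expect_true(file.exists(file.path(dir, "qc", "distribution_pre.csv")))

  prepare_pipeline(dir, platform = "probeset", pattern = "sample_.*\\.csv$",
                   output = out2)
  expect_identical(file_bytes(out1), file_bytes(out2))

  # single-probe path: rows = distinct replicate keys
  res2 <- prepare_pipeline(dir, platform = "single_probe",
                           pattern = "sample_.*\\.csv$")
  expect_equal(nrow(res2$matrix), 50L)
})
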