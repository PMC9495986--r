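# Raw-intensity preparation: turn per-sample scanner-style text exports into
# a normalized, summarized, control-free log2 expression matrix.
#
# A raw batch is a list:
#   features  - data.frame(feature_id, control_class, replicate_key)
#   intensity - features x samples matrix of linear-scale intensities
# Feature metadata is shared across samples (the merge step enforces an
# identical feature universe).

control_classes <- c("none", "negative", "other")

read_raw_sample <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("feature_id", "intensity", "control_class", "replicate_key")
  missing <- setdiff(need, colnames(d))
  if (length(missing)) {
    stop("raw sample ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(d$feature_id)) {
    dup <- unique(d$feature_id[duplicated(d$feature_id)])
    stop("duplicated feature ids in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(d$intensity) || any(!is.finite(d$intensity)) ||
      any(d$intensity <= 0)) {
    stop("intensities in ", path, " must be finite and > 0", call. = FALSE)
  }
  bad <- setdiff(unique(d$control_class), control_classes)
  if (length(bad)) {
    stop("unknown control class(es) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d[, need]
}

#' Load and merge a directory of raw intensity files
#'
#' One file per sample, sample name = file name without extension. All files
#' must describe exactly the same feature universe (ids, control classes and
#' replicate keys); features are aligned to the first file's order.
#'
#' @param directory directory holding the raw sample files.
#' @param pattern regular expression selecting the files (>= 2 must match).
#' @return a raw batch list (`features`, `intensity`).
#' @export
load_raw_batch <- function(directory, pattern = "\\.csv$") {
  if (!dir.exists(directory)) {
    stop("directory not found: ", directory, call. = FALSE)
  }
  files <- sort(list.files(directory, pattern = pattern, full.names = TRUE))
  if (length(files) < 2) {
    stop("pattern '", pattern, "' matches ", length(files),
         " file(s) in ", directory, "; at least 2 samples are required",
         call. = FALSE)
  }
  samples <- lapply(files, read_raw_sample)
  names(samples) <- tools::file_path_sans_ext(basename(files))
  ref <- samples[[1]]
  intensity <- matrix(NA_real_, nrow(ref), length(samples),
                      dimnames = list(ref$feature_id, names(samples)))
  intensity[, 1] <- ref$intensity
  for (i in seq_along(samples)[-1]) {
    s <- samples[[i]]
    extra <- setdiff(s$feature_id, ref$feature_id)
    absent <- setdiff(ref$feature_id, s$feature_id)
    if (length(extra) || length(absent)) {
      stop("feature universe mismatch in sample '", names(samples)[i], "': ",
           if (length(extra)) paste0("unexpected [",
             paste(utils::head(extra, 5), collapse = ", "), "] "),
           if (length(absent)) paste0("missing [",
             paste(utils::head(absent, 5), collapse = ", "), "]"),
           call. = FALSE)
    }
    idx <- match(ref$feature_id, s$feature_id)
    if (!identical(s$control_class[idx], ref$control_class) ||
        !identical(s$replicate_key[idx], ref$replicate_key)) {
      stop("feature metadata (control class / replicate key) differs in sample '",
           names(samples)[i], "'", call. = FALSE)
    }
    intensity[, i] <- s$intensity[idx]
  }
  if (all(ref$control_class != "none")) {
    stop("every feature is flagged as a control", call. = FALSE)
  }
  list(
    features = data.frame(feature_id = ref$feature_id,
                          control_class = ref$control_class,
                          replicate_key = ref$replicate_key,
                          stringsAsFactors = FALSE),
    intensity = intensity
  )
}

#' Normal + exponential convolution parameters
#'
#' Observed intensity X = S + B with signal S ~ Exponential(mean `alpha`)
#' and background B ~ Normal(`mu`, `sigma`^2).
#'
#' @param mu background mean (linear intensity scale).
#' @param sigma background standard deviation (> 0).
#' @param alpha signal exponential mean (> 0).
#' @return object of class `normexp_params`.
#' @export
normexp_params <- function(mu, sigma, alpha) {
  stopifnot(is.finite(mu), is.finite(sigma), is.finite(alpha))
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, alpha = alpha),
            class = "normexp_params")
}

# log-density of the normexp convolution, vectorized over x
normexp_loglik <- function(x, mu, sigma, alpha) {
  -log(alpha) + (mu - x) / alpha + sigma^2 / (2 * alpha^2) +
    stats::pnorm((x - mu - sigma^2 / alpha) / sigma, log.p = TRUE)
}

#' Estimate normexp parameters
#'
#' With negative controls: `mu` and `sigma` are their mean and standard
#' deviation and `alpha` is the mean foreground excess over `mu`. Without
#' controls: maximum likelihood on the convolution density by numerical
#' optimization, initialized from robust moments (5th percentile; s.d. of
#' values below the 10th percentile; mean excess over the 5th percentile).
#' `sigma` is floored at 1e-6 of the mean intensity to avoid degeneracy.
#'
#' @param intensities linear-scale positive intensities (>= 50 values).
#' @param negative_controls optional linear-scale negative-control
#'   intensities.
#' @return a [normexp_params()] object.
#' @export
estimate_normexp_params <- function(intensities, negative_controls = NULL) {
  x <- as.numeric(intensities)
  if (length(x) < 50) {
    stop("need at least 50 intensities to estimate normexp parameters",
         call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("intensities must be finite and > 0", call. = FALSE)
  }
  floor_sigma <- 1e-6 * mean(x)
  if (!is.null(negative_controls) && length(negative_controls)) {
    nc <- as.numeric(negative_controls)
    if (any(!is.finite(nc)) || any(nc <= 0)) {
      stop("negative-control intensities must be finite and > 0",
           call. = FALSE)
    }
    mu <- mean(nc)
    sigma <- max(stats::sd(nc), floor_sigma)
    if (is.na(sigma)) sigma <- floor_sigma  # a single control value
    alpha <- max(mean(x) - mu, floor_sigma)
    return(normexp_params(mu, sigma, alpha))
  }
  q05 <- stats::quantile(x, 0.05, names = FALSE)
  low <- x[x < stats::quantile(x, 0.10, names = FALSE)]
  sigma0 <- max(stats::sd(low), floor_sigma)
  if (is.na(sigma0)) sigma0 <- floor_sigma
  alpha0 <- max(mean(x) - q05, floor_sigma)
  par0 <- c(q05, log(sigma0), log(alpha0))
  nll <- function(par) {
    -sum(normexp_loglik(x, par[1], exp(par[2]), exp(par[3])))
  }
  fit <- stats::optim(par0, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (fit$convergence != 0) {
    stop("normexp maximum-likelihood fit did not converge (code ",
         fit$convergence, ", value ", format(fit$value), ", par ",
         paste(format(fit$par), collapse = ", "), ")", call. = FALSE)
  }
  normexp_params(fit$par[1], max(exp(fit$par[2]), floor_sigma),
                 exp(fit$par[3]))
}

#' Normexp background correction
#'
#' Replaces an observed intensity x by the posterior mean of the signal,
#' E\[S | X = x\] = m + sigma * phi(m/sigma) / Phi(m/sigma) with
#' m = x - mu - sigma^2/alpha, evaluated through a numerically stable
#' log-scale Mills ratio. The result is strictly positive and monotone
#' non-decreasing in x.
#'
#' @param x observed intensities (any real values accepted).
#' @param params a [normexp_params()] object.
#' @return corrected intensities, same length as `x`.
#' @export
normexp_correct <- function(x, params) {
  stopifnot(inherits(params, "normexp_params"))
  m <- x - params$mu - params$sigma^2 / params$alpha
  z <- m / params$sigma
  out <- m + params$sigma *
    exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  # mathematically > 0; clamp against floating-point underflow far below mu
  pmax(out, .Machine$double.xmin)
}

#' Quantile normalization
#'
#' Forces identical empirical distributions across samples: sort each
#' column, replace the value of rank r everywhere by the mean across columns
#' of the rank-r values, restore the original order. Ties within a column
#' receive the mean of the reference values over their tied rank span. The
#' operation is idempotent.
#'
#' @param m expression matrix with >= 2 samples.
#' @return quantile-normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || ncol(m) < 2) {
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(m))) stop("matrix must be complete", call. = FALSE)
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    v <- numeric(nrow(m))
    v[o] <- ref
    out[, j] <- stats::ave(v, m[, j], FUN = mean)
  }
  out
}

#' Median-polish summarization
#'
#' Two-way median polish of a probes x samples log2 block (row sweep first,
#' then column sweep; at most `max_iter` iterations or until the largest
#' absolute sweep change drops below `eps`). The per-sample summary is the
#' overall effect plus the sample's column effect, as in RMA.
#'
#' @param probe_values numeric matrix, probes x samples.
#' @param max_iter maximum sweep iterations.
#' @param eps convergence tolerance on the largest absolute change.
#' @return numeric vector of per-sample summaries (named like the columns).
#' @export
median_polish_summarize <- function(probe_values, max_iter = 10, eps = 1e-4) {
  z <- as.matrix(probe_values)
  if (!nrow(z) || !ncol(z)) stop("empty probe block", call. = FALSE)
  t_eff <- 0
  row_eff <- numeric(nrow(z))
  col_eff <- numeric(ncol(z))
  for (iter in seq_len(max_iter)) {
    rdelta <- apply(z, 1, stats::median)
    z <- z - rdelta
    row_eff <- row_eff + rdelta
    delta <- stats::median(col_eff)
    col_eff <- col_eff - delta
    t_eff <- t_eff + delta
    cdelta <- apply(z, 2, stats::median)
    z <- sweep(z, 2, cdelta)
    col_eff <- col_eff + cdelta
    delta <- stats::median(row_eff)
    row_eff <- row_eff - delta
    t_eff <- t_eff + delta
    if (max(abs(rdelta), abs(cdelta)) < eps) break
  }
  stats::setNames(t_eff + col_eff, colnames(probe_values))
}

#' Collapse replicate rows by key
#'
#' One output row per replicate key, the arithmetic mean of its member rows
#' per sample; output order is the first-appearance order of the keys.
#'
#' @param m expression matrix.
#' @param replicate_keys character vector, one key per row of `m`.
#' @return collapsed matrix with the keys as rownames.
#' @export
collapse_replicates <- function(m, replicate_keys) {
  if (length(replicate_keys) != nrow(m)) {
    stop("replicate keys must cover every row", call. = FALSE)
  }
  keys <- as.character(replicate_keys)
  sums <- rowsum(m, group = keys, reorder = FALSE)
  counts <- as.vector(rowsum(rep(1, nrow(m)), group = keys, reorder = FALSE))
  sums / counts
}

#' Split control features out of a raw batch
#'
#' Removes control-flagged features from the expression stream and returns
#' the log2 intensities of the negative-control class (the empirical picture
#' of an unexpressed feature) for downstream thresholding.
#'
#' @param batch a raw batch from [load_raw_batch()].
#' @return list with `batch` (controls removed) and `negative_log2`
#'   (numeric vector, possibly empty).
#' @export
split_controls <- function(batch) {
  cls <- batch$features$control_class
  keep <- cls == "none"
  if (!any(keep)) stop("every feature is flagged as a control", call. = FALSE)
  neg <- batch$intensity[cls == "negative", , drop = FALSE]
  list(
    batch = list(features = batch$features[keep, , drop = FALSE],
                 intensity = batch$intensity[keep, , drop = FALSE]),
    negative_log2 = as.vector(log2(neg))
  )
}

#' Unexpressed-intensity threshold from negative controls
#'
#' The 95th percentile (linear-interpolation definition) of the
#' negative-control log2 intensities: a conservative estimate of the
#' intensity an unexpressed feature can reach through background and
#' non-specific hybridization, usable as the filtering threshold theta_E.
#'
#' @param neg_control_log2 log2 negative-control intensities.
#' @return log2 threshold (scalar).
#' @export
estimate_unexpressed_threshold <- function(neg_control_log2) {
  x <- as.numeric(neg_control_log2)
  if (length(x) < 10) {
    warning("fewer than 10 negative-control values; returning their maximum")
    return(max(x))
  }
  stats::quantile(x, 0.95, names = FALSE)
}

# collapse per-feature control classes to the replicate-key level: a key is
# a control only if all member features agree on a non-"none" class
key_control_class <- function(features) {
  keys <- unique(features$replicate_key)
  cls <- vapply(keys, function(k) {
    v <- unique(features$control_class[features$replicate_key == k])
    if (length(v) == 1) v else "none"
  }, character(1))
  stats::setNames(cls, keys)
}

#' Full raw-data preparation pipeline
#'
#' Runs, in order: load + merge, log2 for pre-normalization QC, per-sample
#' normexp background correction on the linear scale, log2, quantile
#' normalization, (probeset platforms) median-polish summarization by
#' replicate key, post-normalization QC, control removal with
#' negative-control threshold estimation, (single-probe platforms) replicate
#' collapsing, and optional CSV output.
#'
#' @param directory directory of raw sample files.
#' @param platform `"probeset"` (probes summarized into probe sets) or
#'   `"single_probe"` (replicate probes averaged).
#' @param pattern regular expression selecting raw files.
#' @param remove_controls drop control features from the output.
#' @param output optional path for the final expression CSV.
#' @param qc_dir optional directory for QC data files.
#' @return list with `matrix` (the final expression matrix), `threshold`
#'   (negative-control log2 threshold or `NA`), `qc` (pre/post summaries)
#'   and `log` (character vector describing every step).
#' @export
prepare_pipeline <- function(directory,
                             platform = c("probeset", "single_probe"),
                             pattern = "\\.csv$", remove_controls = TRUE,
                             output = NULL, qc_dir = NULL) {
  platform <- match.arg(platform)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  batch <- load_raw_batch(directory, pattern)
  note("loaded ", ncol(batch$intensity), " samples x ",
       nrow(batch$intensity), " features from ", directory,
       " (pattern '", pattern, "')")

  raw_log2 <- log2(batch$intensity)
  rownames(raw_log2) <- batch$features$feature_id
  qc_pre <- distribution_summary(raw_log2)
  note("pre-normalization QC computed on log2 raw intensities")

  corrected <- batch$intensity
  for (j in seq_len(ncol(corrected))) {
    neg <- batch$intensity[batch$features$control_class == "negative", j]
    params <- estimate_normexp_params(batch$intensity[, j],
                                      if (length(neg) >= 2) neg)
    corrected[, j] <- normexp_correct(batch$intensity[, j], params)
    note(sprintf(
      "normexp sample '%s': mu=%.4g sigma=%.4g alpha=%.4g (%s)",
      colnames(corrected)[j], params$mu, params$sigma, params$alpha,
      if (length(neg) >= 2) "negative-control estimator" else "MLE"))
  }

  m <- quantile_normalize(log2(corrected))
  rownames(m) <- batch$features$feature_id
  note("quantile normalization applied (", ncol(m), " samples)")

  if (platform == "probeset") {
    keys <- unique(batch$features$replicate_key)
    summarized <- matrix(NA_real_, length(keys), ncol(m),
                         dimnames = list(keys, colnames(m)))
    for (k in keys) {
      rows <- batch$features$replicate_key == k
      summarized[k, ] <- median_polish_summarize(m[rows, , drop = FALSE])
    }
    cls <- key_control_class(batch$features)
    m <- summarized
    note("median-polish summarization: ", length(keys), " probe sets")
  } else {
    cls <- stats::setNames(batch$features$control_class,
                           batch$features$feature_id)
  }

  qc_post <- distribution_summary(m)
  note("post-normalization QC computed")

  neg_log2 <- as.vector(m[cls[rownames(m)] == "negative", , drop = FALSE])
  threshold <- NA_real_
  if (length(neg_log2)) {
    threshold <- estimate_unexpressed_threshold(neg_log2)
    note(sprintf(
      "unexpressed-intensity estimate (95th percentile of %d negative-control log2 values): %.6g",
      length(neg_log2), threshold))
  } else {
    note("no negative controls: no unexpressed-intensity estimate")
  }
  if (remove_controls) {
    keep <- cls[rownames(m)] == "none"
    if (!any(keep)) stop("every row is a control", call. = FALSE)
    m <- m[keep, , drop = FALSE]
    note("control removal: ", sum(!keep), " control rows dropped, ",
         sum(keep), " retained")
  }

  if (platform == "single_probe") {
    keys <- batch$features$replicate_key[
      match(rownames(m), batch$features$feature_id)]
    m <- collapse_replicates(m, keys)
    note("replicate collapsing: ", nrow(m), " distinct keys")
  }

  validate_expression_matrix(m, "prepared matrix")
  if (!is.null(qc_dir)) {
    dir.create(qc_dir, recursive = TRUE, showWarnings = FALSE)
    write_distribution_summary(qc_pre, file.path(qc_dir, "distribution_pre.csv"))
    write_distribution_summary(qc_post, file.path(qc_dir, "distribution_post.csv"))
    if (ncol(m) >= 3) {
      ord <- order_by_loess_linearity(m)
      write_table_csv(ord, file.path(qc_dir, "ma_linearity_order.csv"))
    }
    note("QC data files written to ", qc_dir)
  }
  if (!is.null(output)) {
    write_expression_matrix(m, output)
    note("expression matrix written to ", output)
  }
  list(matrix = m, threshold = threshold,
       qc = list(pre = qc_pre, post = qc_post), log = log)
}
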