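# Seeded synthetic-data generators with known ground truth. The expression
# generator draws from exactly the hierarchical model the empirical-Bayes
# arm assumes (scaled inverse-chi-square gene variances), so calibration
# and recovery tests have a stated world to measure against. Every
# generator is a pure function of its parameters plus the seed.

#' Generate a two-group log2 expression dataset with known DE genes
#'
#' Gene variances are drawn as s0_sq * d0 / chisq(d0) (the EB prior),
#' baseline means as Normal(7, 1.5^2) on the log2 scale. A `de_fraction`
#' share of genes is shifted by +/- `log2fc` (random sign) in the test
#' group. Optionally an additive `batch_shift` is applied to a random half
#' of the samples (balanced across groups).
#'
#' @param genes number of genes.
#' @param n_per_group samples per group (groups are `control`, `treated`).
#' @param de_fraction fraction of genes truly differentially expressed.
#' @param log2fc true absolute log2 fold change of DE genes.
#' @param d0,s0_sq variance-prior degrees of freedom and scale.
#' @param batch_shift additive shift for the second batch (0 = no batches).
#' @param seed integer seed.
#' @return list with `matrix`, `groups` and `truth` (`de_ids`, `signs`,
#'   `batch_labels`, `sigma2`).
#' @export
generate_expression_dataset <- function(genes = 2000, n_per_group = 10,
                                        de_fraction = 0.1, log2fc = 1,
                                        d0 = 4, s0_sq = 0.05,
                                        batch_shift = 0, seed = 1) {
  if (de_fraction < 0 || de_fraction > 1) {
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    n <- 2 * n_per_group
    gene_ids <- sprintf("gene_%05d", seq_len(genes))
    groups <- rep(c("control", "treated"), each = n_per_group)
    sample_names <- paste0(groups, "_", c(seq_len(n_per_group),
                                          seq_len(n_per_group)))
    sigma2 <- if (is.finite(d0)) {
      s0_sq * d0 / stats::rchisq(genes, df = d0)
    } else {
      rep(s0_sq, genes)
    }
    baseline <- stats::rnorm(genes, 7, 1.5)
    n_de <- round(genes * de_fraction)
    de_idx <- sort(sample.int(genes, n_de))
    signs <- sample(c(-1, 1), n_de, replace = TRUE)
    mu <- matrix(baseline, genes, n)
    mu[de_idx, groups == "treated"] <- mu[de_idx, groups == "treated"] +
      signs * log2fc
    batch_labels <- NULL
    if (batch_shift != 0) {
      # balanced: half of each group in the shifted batch
      in_b2 <- unlist(lapply(unique(groups), function(g) {
        idx <- which(groups == g)
        sample(idx, length(idx) %/% 2)
      }))
      batch_labels <- rep("b1", n)
      batch_labels[in_b2] <- "b2"
      mu[, batch_labels == "b2"] <- mu[, batch_labels == "b2"] + batch_shift
    }
    m <- mu + matrix(stats::rnorm(genes * n, sd = sqrt(sigma2)), genes, n)
    dimnames(m) <- list(gene_ids, sample_names)
    list(matrix = m, groups = groups,
         truth = list(de_ids = gene_ids[de_idx],
                      signs = stats::setNames(signs, gene_ids[de_idx]),
                      batch_labels = batch_labels, sigma2 = sigma2))
  })
}

#' Generate raw intensity files matching the normexp model
#'
#' Per-feature intensity = Normal(mu, sigma^2) background plus an
#' Exponential signal whose mean is `alpha` scaled by the probe set's true
#' expression factor (2^Normal(0, 2^2) across probe sets, i.e. roughly the
#' 2-3 orders of magnitude of dynamic range a one-color array resolves),
#' truncated positive.
#' Negative controls carry background only. One CSV per sample is written
#' in the raw preparation format; output is byte-identical for a fixed
#' seed.
#'
#' @param directory output directory (created if needed).
#' @param probesets number of probe sets.
#' @param probes_per_set probes per probe set.
#' @param samples number of samples.
#' @param mu,sigma background mean and s.d. (linear scale).
#' @param alpha signal exponential mean (linear scale).
#' @param n_neg_controls number of negative-control features.
#' @param seed integer seed.
#' @return list with `files` and `truth` (`expression_factor` per probe
#'   set).
#' @export
generate_raw_batch <- function(directory, probesets = 50, probes_per_set = 11,
                               samples = 4, mu = 100, sigma = 10,
                               alpha = 500, n_neg_controls = 50, seed = 1) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    factor <- 2^stats::rnorm(probesets, 0, 2)
    set_ids <- sprintf("ps_%04d", seq_len(probesets))
    features <- data.frame(
      feature_id = c(sprintf("ps_%04d_p%02d",
                             rep(seq_len(probesets), each = probes_per_set),
                             rep(seq_len(probes_per_set), probesets)),
                     sprintf("neg_%04d", seq_len(n_neg_controls))),
      control_class = c(rep("none", probesets * probes_per_set),
                        rep("negative", n_neg_controls)),
      replicate_key = c(rep(set_ids, each = probes_per_set),
                        sprintf("neg_%04d", seq_len(n_neg_controls))),
      stringsAsFactors = FALSE
    )
    n_fg <- probesets * probes_per_set
    files <- character(samples)
    for (s in seq_len(samples)) {
      signal <- stats::rexp(n_fg, rate = 1 /
                              (alpha * rep(factor, each = probes_per_set)))
      bg <- stats::rnorm(n_fg + n_neg_controls, mu, sigma)
      intensity <- pmax(c(bg[seq_len(n_fg)] + signal,
                          bg[(n_fg + 1):(n_fg + n_neg_controls)]), 1e-6)
      out <- data.frame(feature_id = features$feature_id,
                        intensity = intensity,
                        control_class = features$control_class,
                        replicate_key = features$replicate_key,
                        stringsAsFactors = FALSE)
      files[s] <- file.path(directory, sprintf("sample_%02d.csv", s))
      write_table_csv(out, files[s])
    }
    list(files = files,
         truth = list(expression_factor = stats::setNames(factor, set_ids)))
  })
}

#' Generate a negative-binomial count dataset with known DE genes
#'
#' Relative gene abundances are log-normal and normalized to proportions;
#' the expected count is `lib_size` times the proportion, multiplied by
#' `fold^(+/-1)` for DE genes in the test group. Counts are negative
#' binomial with the given dispersion (variance = mu + dispersion * mu^2).
#'
#' @param genes number of genes.
#' @param n_per_group samples per group.
#' @param de_fraction fraction of DE genes.
#' @param fold true fold change of DE genes (1 = null dataset).
#' @param dispersion NB dispersion (> 0).
#' @param lib_size expected library size.
#' @param seed integer seed.
#' @return list with `counts`, `groups` and `truth` (`de_ids`, `signs`).
#' @export
generate_count_dataset <- function(genes = 2000, n_per_group = 8,
                                   de_fraction = 0.1, fold = 2,
                                   dispersion = 0.1, lib_size = 1e6,
                                   seed = 1) {
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (de_fraction < 0 || de_fraction > 1) {
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    n <- 2 * n_per_group
    gene_ids <- sprintf("gene_%05d", seq_len(genes))
    groups <- rep(c("control", "treated"), each = n_per_group)
    sample_names <- paste0(groups, "_", c(seq_len(n_per_group),
                                          seq_len(n_per_group)))
    prop <- stats::rlnorm(genes, meanlog = 0, sdlog = 1.5)
    prop <- prop / sum(prop)
    n_de <- round(genes * de_fraction)
    de_idx <- sort(sample.int(genes, n_de))
    signs <- sample(c(-1, 1), n_de, replace = TRUE)
    mu <- matrix(lib_size * prop, genes, n)
    mu[de_idx, groups == "treated"] <- mu[de_idx, groups == "treated"] *
      fold^signs
    counts <- matrix(stats::rnbinom(genes * n, mu = mu, size = 1 / dispersion),
                     genes, n, dimnames = list(gene_ids, sample_names))
    list(counts = counts, groups = groups,
         truth = list(de_ids = gene_ids[de_idx],
                      signs = stats::setNames(signs, gene_ids[de_idx])))
  })
}
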