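# Non-parametric arm: rank products with a permutation estimate of the
# proportion of false positives (PFP). The rank product of a gene is the
# geometric mean of its fold-change ranks across all pairwise between-group
# comparisons; a small RP means consistently extreme regulation. Batch
# effects are handled by restricting comparisons to within-batch strata.

#' Pairwise log2-ratio matrix for a contrast
#'
#' Unpaired designs: one column per (test sample, reference sample) pair
#' within the same batch stratum, value = test - reference (a log2 ratio on
#' log2 data). Paired designs: one column per pair, test minus reference
#' within the pair.
#'
#' @param m expression matrix (log2).
#' @param groups group label per sample.
#' @param contrast `c(test, reference)` levels.
#' @param pairing optional pairing label per sample.
#' @param batches optional batch label per sample (ignored when paired).
#' @return genes x K numeric matrix of log2 differences.
#' @export
compute_pairwise_ratios <- function(m, groups, contrast, pairing = NULL,
                                    batches = NULL) {
  stopifnot(length(groups) == ncol(m))
  test <- contrast[1]
  ref <- contrast[2]
  if (!all(c(test, ref) %in% groups)) {
    stop("contrast level(s) absent from the design: ",
         paste(setdiff(c(test, ref), groups), collapse = ", "), call. = FALSE)
  }
  if (!is.null(pairing)) {
    stopifnot(length(pairing) == ncol(m))
    involved <- groups %in% c(test, ref)
    pairs <- unique(pairing[involved])
    cols <- lapply(pairs, function(pr) {
      it <- which(pairing == pr & groups == test)
      ir <- which(pairing == pr & groups == ref)
      if (length(it) != 1 || length(ir) != 1) {
        stop("pair '", pr, "' must have exactly one sample per contrast ",
             "level (found ", length(it), " test, ", length(ir),
             " reference)", call. = FALSE)
      }
      m[, it] - m[, ir]
    })
    names(cols) <- paste0("pair_", pairs)
  } else {
    strata <- if (is.null(batches)) rep("all", ncol(m)) else {
      stopifnot(length(batches) == ncol(m))
      batches
    }
    involved_strata <- unique(strata[groups %in% c(test, ref)])
    cols <- list()
    for (b in involved_strata) {
      it <- which(strata == b & groups == test)
      ir <- which(strata == b & groups == ref)
      if (!length(it) || !length(ir)) {
        stop("batch stratum '", b, "' lacks samples of level '",
             if (length(it)) ref else test, "'", call. = FALSE)
      }
      for (i in it) for (j in ir) {
        cols[[paste0(colnames(m)[i], ".vs.", colnames(m)[j])]] <-
          m[, i] - m[, j]
      }
    }
  }
  ratios <- do.call(cbind, cols)
  rownames(ratios) <- rownames(m)
  ratios
}

#' Rank-product statistics
#'
#' For each comparison column, genes are ranked by the ratio: descending for
#' the up direction (rank 1 = largest ratio) and ascending for down, with
#' average ranks on ties. RP is the geometric mean of the K ranks, so
#' 1 <= RP <= G.
#'
#' @param ratios genes x K ratio matrix (>= 2 genes).
#' @return list with `rp_up` and `rp_down` (named numeric vectors).
#' @export
rank_product_stat <- function(ratios) {
  if (nrow(ratios) < 2) stop("need at least 2 genes", call. = FALSE)
  up_ranks <- apply(ratios, 2, function(x) rank(-x, ties.method = "average"))
  down_ranks <- apply(ratios, 2, function(x) rank(x, ties.method = "average"))
  list(
    rp_up = stats::setNames(exp(rowMeans(log(up_ranks))), rownames(ratios)),
    rp_down = stats::setNames(exp(rowMeans(log(down_ranks))), rownames(ratios)),
    up_ranks = up_ranks, down_ranks = down_ranks
  )
}

#' Permutation p and PFP estimates for rank products
#'
#' Null model: independently shuffle the gene labels within every comparison
#' column (equivalently, permute each column's rank vector) and recompute
#' the rank products. Pooling permuted values across genes and permutations,
#' for each gene g: c_g = count of permuted RP <= observed RP_g,
#' E_g = c_g / n_perm (expected false positives at g's cutoff),
#' p_g = c_g / (n_perm * G), PFP_g = E_g / rank(RP_g ascending). Fully
#' deterministic for a fixed seed.
#'
#' @param ratios genes x K ratio matrix.
#' @param rp observed statistics from [rank_product_stat()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return data.frame with `p_up`, `pfp_up`, `p_down`, `pfp_down` (raw PFP,
#'   not clipped), one row per gene.
#' @export
permutation_pfp <- function(ratios, rp, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  G <- nrow(ratios)
  K <- ncol(ratios)
  lup <- log(rp$up_ranks)
  ldown <- log(rp$down_ranks)
  perm_up <- matrix(NA_real_, G, n_perm)
  perm_down <- matrix(NA_real_, G, n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      s_up <- numeric(G)
      s_down <- numeric(G)
      for (k in seq_len(K)) {
        idx <- sample.int(G)
        s_up <- s_up + lup[idx, k]
        s_down <- s_down + ldown[idx, k]
      }
      perm_up[, b] <- exp(s_up / K)
      perm_down[, b] <- exp(s_down / K)
    }
  })
  count_le <- function(observed, permuted) {
    sorted <- sort(as.vector(permuted))
    # small relative tolerance so equal geometric means summed in a
    # different order still count as ties
    findInterval(observed * (1 + 1e-9), sorted)
  }
  per_direction <- function(observed, permuted) {
    cg <- count_le(observed, permuted)
    e <- cg / n_perm
    list(p = cg / (n_perm * G),
         pfp = e / rank(observed, ties.method = "average"))
  }
  up <- per_direction(rp$rp_up, perm_up)
  down <- per_direction(rp$rp_down, perm_down)
  data.frame(p_up = up$p, pfp_up = up$pfp, p_down = down$p,
             pfp_down = down$pfp, row.names = rownames(ratios))
}

#' Rank-product test for one contrast
#'
#' Runs the full non-parametric arm and merges the two one-sided results
#' into one signed table: per gene, the direction with the smaller
#' permutation p-value wins; an exact tie is flagged and marked 0. The
#' reported `q_value` is the winning direction's PFP clipped to `[0, 1]`
#' (the raw value is kept in `pfp_raw`); `log2_fc` is the mean of the
#' pairwise ratios; the sign convention makes `log2_fc` positive for
#' upregulation in the test group.
#'
#' @param m expression matrix (log2).
#' @param groups group label per sample.
#' @param contrast `c(test, reference)`.
#' @param pairing,batches optional per-sample labels.
#' @param n_perm permutations for the PFP estimate.
#' @param seed integer seed.
#' @return list with `table` (data.frame: `log2_fc`, `stat`, `p_value`,
#'   `q_value`, `pfp_raw`, `direction`, `tie`), `ratios` and the raw
#'   per-direction estimates.
#' @export
rank_product_test <- function(m, groups, contrast, pairing = NULL,
                              batches = NULL, n_perm = 1000, seed = 1) {
  ratios <- compute_pairwise_ratios(m, groups, contrast, pairing, batches)
  rp <- rank_product_stat(ratios)
  est <- permutation_pfp(ratios, rp, n_perm = n_perm, seed = seed)
  up_wins <- est$p_up < est$p_down
  tie <- est$p_up == est$p_down
  table <- data.frame(
    log2_fc = rowMeans(ratios),
    stat = ifelse(up_wins, rp$rp_up, rp$rp_down),
    p_value = pmin(est$p_up, est$p_down),
    q_value = pmin(pmax(ifelse(up_wins, est$pfp_up, est$pfp_down), 0), 1),
    pfp_raw = ifelse(up_wins, est$pfp_up, est$pfp_down),
    direction = ifelse(tie, 0L, ifelse(up_wins, 1L, -1L)),
    tie = tie,
    row.names = rownames(m), stringsAsFactors = FALSE
  )
  list(table = table, ratios = ratios, estimates = est, rp = rp)
}
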