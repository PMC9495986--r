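# Design-matrix construction. Group means are parameterized without an
# intercept so contrast vectors are simple +1/-1 indicators; batch, pairing
# and extra covariates enter as reference-dropped indicator blocks.

#' Expand design-label shorthand
#'
#' Grammar: a comma-separated list of tokens, each either a literal label or
#' a run-length term `k*label` (k a positive integer), expanded left to
#' right. Labels are applied to samples order-wise, so label i belongs to
#' sample i of the matrix column order.
#'
#' @param spec character scalar, e.g. `"2*control,2*treated"`.
#' @return character vector of labels.
#' @examples
#' parse_design_labels("2*control,2*treated")
#' @export
parse_design_labels <- function(spec) {
  if (!is.character(spec) || length(spec) != 1 || !nzchar(trimws(spec))) {
    stop("empty design label specification", call. = FALSE)
  }
  tokens <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
  if (any(!nzchar(tokens))) {
    stop("empty token in design label specification: '", spec, "'",
         call. = FALSE)
  }
  out <- lapply(tokens, function(tok) {
    if (grepl("*", tok, fixed = TRUE)) {
      parts <- strsplit(tok, "*", fixed = TRUE)[[1]]
      if (length(parts) != 2) {
        stop("malformed shorthand token '", tok, "' (expected k*label)",
             call. = FALSE)
      }
      k <- suppressWarnings(as.numeric(parts[1]))
      label <- trimws(parts[2])
      if (is.na(k) || k != round(k) || k <= 0) {
        stop("multiplier in '", tok, "' must be a positive integer",
             call. = FALSE)
      }
      if (!nzchar(label)) stop("empty label in '", tok, "'", call. = FALSE)
      rep(label, k)
    } else {
      tok
    }
  })
  check_labels(unlist(out), "design")
}

# reference-dropped indicator block for one categorical covariate;
# levels sorted lexicographically, reference = first level.
indicator_block <- function(labels, prefix) {
  levels <- sort(unique(labels))
  if (length(levels) < 2) return(NULL)
  block <- vapply(levels[-1], function(lv) as.numeric(labels == lv),
                  numeric(length(labels)))
  colnames(block) <- paste0(prefix, levels[-1])
  block
}

#' Build the model matrix for a design
#'
#' Columns are, in order: one group-mean indicator per group level (levels
#' sorted lexicographically, no intercept), then batch indicators (reference
#' batch dropped), then pairing indicators (reference pair dropped), then
#' extra covariate indicators. A rank-deficient result (e.g. batch confounded
#' with group) is a hard error naming the collinear columns.
#'
#' @param design a [design_spec()].
#' @param sample_names sample names in matrix column order.
#' @return numeric model matrix of class `model_matrix` with attribute
#'   `group_levels` naming the group-mean columns.
#' @export
build_design_matrix <- function(design, sample_names) {
  stopifnot(inherits(design, "design_spec"))
  n <- length(sample_names)
  if (length(design$group_labels) != n) {
    stop("design labels ", length(design$group_labels),
         " sample(s) but there are ", n, " samples", call. = FALSE)
  }
  levels <- sort(unique(design$group_labels))
  mm <- vapply(levels, function(lv) as.numeric(design$group_labels == lv),
               numeric(n))
  colnames(mm) <- levels
  for (block in list(
    if (!is.null(design$batch_labels))
      indicator_block(design$batch_labels, "batch"),
    if (!is.null(design$pairing_labels))
      indicator_block(design$pairing_labels, "pair"),
    if (!is.null(design$extra_covariates)) {
      do.call(cbind, Map(function(v, nm) indicator_block(v, paste0(nm, "_")),
                         design$extra_covariates,
                         names(design$extra_covariates)))
    }
  )) {
    if (!is.null(block)) mm <- cbind(mm, block)
  }
  rownames(mm) <- sample_names
  qrd <- qr(mm)
  if (qrd$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrd$pivot[(qrd$rank + 1):ncol(mm)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  structure(mm, group_levels = levels, class = c("model_matrix", "matrix"))
}

#' Contrast vector for a (test, reference) pair
#'
#' +1 at the test group column, -1 at the reference group column, 0
#' elsewhere, so that `t(contrast) %*% coefficients` is the log2 fold change
#' test minus reference.
#'
#' @param contrast length-2 character vector `c(test, reference)`.
#' @param mm model matrix from [build_design_matrix()].
#' @return numeric vector, one element per model-matrix column.
#' @export
contrast_vector <- function(contrast, mm) {
  levels <- attr(mm, "group_levels")
  contrast <- as.character(contrast)
  if (length(contrast) != 2) {
    stop("contrast must be (test, reference)", call. = FALSE)
  }
  if (contrast[1] == contrast[2]) {
    stop("contrast compares a level with itself: ", contrast[1], call. = FALSE)
  }
  missing <- setdiff(contrast, levels)
  if (length(missing)) {
    stop("unknown group level(s) in contrast: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- numeric(ncol(mm))
  names(v) <- colnames(mm)
  v[contrast[1]] <- 1
  v[contrast[2]] <- -1
  v
}

#' Sample correspondence table
#'
#' Samples are relabeled order-wise by their group level (`level_1`,
#' `level_2`, ...); the correspondence between new labels and original
#' sample names is always emitted so the order-wise labeling can be checked
#' by eye.
#'
#' @param sample_names original sample names.
#' @param group_labels group label per sample.
#' @return data.frame with `original_name`, `group` and `new_label`.
#' @export
sample_correspondence <- function(sample_names, group_labels) {
  stopifnot(length(sample_names) == length(group_labels))
  idx <- stats::ave(seq_along(group_labels), group_labels, FUN = seq_along)
  data.frame(
    original_name = sample_names,
    group = group_labels,
    new_label = paste0(group_labels, "_", idx),
    stringsAsFactors = FALSE
  )
}
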