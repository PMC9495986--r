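# Analysis options are the replay contract: one flat, typed key = value text
# document records every analysis choice, so that sharing the options file
# plus the input matrix deterministically reproduces a run.

label_re <- "^[A-Za-z0-9_.]+$"

check_labels <- function(x, what) {
  if (any(!grepl(label_re, x))) {
    bad <- unique(x[!grepl(label_re, x)])
    stop(what, " labels must match ", label_re, " (no '-', ',' or '*'): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' Construct an experimental design specification
#'
#' Group labels name the level of the variable of interest for each sample,
#' order-wise (label i applies to sample i of the matrix column order).
#' Contrasts are ordered (test, reference) level pairs. Batch and pairing
#' labels, when given, must also be one per sample.
#'
#' @param group_labels character vector, one level per sample.
#' @param contrasts list of length-2 character vectors `c(test, reference)`.
#' @param batch_labels optional character vector, one per sample.
#' @param pairing_labels optional character vector, one per sample.
#' @param extra_covariates optional named list of per-sample label vectors.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(group_labels, contrasts, batch_labels = NULL,
                        pairing_labels = NULL, extra_covariates = NULL) {
  group_labels <- check_labels(as.character(group_labels), "group")
  if (!length(group_labels)) stop("empty design", call. = FALSE)
  if (!is.list(contrasts) || !length(contrasts)) {
    stop("contrasts must be a non-empty list of (test, reference) pairs",
         call. = FALSE)
  }
  contrasts <- lapply(contrasts, function(ct) {
    ct <- as.character(ct)
    if (length(ct) != 2) {
      stop("each contrast must have exactly two levels", call. = FALSE)
    }
    if (ct[1] == ct[2]) {
      stop("contrast compares a level with itself: ", ct[1], call. = FALSE)
    }
    missing <- setdiff(ct, group_labels)
    if (length(missing)) {
      stop("contrast level(s) not present in design: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    ct
  })
  n <- length(group_labels)
  for (nm in c("batch_labels", "pairing_labels")) {
    v <- get(nm)
    if (!is.null(v)) {
      v <- check_labels(as.character(v), sub("_labels", "", nm))
      if (length(v) != n) {
        stop(nm, " length (", length(v), ") != sample count (", n, ")",
             call. = FALSE)
      }
      assign(nm, v)
    }
  }
  if (!is.null(extra_covariates)) {
    stopifnot(is.list(extra_covariates), !is.null(names(extra_covariates)))
    extra_covariates <- lapply(extra_covariates, function(v) {
      v <- check_labels(as.character(v), "covariate")
      if (length(v) != n) stop("covariate length mismatch", call. = FALSE)
      v
    })
  }
  structure(
    list(group_labels = group_labels, contrasts = contrasts,
         batch_labels = batch_labels, pairing_labels = pairing_labels,
         extra_covariates = extra_covariates),
    class = "design_spec"
  )
}

#' Construct a full set of analysis options
#'
#' Defaults follow the documented pipeline conventions: kappa = 0.8,
#' theta_f = 0.5, alpha = 0.05, 1000 permutations, both test arms on.
#' `theta_e = NA` means "decide at run time": the negative-control estimate
#' from preparation when available, else the 20th percentile of expression.
#'
#' @param design a [design_spec()].
#' @param kappa minimum group-wise presence fraction in `[0, 1]`.
#' @param theta_e log2 expression threshold, or `NA` for automatic.
#' @param theta_f log2 fold-change threshold (>= 0) used by DEG marking.
#' @param alpha significance level on the q-value / PFP scale.
#' @param run_limma_like run the moderated-t arm.
#' @param run_rankprod run the rank-product arm.
#' @param renormalize quantile-normalize the input matrix before analysis.
#' @param input_kind `"microarray"` (log2 matrix) or `"counts"`.
#' @param rng_seed integer seed driving every stochastic stage.
#' @param permutations permutation count for the rank-product PFP (>= 100).
#' @return object of class `analysis_options`.
#' @export
analysis_options <- function(design, kappa = 0.8, theta_e = NA_real_,
                             theta_f = 0.5, alpha = 0.05,
                             run_limma_like = TRUE, run_rankprod = TRUE,
                             renormalize = FALSE,
                             input_kind = c("microarray", "counts"),
                             rng_seed = 1L, permutations = 1000L) {
  stopifnot(inherits(design, "design_spec"))
  input_kind <- match.arg(input_kind)
  check_range <- function(x, lo, hi, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
      stop("option '", name, "' out of range [", lo, ", ", hi, "]: ", x,
           call. = FALSE)
    }
    as.numeric(x)
  }
  kappa <- check_range(kappa, 0, 1, "filter.kappa")
  theta_f <- check_range(theta_f, 0, Inf, "filter.theta_f")
  alpha <- check_range(alpha, 0, 1, "alpha")
  if (!is.na(theta_e)) theta_e <- as.numeric(theta_e)
  if (!isTRUE(run_limma_like) && !isTRUE(run_rankprod)) {
    stop("at least one of the limma-like and rank-product arms must run",
         call. = FALSE)
  }
  rng_seed <- as.integer(rng_seed)
  if (is.na(rng_seed)) stop("seed must be an integer", call. = FALSE)
  permutations <- as.integer(permutations)
  if (is.na(permutations) || permutations < 100) {
    stop("option 'permutations' must be an integer >= 100", call. = FALSE)
  }
  structure(
    list(design = design, kappa = kappa, theta_e = theta_e,
         theta_f = theta_f, alpha = alpha,
         run_limma_like = isTRUE(run_limma_like),
         run_rankprod = isTRUE(run_rankprod),
         renormalize = isTRUE(renormalize), input_kind = input_kind,
         rng_seed = rng_seed, permutations = permutations),
    class = "analysis_options"
  )
}

options_schema <- c(
  "design.groups", "design.contrasts", "design.batches", "design.pairings",
  "filter.kappa", "filter.theta_e", "filter.theta_f", "alpha", "methods",
  "input_kind", "seed", "permutations", "renormalize"
)
options_mandatory <- c("design.groups", "design.contrasts", "methods",
                       "input_kind", "seed")

#' Read an options file
#'
#' Strict parser for the flat `key = value` schema; `#` starts a comment.
#' Unknown keys, missing mandatory keys and out-of-range values are hard
#' errors naming the key. `read_options(write_options(x)) == x` for every
#' valid `x`.
#'
#' @param path path to the options file.
#' @param n_samples optional sample count to validate label lengths against.
#' @return an [analysis_options()] object.
#' @export
read_options <- function(path, n_samples = NULL) {
  if (!file.exists(path)) stop("options file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_.]+)[[:space:]]*=[[:space:]]*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) == 0]
  if (length(bad)) {
    stop("malformed options line(s): ", paste(bad, collapse = " | "),
         call. = FALSE)
  }
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  unknown <- setdiff(keys, options_schema)
  if (length(unknown)) {
    stop("unknown options key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop("duplicated options key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(options_mandatory, keys)
  if (length(missing)) {
    stop("missing mandatory options key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  opt <- stats::setNames(as.list(vals), keys)
  get_num <- function(key, default) {
    if (is.null(opt[[key]])) return(default)
    x <- suppressWarnings(as.numeric(opt[[key]]))
    if (is.na(x)) stop("option '", key, "' is not a number: ", opt[[key]],
                       call. = FALSE)
    x
  }
  get_bool <- function(key, default) {
    if (is.null(opt[[key]])) return(default)
    v <- tolower(opt[[key]])
    if (!v %in% c("true", "false")) {
      stop("option '", key, "' must be true or false: ", opt[[key]],
           call. = FALSE)
    }
    v == "true"
  }
  split_list <- function(x) trimws(strsplit(x, ",", fixed = TRUE)[[1]])

  groups <- parse_design_labels(opt[["design.groups"]])
  contrasts <- lapply(split_list(opt[["design.contrasts"]]), function(s) {
    parts <- strsplit(s, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2 || any(!nzchar(parts))) {
      stop("option 'design.contrasts': each contrast must be 'test-reference', got '",
           s, "'", call. = FALSE)
    }
    parts
  })
  batches <- if (!is.null(opt[["design.batches"]]) && nzchar(opt[["design.batches"]])) {
    parse_design_labels(opt[["design.batches"]])
  }
  pairings <- if (!is.null(opt[["design.pairings"]]) && nzchar(opt[["design.pairings"]])) {
    parse_design_labels(opt[["design.pairings"]])
  }
  if (!is.null(n_samples) && length(groups) != n_samples) {
    stop("design.groups labels ", length(groups),
         " sample(s) but the matrix has ", n_samples, call. = FALSE)
  }
  design <- design_spec(groups, contrasts, batches, pairings)

  methods <- split_list(opt[["methods"]])
  bad_m <- setdiff(methods, c("limma_like", "rankprod"))
  if (length(bad_m)) {
    stop("option 'methods': unknown method(s): ", paste(bad_m, collapse = ", "),
         call. = FALSE)
  }
  input_kind <- opt[["input_kind"]]
  if (!input_kind %in% c("microarray", "counts")) {
    stop("option 'input_kind' must be microarray or counts: ", input_kind,
         call. = FALSE)
  }
  theta_e <- if (is.null(opt[["filter.theta_e"]]) ||
                 tolower(opt[["filter.theta_e"]]) == "auto") {
    NA_real_
  } else {
    get_num("filter.theta_e", NA_real_)
  }
  seed <- get_num("seed", NA_real_)
  if (is.na(seed) || seed != round(seed)) {
    stop("option 'seed' must be an integer", call. = FALSE)
  }
  analysis_options(
    design = design,
    kappa = get_num("filter.kappa", 0.8),
    theta_e = theta_e,
    theta_f = get_num("filter.theta_f", 0.5),
    alpha = get_num("alpha", 0.05),
    run_limma_like = "limma_like" %in% methods,
    run_rankprod = "rankprod" %in% methods,
    renormalize = get_bool("renormalize", FALSE),
    input_kind = input_kind,
    rng_seed = as.integer(seed),
    permutations = {
      p <- get_num("permutations", 1000)
      if (p != round(p)) stop("option 'permutations' must be an integer",
                              call. = FALSE)
      as.integer(p)
    }
  )
}

serialize_labels <- function(x) paste(x, collapse = ",")

#' Write an options file
#'
#' Emits every schema key in a fixed order with full numeric precision, so
#' the file is byte-stable and round-trips through [read_options()].
#'
#' @param opts an [analysis_options()] object.
#' @param path output path.
#' @param comments include explanatory comments (as `initialize` does).
#' @return `path`, invisibly.
#' @export
write_options <- function(opts, path, comments = FALSE) {
  stopifnot(inherits(opts, "analysis_options"))
  d <- opts$design
  methods <- c(if (opts$run_limma_like) "limma_like",
               if (opts$run_rankprod) "rankprod")
  line <- function(key, value, comment = NULL) {
    c(if (comments && !is.null(comment)) paste0("# ", comment),
      paste0(key, " = ", value))
  }
  out <- c(
    if (comments) c("# teaflow analysis options file",
                    "# flat key = value document; '#' starts a comment", ""),
    line("design.groups", serialize_labels(d$group_labels),
         "one level per sample, order-wise; shorthand k*label allowed"),
    line("design.contrasts",
         paste(vapply(d$contrasts, function(ct) paste(ct, collapse = "-"),
                      character(1)), collapse = ","),
         "comma-separated test-reference pairs"),
    if (!is.null(d$batch_labels))
      line("design.batches", serialize_labels(d$batch_labels),
           "optional batch label per sample"),
    if (!is.null(d$pairing_labels))
      line("design.pairings", serialize_labels(d$pairing_labels),
           "optional pairing label per sample"),
    line("filter.kappa", format_full(opts$kappa),
         "minimum group-wise presence fraction in [0, 1]"),
    line("filter.theta_e",
         if (is.na(opts$theta_e)) "auto" else format_full(opts$theta_e),
         "log2 expression threshold; 'auto' = control estimate or 20th percentile"),
    line("filter.theta_f", format_full(opts$theta_f),
         "log2 fold-change threshold for DEG marking"),
    line("alpha", format_full(opts$alpha), "q-value / PFP significance level"),
    line("methods", paste(methods, collapse = ","),
         "subset of limma_like, rankprod"),
    line("input_kind", opts$input_kind, "microarray or counts"),
    line("seed", format_full(opts$rng_seed), "seed for all stochastic stages"),
    line("permutations", format_full(opts$permutations),
         "rank-product permutation count (>= 100)"),
    line("renormalize", if (opts$renormalize) "true" else "false",
         "quantile-normalize the input matrix before analysis")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con = con, sep = "\n")
  invisible(path)
}
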