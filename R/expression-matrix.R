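# Expression matrices are plain numeric matrices on the log2 scale with
# rownames = entry identifiers and colnames = sample names. This mirrors the
# container type used throughout the microarray analysis ecosystem, so every
# matrix operation in base R applies directly.

#' Validate an expression matrix
#'
#' Checks the container invariants: a numeric matrix with unique, non-empty
#' row (entry) and column (sample) identifiers and all values finite. Called
#' by every reader and pipeline stage; exported because downstream code that
#' builds matrices by hand can use it as a guard.
#'
#' @param m numeric matrix, entries x samples, log2 scale.
#' @param what label used in error messages.
#' @return `m`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  ids <- rownames(m)
  samples <- colnames(m)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop(what, ": entry ids must be present and non-empty", call. = FALSE)
  }
  if (is.null(samples) || anyNA(samples) || any(!nzchar(samples))) {
    stop(what, ": sample names must be present and non-empty", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(what, ": duplicated entry ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    dup <- unique(samples[duplicated(samples)])
    stop(what, ": duplicated sample names: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(what, ": non-finite value at entry '", ids[bad[1]], "', sample '",
         samples[bad[2]], "'", call. = FALSE)
  }
  invisible(m)
}

# Full-precision, locale-independent number formatting used by all writers.
# %.17g guarantees that read(write(x)) reproduces the double exactly.
format_full <- function(x) {
  sprintf("%.17g", x)
}

#' Read an expression matrix from CSV
#'
#' The file layout is: header row with the entry-id column name followed by
#' sample names; one row per entry, first field the entry id, remaining
#' fields log2 expression values. Row and column order are preserved.
#'
#' @param path path to a CSV file.
#' @return numeric matrix with entry ids as rownames, samples as colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         stringsAsFactors = FALSE)
  if (ncol(raw) < 2) {
    stop("expression CSV needs an id column plus at least one sample: ", path,
         call. = FALSE)
  }
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicated entry ids in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  samples <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric cell in ", path, " at row ", bad[1], " (entry '",
         ids[bad[1]], "'), column '", samples[bad[2]], "': '",
         vals[bad[1], bad[2]], "'", call. = FALSE)
  }
  m <- num
  dimnames(m) <- list(ids, samples)
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix to CSV
#'
#' Deterministic output: fixed field order (ids first, then samples in matrix
#' order), `%.17g` numeric formatting, `.` decimal point, `\n` line endings.
#' Two writes of the same matrix are byte-identical.
#'
#' @param m valid expression matrix.
#' @param path output path.
#' @param id_column header name for the id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_column = "entry_id") {
  validate_expression_matrix(m)
  ids <- rownames(m)
  if (any(grepl("[,\"\n]", c(ids, colnames(m))))) {
    stop("entry ids and sample names must not contain commas, quotes or newlines",
         call. = FALSE)
  }
  header <- paste(c(id_column, colnames(m)), collapse = ",")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(ids[i], format_full(m[i, ])), collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con = con, sep = "\n")
  invisible(path)
}

#' Read an annotation table
#'
#' Expected columns: `entry_id, gene_symbol, gene_name, source_name,
#' source_version`. Missing annotations are empty strings.
#'
#' @param path path to the annotation CSV.
#' @return data.frame with the five columns above; `entry_id` unique.
#' @export
read_annotation <- function(path) {
  a <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                       stringsAsFactors = FALSE)
  validate_annotation(a)
}

annotation_columns <- c("gene_symbol", "gene_name", "source_name", "source_version")

validate_annotation <- function(a) {
  need <- c("entry_id", annotation_columns)
  missing <- setdiff(need, colnames(a))
  if (length(missing)) {
    stop("annotation table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(a$entry_id)) {
    dup <- unique(a$entry_id[duplicated(a$entry_id)])
    stop("duplicated entry ids in annotation: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) a[[col]][is.na(a[[col]])] <- ""
  a[, need, drop = FALSE]
}

#' Join annotations onto a table or expression matrix
#'
#' Left join on entry id: every input row is kept in its original order,
#' unmatched entries receive empty annotation fields, numeric columns are
#' untouched. An expression matrix is returned as a data.frame (annotation
#' fields are character). Re-annotating with the same source overwrites the
#' annotation columns, so the operation is idempotent.
#'
#' @param x DEG table (data.frame with an `entry_id` column) or expression
#'   matrix.
#' @param annotation data.frame as returned by [read_annotation()].
#' @return same rows as `x` with `gene_symbol`, `gene_name`, `source_name`
#'   and `source_version` columns appended.
#' @export
annotate_table <- function(x, annotation) {
  annotation <- validate_annotation(annotation)
  if (is.matrix(x)) {
    validate_expression_matrix(x)
    df <- data.frame(entry_id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE, row.names = NULL)
  } else {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    if (!"entry_id" %in% colnames(df)) {
      stop("table has no 'entry_id' column", call. = FALSE)
    }
  }
  df <- df[, setdiff(colnames(df), annotation_columns), drop = FALSE]
  idx <- match(df$entry_id, annotation$entry_id)
  for (col in annotation_columns) {
    v <- annotation[[col]][idx]
    v[is.na(v)] <- ""
    df[[col]] <- v
  }
  df
}
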