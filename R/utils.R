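# Shared internal helpers.

# Deterministic CSV writer for data.frames: numeric columns at full %.17g
# precision, "\n" line endings, no row names. Used for DEG tables, QC data
# files and correspondence tables so re-runs are byte-identical.
write_table_csv <- function(df, path) {
  out <- df
  for (col in colnames(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- format_full(out[[col]])
    } else {
      out[[col]] <- as.character(out[[col]])
    }
  }
  if (any(vapply(out, function(v) any(grepl("[,\"\n]", v)), logical(1)))) {
    stop("table fields must not contain commas, quotes or newlines",
         call. = FALSE)
  }
  lines <- c(paste(colnames(out), collapse = ","),
             do.call(paste, c(unname(out), sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
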