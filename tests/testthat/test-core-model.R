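test_that("expression CSV round-trips to value identity and is byte-deterministic", {
  m <- rand_matrix(10, 4, seed = 101)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_expression_matrix(m, f1)
  write_expression_matrix(m, f2)
  expect_identical(file_bytes(f1), file_bytes(f2))
  back <- read_expression_matrix(f1)
  expect_identical(back, m)

  one <- matrix(0, 1, 1, dimnames = list("g1", "s1"))
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_expression_matrix(one, f3)
  expect_length(readLines(f3), 2L)  # header + exactly one data row
  expect_identical(read_expression_matrix(f3), one)
})

test_that("expression CSV reader rejects duplicates and non-numeric cells with coordinates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("entry_id,s1,s2", "gA,1,2", "gA,3,4"), f)
  expect_error(read_expression_matrix(f), "gA")

  writeLines(c("entry_id,s1,s2", "g1,1,2", "g2,oops,4"), f)
  err <- tryCatch(read_expression_matrix(f), error = conditionMessage)
  expect_match(err, "row 2")
  expect_match(err, "s1")
  expect_match(err, "oops")
})

test_that("options file defaults, range checks and strict schema", {
  f <- withr::local_tempfile()
  writeLines(c(
    "design.groups = 2*control,2*treated",
    "design.contrasts = treated-control",
    "methods = limma_like,rankprod",
    "input_kind = microarray",
    "seed = 7"
  ), f)
  opts <- read_options(f)
  expect_equal(opts$theta_f, 0.5)
  expect_equal(opts$alpha, 0.05)
  expect_equal(opts$kappa, 0.8)
  expect_equal(opts$permutations, 1000L)
  expect_false(opts$renormalize)
  expect_true(is.na(opts$theta_e))
  expect_identical(opts$design$group_labels,
                   c("control", "control", "treated", "treated"))

  writeLines(c(readLines(f), "filter.kappa = 1.5"), f)
  expect_error(read_options(f), "filter.kappa")
  writeLines(c("design.groups = a,b", "design.contrasts = a-b",
               "methods = limma_like", "input_kind = microarray",
               "seed = 1", "bogus.key = 3"), f)
  expect_error(read_options(f), "bogus.key")
  writeLines(c("design.groups = a,b", "design.contrasts = a-b"), f)
  expect_error(read_options(f), "methods")
})

test_that("random valid options round-trip through write/read", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    groups <- rep(c("ctrl", "trt"), each = n)
    opts <- analysis_options(
      design_spec(groups, list(c("trt", "ctrl")),
                  batch_labels = if (runif(1) < 0.5)
                    rep(c("b1", "b2"), n) else NULL),
      kappa = round(runif(1), 3),
      theta_e = if (runif(1) < 0.3) NA_real_ else round(rnorm(1, 5), 4),
      theta_f = round(runif(1, 0, 2), 3),
      alpha = round(runif(1, 0.01, 0.2), 4),
      run_limma_like = TRUE,
      run_rankprod = runif(1) < 0.5,
      renormalize = runif(1) < 0.5,
      input_kind = sample(c("microarray", "counts"), 1),
      rng_seed = sample.int(1e6, 1),
      permutations = sample(100:2000, 1)
    )
    f <- withr::local_tempfile()
    write_options(opts, f)
    expect_equal(read_options(f), opts)
  }
})

test_that("annotation join keeps rows, order and numeric columns; counts matched ids", {
  ann <- data.frame(entry_id = "g1", gene_symbol = "ABC1",
                    gene_name = "abc one", source_name = "synthetic",
                    source_version = "1", stringsAsFactors = FALSE)
  tab <- data.frame(entry_id = c("g1", "g2"), log2_fc = c(1.5, -0.2),
                    stringsAsFactors = FALSE)
  out <- annotate_table(tab, ann)
  expect_identical(out$entry_id, tab$entry_id)
  expect_identical(out$log2_fc, tab$log2_fc)
  expect_identical(out$gene_symbol, c("ABC1", ""))

  empty <- ann[0, ]
  out2 <- annotate_table(tab, empty)
  expect_identical(out2$entry_id, tab$entry_id)
  expect_true(all(out2$gene_symbol == ""))

  # counting oracle: 100 ids, 60 annotated -> exactly 60 non-empty symbols
  set.seed(303)
  ids <- sprintf("id%03d", 1:100)
  covered <- sample(ids, 60)
  ann3 <- data.frame(entry_id = covered,
                     gene_symbol = paste0("SYM_", covered),
                     gene_name = "", source_name = "synthetic",
                     source_version = "0", stringsAsFactors = FALSE)
  tab3 <- data.frame(entry_id = ids, stat = rnorm(100),
                     stringsAsFactors = FALSE)
  out3 <- annotate_table(tab3, ann3)
  expect_equal(sum(nzchar(out3$gene_symbol)), 60L)
  expect_identical(out3$entry_id, ids)

  expect_error(annotate_table(tab, rbind(ann, ann)), "duplicat")
})

test_that("expression matrices are annotated as data frames with samples intact", {
  m <- rand_matrix(5, 3, seed = 404)
  ann <- data.frame(entry_id = rownames(m)[1:2],
                    gene_symbol = c("A", "B"), gene_name = c("a", "b"),
                    source_name = "synthetic", source_version = "1",
                    stringsAsFactors = FALSE)
  out <- annotate_table(m, ann)
  expect_equal(nrow(out), nrow(m))
  expect_identical(out$s01, unname(m[, "s01"]))
  expect_identical(out$gene_symbol, c("A", "B", "", "", ""))
})
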