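test_that("write then read restores the flat-file example exactly", {
  feats <- table1_features()
  path <- withr::local_tempfile(fileext = ".tsv")
  n <- write_mutations_table(feats, path)
  expect_equal(n, 6L) # five features, one spread over two rows
  back <- read_mutations_table(path)
  expect_equal(back, feats)
})

test_that("rows sharing a feature accession merge into one multi-segment feature", {
  feats <- table1_features()
  collapsed <- ppimutr:::collapse_features(feats)
  expect_equal(nrow(collapsed), 5)
  two <- collapsed[collapsed$feature_ac == "EBI-4370347", ]
  expect_equal(two$n_segments, 2L)
  expect_equal(two$segments[[1]]$start, c(31L, 60L))
})

test_that("a header-only file reads as an empty table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(ppimutr:::MUT_TSV_COLUMNS, collapse = "\t"), path)
  expect_equal(nrow(read_mutations_table(path)), 0)
})

test_that("structural problems raise read errors naming the rows", {
  feats <- table1_features()
  path <- withr::local_tempfile(fileext = ".tsv")

  out <- tibble::as_tibble(feats)
  out$feature_range <- paste0(out$start, "-", out$end)
  dropped <- out[, setdiff(ppimutr:::MUT_TSV_COLUMNS, "protein_ac")]
  readr::write_tsv(dropped, path, progress = FALSE)
  expect_error(read_mutations_table(path), "protein_ac")

  bad <- out[, ppimutr:::MUT_TSV_COLUMNS]
  bad$feature_range[2] <- "x-114"
  readr::write_tsv(bad, path, progress = FALSE)
  expect_error(read_mutations_table(path), "row.*2")

  conflicting <- feats
  conflicting$protein_ac[4] <- "P99999" # second row of EBI-4370347
  write_mutations_table(conflicting, path)
  expect_error(read_mutations_table(path), "EBI-4370347")
})

test_that("en-dash ranges are accepted on read, hyphen is written", {
  feats <- table1_features()[1, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutations_table(feats, path)
  lines <- readLines(path)
  expect_match(lines[2], "725-725")
  lines[2] <- sub("725-725", "725–725", lines[2])
  writeLines(lines, path)
  back <- read_mutations_table(path)
  expect_equal(back$start, 725L)
  expect_equal(back$end, 725L)
})

test_that("read and write round-trip a generated thousand-feature dataset", {
  spec <- fixture_spec(
    effects = c(
      disrupting = 400, decreasing = 250, increasing = 120, causing = 30,
      no_effect = 120, undefined = 80
    ),
    organisms = tibble::tibble(
      taxid = "9606", annotations = 1000L, changes = 700L, proteins = 100L,
      interactions = 500L, publications = 50L
    ),
    consistency = list(n_multi_groups = 300, n_mild = 10, n_conflict = 5),
    indels = list(n_deletions = 10, n_insertions = 10),
    n_multi_segment = 10
  )
  fx <- generate_fixture(spec, seed = 11)
  tbl <- fx$main$mutations
  expect_equal(length(unique(tbl$feature_ac)), 1000)
  path <- withr::local_tempfile(fileext = ".tsv")
  n <- write_mutations_table(tbl, path)
  expect_equal(n, nrow(tbl)) # one row per contiguous segment
  expect_equal(read_mutations_table(path), tbl)
})

test_that("validation reports sequence disagreements as issues, not errors", {
  feats <- table1_features(faithful = FALSE)
  proteome <- table1_proteome(faithful = FALSE)
  expect_equal(nrow(validate_dataset(feats, proteome)), 0)

  # original R at 725 where the protein has K
  broken <- proteome
  substr(broken[["P10001"]], 725, 725) <- "K"
  issues <- validate_dataset(feats, broken)
  expect_equal(issues$code, "sequence-mismatch")
  expect_equal(issues$severity, "error")

  # feature on an absent accession is a warning, never a stop
  issues <- validate_dataset(feats, proteome[-1])
  expect_equal(unique(issues$code), "protein-unavailable")
  expect_equal(unique(issues$severity), "warning")

  # range wider than the stored original
  off <- mk_feature("EBI-X2", "mutation(MI:0118)",
    protein = "P10001",
    start = 725L, end = 726L, original = "R", resulting = "E",
    label = "p.Arg725Glu"
  )
  issues <- validate_dataset(off, proteome)
  expect_true("range-length-mismatch" %in% issues$code)

  # unknown effect vocabulary terms are flagged
  odd <- mk_feature("EBI-X3", "mutation exploding(MI:4242)",
    protein = "P10001",
    start = 725L, original = "R", resulting = "E"
  )
  issues <- validate_dataset(odd, proteome)
  expect_true("unknown-effect-term" %in% issues$code)
})

test_that("a freshly generated fixture validates with zero error issues", {
  fx <- mini_fx()
  issues <- validate_dataset(fx$main$mutations, fx$main$proteome)
  expect_equal(sum(issues$severity == "error"), 0)
})

test_that("proteome FASTA round-trips through Biostrings", {
  proteome <- table1_proteome()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(proteome, path)
  expect_equal(read_proteome_fasta(path), proteome)
})
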