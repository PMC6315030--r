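test_that("single, contiguous and bracketed substitution labels parse", {
  p <- parse_hgvs_label("p.Arg725Glu")
  expect_equal(p$variant_form, "single")
  expect_equal(
    p$segments[, 1:4],
    tibble::tibble(start = 725L, end = 725L, original = "R", resulting = "E")
  )

  p <- parse_hgvs_label("p.Cys_Ser215-216Ala_Ala")
  expect_equal(p$variant_form, "contiguous_multi")
  expect_equal(
    p$segments[, 1:4],
    tibble::tibble(start = 215L, end = 216L, original = "CS", resulting = "AA")
  )

  p <- parse_hgvs_label("p.[Asn31His;Ala60Val]")
  expect_equal(p$variant_form, "multi_bracket")
  expect_equal(p$segments$start, c(31L, 60L))
  expect_equal(p$segments$original, c("N", "A"))
  expect_equal(p$segments$resulting, c("H", "V"))
})

test_that("deletion and insertion labels parse with empty counterpart strings", {
  d <- parse_hgvs_label("p.Arg12del")$segments
  expect_equal(d$original, "R")
  expect_equal(d$resulting, "")
  d2 <- parse_hgvs_label("p.Cys12_Ser13del")$segments
  expect_equal(d2$original, "CS")
  expect_equal(c(d2$start, d2$end), c(12L, 13L))
  i <- parse_hgvs_label("p.Lys2_Gly3insGlnSer")$segments
  expect_equal(i$original, "")
  expect_equal(i$resulting, "QS")
  expect_equal(c(i$flank_left, i$flank_right), c("K", "G"))
})

test_that("malformed labels raise informative strict-mode errors", {
  expect_error(parse_hgvs_label("p.Xyz12Ala"), "unknown residue")
  expect_error(parse_hgvs_label("Arg725Glu"), "must start with 'p\\.'")
  expect_error(parse_hgvs_label("p.Arg12_Glu15ins"), "syntax|adjacent")
  expect_error(parse_hgvs_label("p.Cys_Ser215-217Ala_Ala"), "range length")
  expect_error(parse_hgvs_label("p.ArgXXGlu"), "syntax")
})

test_that("formatting emits the canonical forms", {
  expect_equal(
    format_hgvs_label(data.frame(start = 2, end = 2, original = "T", resulting = "A")),
    "p.Thr2Ala"
  )
  expect_equal(
    format_hgvs_label(data.frame(start = 114, end = 114, original = "I", resulting = "G")),
    "p.Ile114Gly"
  )
  expect_error(format_hgvs_label(data.frame()), "empty")
  # insertions cannot be formatted without flank residues
  expect_error(
    format_hgvs_label(data.frame(start = 2, end = 3, original = "", resulting = "Q")),
    "flank"
  )
})

test_that("parse and format round-trip on the flat-file example labels", {
  labels <- c(
    "p.Arg725Glu", "p.Ile114Gly", "p.[Asn31His;Ala60Val]",
    "p.Thr2Ala", "p.Cys_Ser215-216Ala_Ala"
  )
  for (lab in labels) {
    expect_equal(format_hgvs_label(parse_hgvs_label(lab)$segments), lab)
  }
})

test_that("parse and format round-trip on randomized segment lists", {
  set.seed(7)
  aa <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  for (rep in 1:150) {
    n_seg <- sample(1:3, 1)
    starts <- sort(sample(1:900, n_seg)) + c(0L, 10L, 20L)[seq_len(n_seg)]
    segs <- do.call(rbind, lapply(seq_len(n_seg), function(i) {
      span <- if (n_seg == 1) sample(1:3, 1) else 1L
      data.frame(
        start = starts[i], end = starts[i] + span - 1L,
        original = paste(sample(aa, span, replace = TRUE), collapse = ""),
        resulting = paste(sample(aa, span, replace = TRUE), collapse = "")
      )
    }))
    label <- format_hgvs_label(segs)
    back <- parse_hgvs_label(label)$segments
    expect_equal(back$start, segs$start)
    expect_equal(back$end, segs$end)
    expect_equal(back$original, segs$original)
    expect_equal(back$resulting, segs$resulting)
    expect_equal(format_hgvs_label(back), label)
  }
})

test_that("lenient mode warns exactly when strict mode would raise", {
  clean <- parse_hgvs_label("p.Arg725Glu", strict = FALSE)
  expect_length(clean$warnings, 0)

  cases <- c(" p.Arg725Glu ", "p.arg725glu", "p.Cys_Ser215–216Ala_Ala")
  for (lab in cases) {
    expect_error(parse_hgvs_label(lab, strict = TRUE))
    lenient <- parse_hgvs_label(lab, strict = FALSE)
    expect_gt(length(lenient$warnings), 0)
    expect_gt(nrow(lenient$segments), 0)
  }
  # unrepairable: best effort returns no segments but never raises
  broken <- parse_hgvs_label("p.Foo12Ala", strict = FALSE)
  expect_equal(nrow(broken$segments), 0)
  expect_gt(length(broken$warnings), 0)
})

test_that("label/column disagreements are flagged as issues, not resolved", {
  clean <- table1_features(faithful = FALSE)
  expect_equal(nrow(validate_label_consistency(clean)), 0)

  # stored original 'D' at 31 contradicts label token Asn
  faithful <- table1_features(faithful = TRUE)
  issues <- validate_label_consistency(faithful)
  expect_equal(issues$feature_ac, "EBI-4370347")
  expect_equal(issues$code, "original-mismatch")

  # stored range wider than the label's single position
  off <- mk_feature("EBI-X1", "mutation(MI:0118)",
    start = 2L, end = 3L,
    original = "TA", resulting = "AA", label = "p.Thr2Ala"
  )
  issues <- validate_label_consistency(off)
  expect_equal(issues$code, "range-mismatch")
})
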