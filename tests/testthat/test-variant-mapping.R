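mk_catalogue <- function(...) {
  tbl <- tibble::tribble(...)
  defaults <- tibble::tibble(
    reference = NA_character_, disease_linked = FALSE,
    external_id = "", source = "test"
  )
  for (col in names(defaults)) {
    if (!col %in% names(tbl)) tbl[[col]] <- defaults[[col]]
  }
  tbl
}

# independent oracle: nested-loop scan over every (point change, variant) pair
oracle_category <- function(points, catalogue) {
  n <- nrow(points)
  if (n == 0) return("none")
  pos_hit <- rep(FALSE, n)
  full_hit <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(catalogue))) {
      if (catalogue$protein_ac[j] != points$protein_ac[i]) next
      if (catalogue$position[j] != points$position[i]) next
      pos_hit[i] <- TRUE
      ref <- catalogue$reference[j]
      if (catalogue$alternate[j] == points$resulting[i] &&
        (is.na(ref) || ref == "" || ref == points$original[i])) {
        full_hit[i] <- TRUE
      }
    }
  }
  if (all(full_hit)) return("full")
  if (!any(pos_hit)) return("none")
  if (n == 1) return("positional")
  "partial"
}

test_that("multi-position features split into individual substitutions", {
  single <- mk_feature("F1", "mutation(MI:0118)",
    start = 725L, original = "R", resulting = "E"
  )
  pts <- split_point_changes(single)
  expect_equal(pts$position, 725L)
  expect_equal(pts$original, "R")
  expect_equal(pts$resulting, "E")

  multi <- mk_feature("F2", "mutation disrupting(MI:0573)",
    start = 215L, end = 216L, original = "CS", resulting = "AA"
  )
  pts <- split_point_changes(multi)
  expect_equal(pts$position, c(215L, 216L))
  expect_equal(pts$original, c("C", "S"))
  expect_equal(pts$resulting, c("A", "A"))

  ins <- mk_feature("F3", "mutation(MI:0118)",
    start = 2L, end = 3L,
    original = "", resulting = "Q", label = "p.Lys2_Gly3insGln"
  )
  pts <- split_point_changes(ins)
  expect_equal(nrow(pts), 0)
  expect_equal(attr(pts, "excluded")$feature_ac, "F3")
})

test_that("full, positional, partial and none categories follow the rules", {
  f <- mk_feature("F1", "mutation(MI:0118)",
    protein = "P1", start = 100L,
    original = "A", resulting = "V", label = "p.Ala100Val"
  )
  full_cat <- mk_catalogue(
    ~protein_ac, ~position, ~alternate, "P1", 100L, "V"
  )
  expect_equal(map_annotations(f, full_cat)$category, "full")

  pos_cat <- mk_catalogue(~protein_ac, ~position, ~alternate, "P1", 100L, "G")
  expect_equal(map_annotations(f, pos_cat)$category, "positional")

  empty <- mk_catalogue(~protein_ac, ~position, ~alternate)
  expect_equal(map_annotations(f, empty)$category, "none")

  two <- mk_feature("F2", "mutation(MI:0118)",
    protein = "P1", start = 215L,
    end = 216L, original = "CS", resulting = "AA",
    label = "p.Cys_Ser215-216Ala_Ala"
  )
  one_of_two <- mk_catalogue(~protein_ac, ~position, ~alternate, "P1", 215L, "A")
  call <- map_annotations(two, one_of_two)
  expect_equal(call$category, "partial")
  expect_equal(call$match_detail, "partial-positions")

  both_pos_wrong_alt <- mk_catalogue(
    ~protein_ac, ~position, ~alternate,
    "P1", 215L, "A", "P1", 216L, "G"
  )
  call <- map_annotations(two, both_pos_wrong_alt)
  expect_equal(call$category, "partial")
  expect_equal(call$match_detail, "partial-residues")

  # indels are unmapped by construction
  ins <- mk_feature("F3", "mutation(MI:0118)",
    protein = "P1", start = 2L,
    end = 3L, original = "", resulting = "Q", label = "p.Lys2_Gly3insGln"
  )
  call <- map_annotations(ins, full_cat)
  expect_equal(call$category, "none")
  expect_equal(call$note, "unmapped-by-construction")
})

test_that("a contradicting catalogue reference residue demotes a full match", {
  f <- mk_feature("F1", "mutation(MI:0118)",
    protein = "P1", start = 100L,
    original = "A", resulting = "V", label = "p.Ala100Val"
  )
  cat <- mk_catalogue(
    ~protein_ac, ~position, ~reference, ~alternate, "P1", 100L, "G", "V"
  )
  call <- map_annotations(f, cat)
  expect_equal(call$category, "positional")
  expect_equal(call$note, "reference-mismatch")
})

test_that("disease linkage passes through from any matched variant", {
  f <- mk_feature("F1", "mutation(MI:0118)",
    protein = "P1", start = 100L,
    original = "A", resulting = "V", label = "p.Ala100Val"
  )
  cat <- mk_catalogue(~protein_ac, ~position, ~alternate, "P1", 100L, "G")
  cat$disease_linked <- TRUE
  call <- map_annotations(f, cat)
  expect_true(call$disease_linked)
})

test_that("indexed mapping equals a brute-force pair scan on random instances", {
  set.seed(31)
  aa <- c("A", "C", "D", "E", "G", "H", "K", "L", "R", "S", "T", "V")
  feats <- dplyr::bind_rows(lapply(1:40, function(i) {
    protein <- sample(paste0("P", 1:6), 1)
    pos <- sample(5:40, 1)
    span <- sample(1:2, 1, prob = c(0.7, 0.3))
    orig <- paste(sample(aa, span, replace = TRUE), collapse = "")
    res <- paste(sample(aa, span, replace = TRUE), collapse = "")
    mk_feature(paste0("F", i), "mutation(MI:0118)",
      protein = protein,
      start = pos, end = pos + span - 1L, original = orig, resulting = res,
      label = "p.Ala2Val"
    )
  }))
  catalogue <- tibble::tibble(
    protein_ac = sample(paste0("P", 1:6), 300, replace = TRUE),
    position = sample(5:41, 300, replace = TRUE),
    reference = NA_character_,
    alternate = sample(aa, 300, replace = TRUE),
    disease_linked = FALSE, external_id = "", source = "rand"
  )
  calls <- map_annotations(feats, catalogue)
  for (i in seq_len(nrow(feats))) {
    pts <- split_point_changes(feats[feats$feature_ac == paste0("F", i), ])
    expect_equal(
      calls$category[calls$feature_ac == paste0("F", i)],
      oracle_category(pts, catalogue),
      info = paste("feature", i)
    )
  }
})

test_that("the mapper recovers the injected match strata of a fixture", {
  fx <- mini_fx()
  calls <- map_annotations(fx$variants$mutations, fx$variants$catalogue)
  chg_cat <- unique(calls[, c("protein_ac", "change_key", "category")])
  merged <- merge(chg_cat, fx$variants$truth$changes,
    by = c("protein_ac", "change_key")
  )
  expect_equal(nrow(merged), nrow(fx$variants$truth$changes))
  expect_equal(merged$category, merged$stratum)

  truth <- fx$variants$truth$counts
  summ <- mapping_summary(fx$variants$mutations, fx$variants$catalogue)
  expect_equal(summ$annotation$full, truth$n_full_annotations)
  expect_equal(summ$annotation$positional_partial, truth$n_pos_partial_annotations)
  expect_equal(summ$sequence_change$full, truth$n_full_changes)
  expect_equal(summ$sequence_change$positional_partial, truth$n_pos_partial_changes)
  expect_gte(summ$annotation$cumulative, summ$annotation$full)
  expect_gte(summ$sequence_change$cumulative, summ$sequence_change$full)
})

test_that("mapping shares grow monotonically as the catalogue grows", {
  fx <- mini_fx()
  cat_full <- fx$variants$catalogue
  half <- cat_full[seq_len(nrow(cat_full) %/% 2), ]
  s_half <- mapping_summary(fx$variants$mutations, half, digits = 2)
  s_full <- mapping_summary(fx$variants$mutations, cat_full, digits = 2)
  expect_lte(s_half$annotation$pct_full, s_full$annotation$pct_full)
  expect_lte(s_half$annotation$pct_cumulative, s_full$annotation$pct_cumulative)
  expect_lte(s_half$sequence_change$pct_full, s_full$sequence_change$pct_full)
  expect_lte(
    s_half$sequence_change$pct_cumulative, s_full$sequence_change$pct_cumulative
  )
})
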