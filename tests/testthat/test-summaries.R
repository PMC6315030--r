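test_that("effect shares are computed half-up to one decimal", {
  counts <- c(
    disrupting = 10976, decreasing = 8553, increasing = 2256,
    causing = 188, no_effect = 3057, undefined = 2838
  )
  dist <- effect_distribution(counts)
  expect_equal(attr(dist, "total"), 27868)
  share <- function(cat) dist$percentage[dist$category == cat]
  expect_equal(share("decreasing"), 30.7)
  expect_equal(share("increasing"), 8.1)
  expect_equal(share("no_effect"), 11.0)
  expect_equal(share("causing"), 0.7)
  expect_equal(share("undefined"), 10.2)
  expect_equal(sum(dist$percentage), 100, tolerance = 0.1 / 100)

  even <- effect_distribution(c(disrupting = 1, no_effect = 1))
  expect_equal(even$percentage, c(50.0, 50.0))

  expect_error(effect_distribution(tibble::tibble(
    feature_ac = character(), feature_type = character()
  )), "empty")
})

test_that("distribution over a feature table counts each annotation once", {
  fx <- mini_fx()
  dist <- effect_distribution(fx$main$mutations)
  truth <- fx$main$truth$effects
  expect_equal(
    stats::setNames(dist$count, dist$category),
    truth[dist$category]
  )
  expect_equal(sum(dist$percentage), 100, tolerance = 0.1 / 100)
})

test_that("the replacement matrix counts substitution point changes", {
  single <- mk_feature("F1", "mutation(MI:0118)", original = "S", resulting = "A")
  m <- replacement_matrix(single)
  expect_equal(m$count, 1)
  expect_equal(m$freq, 1.0)

  fx <- mini_fx()
  m <- replacement_matrix(fx$main$mutations)
  pts <- split_point_changes(fx$main$mutations)
  expect_equal(sum(m$count), nrow(pts))
  # exact count recovery against a direct tabulation of the point changes
  direct <- as.data.frame(table(pts$original, pts$resulting), stringsAsFactors = FALSE)
  direct <- direct[direct$Freq > 0, ]
  merged <- merge(m, direct, by.x = c("original", "resulting"), by.y = c("Var1", "Var2"))
  expect_equal(nrow(merged), nrow(m))
  expect_equal(merged$count, merged$Freq)

  by_orig <- replacement_matrix(fx$main$mutations, normalize_by = "original")
  sums <- tapply(by_orig$freq, by_orig$original, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  by_eff <- replacement_matrix(fx$main$mutations, normalize_by = "effect")
  sums <- tapply(by_eff$freq, by_eff$effect, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("single-effect datasets make per-effect and global frequencies agree", {
  feats <- dplyr::bind_rows(
    mk_feature("F1", "mutation disrupting(MI:0573)", original = "S", resulting = "A"),
    mk_feature("F2", "mutation disrupting(MI:0573)", start = 12L, original = "R", resulting = "A")
  )
  none <- replacement_matrix(feats, normalize_by = "none")
  eff <- replacement_matrix(feats, normalize_by = "effect")
  merged <- merge(none, eff, by = c("original", "resulting"))
  expect_equal(merged$freq.x, merged$freq.y)
})

test_that("publication-size shares match direct enumeration", {
  feats <- dplyr::bind_rows(
    mk_feature("A1", "mutation(MI:0118)", pub = "1"),
    mk_feature("B1", "mutation(MI:0118)", pub = "2"),
    mk_feature("B2", "mutation(MI:0118)", pub = "2"),
    lapply(1:200, function(i) {
      mk_feature(paste0("C", i), "mutation(MI:0118)", pub = "3")
    })
  )
  out <- per_publication_counts(feats, threshold = 100)
  # direct enumeration: 2 of 3 publications, 3 of 203 annotations under 100
  expect_equal(out$n_publications, 3)
  expect_equal(out$pct_publications_under, round_half_up(100 * 2 / 3, 1)) # 66.7
  expect_equal(out$pct_annotations_under, round_half_up(100 * 3 / 203, 1)) # 1.5
  expect_equal(out$pct_publications_under, 66.7)
  expect_equal(out$pct_annotations_under, 1.5)

  one <- per_publication_counts(mk_feature("A1", "mutation(MI:0118)"))
  expect_equal(one$pct_publications_under, 100)
})

test_that("per-organism summaries recover the injected composition", {
  fx <- mini_fx()
  out <- per_organism_summary(fx$main$mutations)
  truth <- fx$main$truth$organisms
  for (i in seq_len(nrow(truth))) {
    row <- out[out$taxid == truth$taxid[i], ]
    expect_equal(row$annotations, truth$annotations[i])
    expect_equal(row$sequence_changes, truth$changes[i])
    expect_equal(row$proteins, truth$proteins[i])
    expect_equal(row$interactions, truth$interactions[i])
    expect_equal(row$publications, truth$publications[i])
  }
})

test_that("the totals row uses set semantics for shared identifiers", {
  feats <- dplyr::bind_rows(
    mk_feature("F1", "mutation(MI:0118)", taxid = "9606", pub = "777"),
    mk_feature("F2", "mutation(MI:0118)", taxid = "10090", pub = "777")
  )
  out <- per_organism_summary(feats)
  total <- out[out$taxid == "total", ]
  expect_equal(total$publications, 1) # shared publication counted once
  expect_equal(sum(out$publications[out$taxid != "total"]), 2)
})

test_that("summaries are invariant under row order", {
  fx <- mini_fx()
  tbl <- fx$main$mutations
  set.seed(9)
  shuffled <- tbl[sample(nrow(tbl)), ]
  a <- effect_distribution(tbl)
  b <- effect_distribution(shuffled)
  expect_equal(a, b)
  expect_equal(
    dplyr::arrange(replacement_matrix(tbl), original, resulting),
    dplyr::arrange(replacement_matrix(shuffled), original, resulting)
  )
})

test_that("half-up rounding follows the printing convention", {
  expect_equal(round_half_up(30.65, 1), 30.7)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(28.65), 29)
  expect_equal(round_half_up(-0.25, 1), -0.3)
})
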