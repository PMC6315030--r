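# independent oracle: enumerate every placement of a window by direct scan
scan_offsets <- function(window, subject) {
  hits <- integer(0)
  w <- nchar(window)
  for (i in seq_len(max(0L, nchar(subject) - w + 1L))) {
    if (substr(subject, i, i + w - 1L) == window) hits <- c(hits, i)
  }
  hits
}

rand_seq <- function(n) {
  paste(sample(c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  ), n, replace = TRUE), collapse = "")
}

test_that("feature checking distinguishes valid, mismatch and out-of-bounds", {
  seq <- table1_proteome()[["P10001"]] # has R at 725
  seg <- data.frame(start = 725, end = 725, original = "R", resulting = "E")
  expect_equal(check_feature(seg, seq), "valid")
  expect_equal(check_feature(seg, substr(seq, 1, 700)), "out_of_bounds")
  wrong <- seq
  substr(wrong, 725, 725) <- "K"
  expect_equal(check_feature(seg, wrong), "mismatch")
})

test_that("identical sequences leave features unchanged", {
  set.seed(3)
  old <- rand_seq(200)
  seg <- data.frame(start = 100, end = 100,
                    original = substr(old, 100, 100), resulting = "A")
  rr <- remap_feature(seg, old, old)
  expect_equal(rr$status, "unchanged")
  expect_equal(rr$offset, 0L)
  expect_equal(rr$new_segments$start, 100L)
})

test_that("an N-terminal extension shifts coordinates by its length", {
  set.seed(4)
  old <- rand_seq(300)
  new <- paste0("GS", old)
  seg <- data.frame(start = 150, end = 150,
                    original = substr(old, 150, 150), resulting = "A")
  rr <- remap_feature(seg, old, new, context = 10)
  expect_equal(rr$status, "shifted")
  expect_equal(rr$offset, 2L)
  # the shifted coordinates carry the same original residues
  expect_equal(
    substr(new, rr$new_segments$start, rr$new_segments$end), seg$original
  )
  # agreement with the exhaustive placement oracle
  window <- substr(old, 140, 160)
  expect_equal(scan_offsets(window, new), 142L)
})

test_that("missing or ambiguous context flags the feature instead of guessing", {
  set.seed(5)
  old <- rand_seq(200)
  seg <- data.frame(start = 100, end = 100,
                    original = substr(old, 100, 100), resulting = "A")
  expect_equal(remap_feature(seg, old, rand_seq(200))$reason, "no-match")

  window <- substr(old, 90, 110)
  dup <- paste0(rand_seq(40), window, rand_seq(15), window, rand_seq(40))
  expect_equal(remap_feature(seg, old, dup)$reason, "ambiguous-match")
})

test_that("multi-segment features need one common offset", {
  set.seed(6)
  old <- rand_seq(300)
  segs <- data.frame(
    start = c(50, 200), end = c(50, 200),
    original = c(substr(old, 50, 50), substr(old, 200, 200)),
    resulting = c("A", "A")
  )
  # insert residues between the segments: per-segment offsets now differ
  new <- paste0(substr(old, 1, 120), "WWWWW", substr(old, 121, 300))
  rr <- remap_feature(segs, old, new)
  expect_equal(rr$status, "flagged")
  expect_equal(rr$reason, "inconsistent-offsets")
  # a uniform prefix shifts both segments together
  rr2 <- remap_feature(segs, old, paste0("MGS", old))
  expect_equal(rr2$status, "shifted")
  expect_equal(rr2$offset, 3L)
})

test_that("remapping a feature that fails old-sequence validation errors", {
  old <- rand_seq(100)
  seg <- data.frame(start = 200, end = 200, original = "A", resulting = "G")
  expect_error(remap_feature(seg, old, old), "out_of_bounds")
})

test_that("context search agrees with the brute-force oracle on short proteins", {
  set.seed(8)
  for (rep in 1:40) {
    len <- sample(60:500, 1)
    old <- rand_seq(len)
    pos <- sample(15:(len - 15), 1)
    seg <- data.frame(
      start = pos, end = pos,
      original = substr(old, pos, pos), resulting = "A"
    )
    # random edit: prefix extension, suffix extension, or a distal splice
    new <- switch(sample(3, 1),
      paste0(rand_seq(sample(1:5, 1)), old),
      paste0(old, rand_seq(sample(1:5, 1))),
      paste0(substr(old, 3, len), rand_seq(2))
    )
    window <- substr(old, max(1, pos - 10), min(len, pos + 10))
    hits <- scan_offsets(window, new)
    rr <- remap_feature(seg, old, new, context = 10)
    if (length(hits) == 1L) {
      expect_equal(rr$status, "shifted")
      expect_equal(rr$offset, hits - max(1, pos - 10))
      expect_equal(
        substr(new, rr$new_segments$start, rr$new_segments$end),
        seg$original
      )
    } else {
      expect_equal(rr$status, "flagged")
    }
  }
})

test_that("a proteome update recovers the injected shift and scramble structure", {
  fx <- mini_fx()
  report <- run_update(fx$qc$mutations, fx$qc$old_proteome, fx$qc$new_proteome)
  truth <- fx$qc$truth
  merged <- merge(report$results, truth, by = "feature_ac", suffixes = c("", "_true"))
  expect_equal(merged$status, merged$status_true)
  shifted <- merged[merged$status == "shifted", ]
  expect_equal(shifted$offset, shifted$offset_true)
  expect_equal(sum(report$counts), nrow(truth))
  # flagged features are excluded from the emitted table
  expect_false(any(
    truth$feature_ac[truth$status == "flagged"] %in% report$updated$feature_ac
  ))
  # every emitted feature re-validates against the new proteome
  expect_equal(
    sum(validate_dataset(report$updated, fx$qc$new_proteome)$severity == "error"), 0
  )
})

test_that("updating against an identical proteome is the identity", {
  fx <- mini_fx()
  report <- run_update(fx$qc$mutations, fx$qc$old_proteome, fx$qc$old_proteome)
  expect_equal(report$counts[["unchanged"]], nrow(fx$qc$truth))
  expect_equal(report$updated, fx$qc$mutations)
})
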