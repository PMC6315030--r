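#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all printed percentages so that
#' e.g. 30.65 rounds to 30.7. Base R's `round()` rounds half to even, which
#' does not reproduce the conventions of curated-dataset reports.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero. A tolerance of 1e-9
#'   absorbs floating-point representation error just below .5 boundaries.
#' @export
#' @examples
#' round_half_up(30.65, 1) # 30.7
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 20 standard residues, one-letter
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# sequence alphabet tolerated in protein records
AA_TOLERATED <- c(AA_STANDARD, "X", "U", "B", "Z")

random_residues <- function(n) {
  paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
}

# Distribute `total` items over `n_bins` bins, each receiving at least
# `min_each`, with a skewed (truncated-geometric-like) surplus so most bins
# stay at the minimum. Uses the current RNG state.
distribute_counts <- function(total, n_bins, min_each = 1L, decay = 0.65) {
  if (n_bins == 0L) {
    if (total > 0L) stop("infeasible: ", total, " items but no bins", call. = FALSE)
    return(integer(0))
  }
  if (total < n_bins * min_each) {
    stop(sprintf(
      "infeasible: cannot distribute %d items over %d bins with at least %d each",
      total, n_bins, min_each
    ), call. = FALSE)
  }
  counts <- rep(as.integer(min_each), n_bins)
  leftover <- total - sum(counts)
  if (leftover > 0L) {
    w <- sample(decay^(seq_len(n_bins) - 1))
    counts <- counts +
      tabulate(sample.int(n_bins, leftover, replace = TRUE, prob = w), nbins = n_bins)
  }
  counts
}

# Largest-remainder apportionment of `total` across entries proportional to
# `weights`, respecting per-entry `caps`.
allocate_proportional <- function(total, weights, caps = rep(Inf, length(weights))) {
  if (total > sum(caps)) {
    stop("infeasible: allocation total exceeds capacity", call. = FALSE)
  }
  target <- total * weights / sum(weights)
  x <- pmin(floor(target), caps)
  while (sum(x) < total) {
    room <- which(x < caps)
    j <- room[which.max((target - x)[room])]
    x[j] <- x[j] + 1
  }
  as.integer(x)
}

# drop vector names picked up from named-proteome subsetting
unname_cols <- function(tbl) {
  tbl[] <- lapply(tbl, function(x) {
    names(x) <- NULL
    x
  })
  tbl
}

# all start positions (including overlapping ones) of `pattern` in `subject`
match_positions <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(subject)) {
    return(integer(0))
  }
  Biostrings::start(Biostrings::matchPattern(pattern, Biostrings::AAString(subject)))
}
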