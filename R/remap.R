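#' Check feature coordinates against a protein sequence
#'
#' @param segments Tibble of change segments (`start`, `end`, `original`
#'   or `original_seq`, 1-based inclusive).
#' @param sequence Protein residue string.
#' @return `"valid"` if every segment lies within the sequence and its
#'   original residues equal the sequence at the stated coordinates;
#'   `"out_of_bounds"` if any coordinate exceeds the sequence length;
#'   `"mismatch"` otherwise. Pure-insertion segments (empty original) are
#'   bounds-checked only.
#' @export
check_feature <- function(segments, sequence) {
  segments <- normalize_segments(segments)
  if (any(segments$end > nchar(sequence)) || any(segments$start < 1L)) {
    return("out_of_bounds")
  }
  for (i in seq_len(nrow(segments))) {
    if (segments$original[i] == "") next
    if (substr(sequence, segments$start[i], segments$end[i]) != segments$original[i]) {
      return("mismatch")
    }
  }
  "valid"
}

# accept either label-parse segments (original/resulting) or table rows
# (original_seq/resulting_seq)
normalize_segments <- function(segments) {
  segments <- tibble::as_tibble(segments)
  if ("original_seq" %in% names(segments) && !"original" %in% names(segments)) {
    segments$original <- segments$original_seq
    segments$resulting <- segments$resulting_seq
  }
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  segments[order(segments$start), ]
}

#' Remap feature coordinates onto an updated protein sequence
#'
#' When a referenced protein sequence changes between releases, feature
#' positions are shifted automatically where this can be done safely, and
#' flagged for curator review otherwise. Each segment's original residues
#' plus `context` flanking residues (truncated at the termini) are extracted
#' from the old sequence and searched for exact occurrences in the new one.
#' A unique hit for every segment, with one common offset across segments,
#' yields a shift; zero hits, multiple hits, or inconsistent per-segment
#' offsets flag the feature rather than guessing — a deliberate
#' curation-safety bias.
#'
#' @param segments Change segments that validate against `old_seq`.
#' @param old_seq,new_seq Old and new residue strings.
#' @param context Flank length on each side of a segment used as search
#'   context (default 10 residues; larger values buy uniqueness at the cost
#'   of robustness to nearby edits).
#' @return A list of class `remap_result`: `status` (`"unchanged"`,
#'   `"shifted"` or `"flagged"`), `offset` (signed integer, defined when
#'   shifted), `new_segments` (when not flagged) and `reason` (when
#'   flagged: `"no-match"`, `"ambiguous-match"` or `"inconsistent-offsets"`).
#'   Shifted results re-validate against `new_seq`.
#' @export
remap_feature <- function(segments, old_seq, new_seq, context = 10L) {
  segments <- normalize_segments(segments)
  status <- check_feature(segments, old_seq)
  if (status != "valid") {
    stop("feature does not validate against the old sequence (", status, ")",
      call. = FALSE
    )
  }
  result <- function(status, offset = NA_integer_, new_segments = NULL,
                     reason = NA_character_) {
    structure(
      list(
        status = status, offset = offset,
        new_segments = new_segments, reason = reason
      ),
      class = "remap_result"
    )
  }
  if (identical(old_seq, new_seq)) {
    return(result("unchanged", offset = 0L, new_segments = segments))
  }
  offsets <- integer(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    win_start <- max(1L, segments$start[i] - context)
    win_end <- min(nchar(old_seq), segments$end[i] + context)
    window <- substr(old_seq, win_start, win_end)
    hits <- match_positions(window, new_seq)
    if (length(hits) == 0L) {
      return(result("flagged", reason = "no-match"))
    }
    if (length(hits) > 1L) {
      return(result("flagged", reason = "ambiguous-match"))
    }
    offsets[i] <- hits - win_start
  }
  if (length(unique(offsets)) != 1L) {
    return(result("flagged", reason = "inconsistent-offsets"))
  }
  offset <- offsets[1]
  shifted <- segments
  shifted$start <- shifted$start + offset
  shifted$end <- shifted$end + offset
  if (check_feature(shifted, new_seq) != "valid") {
    return(result("flagged", reason = "revalidation-failed"))
  }
  result("shifted", offset = offset, new_segments = shifted)
}

#' Run a coordinate update across two proteome releases
#'
#' Classifies every feature as unchanged, shifted or flagged against the new
#' proteome, applies shifts (including re-emitting the HGVS-style label at
#' the new coordinates) and drops flagged features from the emitted table —
#' they await curator review. Features whose protein is missing from either
#' release, or that do not validate against the old sequence, are flagged.
#'
#' @param features Mutations table (one row per segment).
#' @param old_proteome,new_proteome Named character vectors of sequences.
#' @param context Search flank length, see [remap_feature()].
#' @return A list of class `update_report`: `counts` (named vector over
#'   unchanged/shifted/flagged, summing to the number of features),
#'   `results` (per-feature tibble with `feature_ac`, `protein_ac`,
#'   `status`, `offset`, `reason`) and `updated` (the mutations table with
#'   shifts applied and flagged features removed).
#' @export
run_update <- function(features, old_proteome, new_proteome, context = 10L) {
  feats <- collapse_features(features)
  res <- vector("list", nrow(feats))
  updated <- vector("list", nrow(feats))
  for (i in seq_len(nrow(feats))) {
    ac <- feats$feature_ac[i]
    prot <- feats$protein_ac[i]
    seg <- feats$segments[[i]]
    old_seq <- unname(old_proteome[prot])
    new_seq <- unname(new_proteome[prot])
    entry <- function(status, offset = NA_integer_, reason = NA_character_) {
      tibble::tibble(
        feature_ac = ac, protein_ac = prot, status = status,
        offset = offset, reason = reason
      )
    }
    rows <- features[features$feature_ac == ac, ]
    if (is.na(old_seq) || is.na(new_seq)) {
      res[[i]] <- entry("flagged", reason = "protein-unavailable")
      next
    }
    if (check_feature(seg, old_seq) != "valid") {
      res[[i]] <- entry("flagged", reason = "invalid-against-old")
      next
    }
    rr <- remap_feature(seg, old_seq, new_seq, context = context)
    if (rr$status == "flagged") {
      res[[i]] <- entry("flagged", reason = rr$reason)
      next
    }
    res[[i]] <- entry(rr$status, offset = rr$offset)
    if (rr$status == "shifted" && rr$offset != 0L) {
      rows <- rows[order(rows$start), ]
      rows$start <- rows$start + rr$offset
      rows$end <- rows$end + rr$offset
      rows$feature_label <- shifted_label(rows, new_seq)
    }
    updated[[i]] <- rows
  }
  results <- dplyr::bind_rows(res)
  counts <- c(
    unchanged = sum(results$status == "unchanged"),
    shifted = sum(results$status == "shifted"),
    flagged = sum(results$status == "flagged")
  )
  structure(
    list(
      counts = counts, results = results,
      updated = dplyr::bind_rows(updated)
    ),
    class = "update_report"
  )
}

# re-emit the label for shifted rows; insertion flanks read off the new sequence
shifted_label <- function(rows, new_seq) {
  seg <- tibble::tibble(
    start = rows$start, end = rows$end,
    original = rows$original_seq, resulting = rows$resulting_seq,
    flank_left = substr(new_seq, rows$start, rows$start),
    flank_right = substr(new_seq, rows$end, rows$end)
  )
  format_hgvs_label(seg)
}

#' @export
print.update_report <- function(x, ...) {
  cat("Coordinate update report\n")
  cat(sprintf(
    "  features: %d (unchanged %d, shifted %d, flagged %d)\n",
    sum(x$counts), x$counts[["unchanged"]], x$counts[["shifted"]],
    x$counts[["flagged"]]
  ))
  if (x$counts[["flagged"]] > 0) {
    tab <- table(x$results$reason[x$results$status == "flagged"])
    cat("  flag reasons:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
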