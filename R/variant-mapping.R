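#' Split substitution features into individual point changes
#'
#' Features spanning more than one amino acid position are split into
#' individual substitutions, one `(position, original, resulting)` triple per
#' residue: a contiguous segment `(215, 216, "CS", "AA")` yields
#' `(215, C, A)` and `(216, S, A)`. Insertion and deletion segments (and
#' length-changing replacements) carry no per-position substitution and are
#' excluded; features left with no point change at all are recorded in the
#' `"excluded"` attribute as unmapped by construction.
#'
#' @param features Mutations table.
#' @return A tibble of point changes (`feature_ac`, `protein_ac`, `position`,
#'   `original`, `resulting`) with attribute `excluded` (tibble of
#'   `feature_ac`, `reason`).
#' @export
split_point_changes <- function(features) {
  sub <- features$original_seq != "" & features$resulting_seq != "" &
    nchar(features$original_seq) == nchar(features$resulting_seq)
  if (any(sub & (features$end - features$start + 1L) != nchar(features$original_seq))) {
    stop("segment length does not match range length", call. = FALSE)
  }
  rows <- features[sub, ]
  n <- nchar(rows$original_seq)
  points <- tibble::tibble(
    feature_ac = rep(rows$feature_ac, n),
    protein_ac = rep(rows$protein_ac, n),
    position = unlist(mapply(function(s, k) s + seq_len(k) - 1L, rows$start, n,
      SIMPLIFY = FALSE
    ), use.names = FALSE),
    original = unlist(strsplit(rows$original_seq, ""), use.names = FALSE),
    resulting = unlist(strsplit(rows$resulting_seq, ""), use.names = FALSE)
  )
  if (nrow(rows) == 0L) {
    points <- tibble::tibble(
      feature_ac = character(), protein_ac = character(),
      position = integer(), original = character(), resulting = character()
    )
  }
  excluded_acs <- setdiff(unique(features$feature_ac), unique(points$feature_ac))
  attr(points, "excluded") <- tibble::tibble(
    feature_ac = excluded_acs,
    reason = rep("non-substitution", length(excluded_acs))
  )
  points
}

#' Map mutation annotations onto a variant catalogue
#'
#' Implements the full / positional / partial matching rules. Every point
#' change of a feature is looked up in the catalogue by (accession,
#' position); accession strings are matched exactly, so isoform-suffixed
#' accessions only match isoform-specific catalogue rows. A feature is a
#' `"full"` match when every position has a catalogue variant with the
#' identical alternate residue; a single-position feature whose position is
#' annotated with a different alternate is `"positional"`; a multi-position
#' feature with at least one matched position but no complete
#' residue-identical cover is `"partial"` (the `match_detail` column keeps
#' the sub-distinction between unmatched positions and differing residues);
#' otherwise `"none"`. A catalogue reference residue that contradicts the
#' feature's original residue demotes a would-be full point match and is
#' noted.
#'
#' @param features Mutations table.
#' @param catalogue Variant catalogue tibble (see [read_variant_catalogue()]).
#' @return Tibble with one row per feature: `feature_ac`, `protein_ac`,
#'   `change_key`, `category` (`"full"`, `"partial"`, `"positional"`,
#'   `"none"`), `match_detail`, `n_positions`, `n_positions_matched`,
#'   `n_full_positions`, `disease_linked` (any matched variant carries a
#'   disease link), `note`.
#' @export
map_annotations <- function(features, catalogue) {
  feats <- collapse_features(features)
  points <- split_point_changes(features)
  cat2 <- catalogue[, c(
    "protein_ac", "position", "reference", "alternate", "disease_linked"
  )]
  j <- dplyr::left_join(points, cat2,
    by = c("protein_ac", "position"), relationship = "many-to-many"
  )
  has_var <- !is.na(j$alternate)
  alt_ok <- has_var & j$alternate == j$resulting
  ref_ok <- has_var & (is.na(j$reference) | j$reference == "" |
    j$reference == j$original)
  j$has_var <- has_var
  j$full_hit <- alt_ok & ref_ok
  j$demote_hit <- alt_ok & !ref_ok
  j$disease_hit <- has_var & !is.na(j$disease_linked) & j$disease_linked
  per_point <- dplyr::summarise(
    dplyr::group_by(j, .data$feature_ac, .data$position),
    pos_matched = any(.data$has_var),
    full = any(.data$full_hit),
    demoted = any(.data$demote_hit) & !any(.data$full_hit),
    disease = any(.data$disease_hit),
    .groups = "drop"
  )
  per_feat <- dplyr::summarise(
    dplyr::group_by(per_point, .data$feature_ac),
    n_positions = dplyr::n(),
    n_positions_matched = sum(.data$pos_matched),
    n_full_positions = sum(.data$full),
    demoted = any(.data$demoted),
    disease_linked = any(.data$disease),
    .groups = "drop"
  )
  out <- dplyr::left_join(
    feats[, c("feature_ac", "protein_ac", "change_key")], per_feat,
    by = "feature_ac"
  )
  out$n_positions[is.na(out$n_positions)] <- 0L
  out$n_positions_matched[is.na(out$n_positions_matched)] <- 0L
  out$n_full_positions[is.na(out$n_full_positions)] <- 0L
  out$demoted[is.na(out$demoted)] <- FALSE
  out$disease_linked[is.na(out$disease_linked)] <- FALSE
  n_pts <- out$n_positions
  all_full <- n_pts > 0L & out$n_full_positions == n_pts
  any_pos <- out$n_positions_matched > 0L
  out$category <- dplyr::case_when(
    n_pts == 0L ~ "none",
    all_full ~ "full",
    !any_pos ~ "none",
    n_pts == 1L ~ "positional",
    TRUE ~ "partial"
  )
  out$match_detail <- dplyr::case_when(
    out$category == "partial" & out$n_positions_matched == n_pts ~ "partial-residues",
    out$category == "partial" ~ "partial-positions",
    TRUE ~ out$category
  )
  out$note <- dplyr::case_when(
    n_pts == 0L ~ "unmapped-by-construction",
    out$demoted & out$category %in% c("positional", "partial") ~ "reference-mismatch",
    TRUE ~ NA_character_
  )
  out$demoted <- NULL
  out[, c(
    "feature_ac", "protein_ac", "change_key", "category", "match_detail",
    "n_positions", "n_positions_matched", "n_full_positions",
    "disease_linked", "note"
  )]
}

MAPPING_CATEGORY_ORDER <- c("full", "partial", "positional", "none")

#' Summarize variant mapping at annotation and sequence-change level
#'
#' Counts and percentages of full and cumulative (full + positional/partial)
#' matches at two granularities: per annotation (feature) and per distinct
#' sequence change (distinct `(protein, segment tuple)`). Percentages are
#' rounded half-up to the nearest integer, the printing convention for
#' mapping shares; `digits` overrides it. The category of a sequence change
#' is the best category among its annotations (they agree by construction,
#' since mapping is a function of the change).
#'
#' @param features Mutations table.
#' @param catalogue Variant catalogue.
#' @param digits Decimal places for the percentages (default 0).
#' @return A list of class `mapping_summary` with `schema_version`,
#'   `annotation` and `sequence_change` sub-lists (`n`, `full`,
#'   `positional_partial`, `cumulative` counts plus `pct_full`,
#'   `pct_positional_partial`, `pct_cumulative`) and the per-feature `calls`
#'   tibble.
#' @export
mapping_summary <- function(features, catalogue, digits = 0) {
  calls <- map_annotations(features, catalogue)
  level <- function(cats) {
    n <- length(cats)
    full <- sum(cats == "full")
    pp <- sum(cats %in% c("partial", "positional"))
    pct <- function(k) if (n == 0) NA_real_ else round_half_up(100 * k / n, digits)
    list(
      n = n, full = full, positional_partial = pp, cumulative = full + pp,
      pct_full = pct(full), pct_positional_partial = pct(pp),
      pct_cumulative = pct(full + pp)
    )
  }
  chg <- dplyr::summarise(
    dplyr::group_by(calls, .data$protein_ac, .data$change_key),
    category = MAPPING_CATEGORY_ORDER[min(match(.data$category, MAPPING_CATEGORY_ORDER))],
    .groups = "drop"
  )
  structure(
    list(
      schema_version = "1.0",
      annotation = level(calls$category),
      sequence_change = level(chg$category),
      calls = calls
    ),
    class = "mapping_summary"
  )
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat("Variant mapping summary\n")
  a <- x$annotation
  s <- x$sequence_change
  cat(sprintf(
    "  annotations:      %d, full %d (%s%%), positional/partial %d (%s%%)\n",
    a$n, a$full, a$pct_full, a$positional_partial, a$pct_positional_partial
  ))
  cat(sprintf(
    "  sequence changes: %d, full %d (%s%%), positional/partial %d (%s%%)\n",
    s$n, s$full, s$pct_full, s$positional_partial, s$pct_positional_partial
  ))
  invisible(x)
}
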