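#' Classify substitutions relative to annotated phosphosites
#'
#' Phosphorylatable residues (serine, threonine, tyrosine) are commonly
#' mutated either to remove the phosphosite — replacement by alanine,
#' glycine, valine or phenylalanine (phospho-disrupting) — or to mimic the
#' phosphorylated state — replacement by glutamic or aspartic acid
#' (phospho-mimetic). The classification is a pure function of the original
#' residue, the resulting residue and phosphosite membership; substitutions
#' away from S/T/Y, or at positions without an annotated site, are
#' `"not_applicable"`, and any other replacement at a site is
#' `"other_at_phosphosite"`. The four classes are exhaustive and mutually
#' exclusive per point change.
#'
#' @param original,resulting One-letter residue codes (vectorized).
#' @param at_phosphosite Logical: is the position an annotated phosphosite?
#' @return Character vector of classes.
#' @export
#' @examples
#' classify_phospho("S", "A", TRUE) # phospho_disrupting
#' classify_phospho("T", "D", TRUE) # phospho_mimetic
classify_phospho <- function(original, resulting, at_phosphosite) {
  dplyr::case_when(
    !(original %in% c("S", "T", "Y")) | !at_phosphosite ~ "not_applicable",
    resulting %in% c("A", "G", "V", "F") ~ "phospho_disrupting",
    resulting %in% c("E", "D") ~ "phospho_mimetic",
    TRUE ~ "other_at_phosphosite"
  )
}

#' Detect alanine-scanning substitutions
#'
#' Alanine is by far the most frequently used replacement residue in
#' site-directed mutagenesis of binding sites; this predicate marks point
#' changes that replace a non-alanine residue with alanine.
#'
#' @param original,resulting One-letter residue codes (vectorized).
#' @return Logical vector.
#' @export
is_alanine_substitution <- function(original, resulting) {
  resulting == "A" & original != "A"
}

#' Simplify an affinity fold change to loss / gain / no effect
#'
#' In vitro affinity data records dissociation constants for the wild-type
#' and mutant forms. The mutant KD is normalized to the wild type,
#' `r = kd_mutant / kd_wild_type`, and calls are made on the ratio: larger
#' KD means weaker binding, so `r > loss_threshold` (default 1.5, a fold
#' change over 50 percent of wild type) is a `"loss"` of binding function,
#' `r < gain_threshold` (default 0.5) a `"gain"`, and anything between
#' `"no_effect"`. Both thresholds (and thereby the asymmetric reading of
#' "over and under 50 percent") are configurable.
#'
#' @param kd_wild_type,kd_mutant Dissociation constants, molar, strictly
#'   positive (vectorized).
#' @param loss_threshold,gain_threshold Ratio cut-offs.
#' @return Character vector: `"loss"`, `"gain"` or `"no_effect"`.
#' @export
#' @examples
#' classify_affinity_fold_change(1e-9, 5e-9) # loss
classify_affinity_fold_change <- function(kd_wild_type, kd_mutant,
                                          loss_threshold = 1.5,
                                          gain_threshold = 0.5) {
  if (any(kd_wild_type <= 0) || any(kd_mutant <= 0)) {
    stop("dissociation constants must be strictly positive", call. = FALSE)
  }
  r <- kd_mutant / kd_wild_type
  dplyr::case_when(
    r > loss_threshold ~ "loss",
    r < gain_threshold ~ "gain",
    TRUE ~ "no_effect"
  )
}

#' Simplify effect categories for cross-resource comparison
#'
#' Collapses the six-level effect vocabulary onto the loss / gain /
#' no-effect / unknown scheme used when comparing against resources that
#' only record a direction of change in binding function: negative-direction
#' categories become `"loss"`, positive ones `"gain"`, neutral
#' `"no_effect"` and undefined `"unknown"`.
#'
#' @param category Character vector of effect categories.
#' @return Character vector of simplified classes.
#' @export
#' @examples
#' simplify_effect(c("disrupting", "causing", "undefined"))
simplify_effect <- function(category) {
  c(
    negative = "loss", positive = "gain",
    neutral = "no_effect", unknown = "unknown"
  )[effect_direction(category)] |> unname()
}

#' Interface membership of point changes
#'
#' Tests whether point changes fall inside annotated interface regions,
#' separately per region source class (`"predicted"` from structural models,
#' `"curated"` from binding-associated-region features in the interaction
#' literature). Coordinates are 1-based inclusive on both sides.
#'
#' @param points Tibble of point changes (`protein_ac`, `position`, as from
#'   [split_point_changes()]).
#' @param regions Interface-region tibble (`protein_ac`, `start`, `end`,
#'   `source`), see [read_interface_regions()].
#' @return `points` with one logical column `inside_<source>` per source
#'   class present in `regions`.
#' @export
interface_membership <- function(points, regions) {
  points <- tibble::as_tibble(points)
  for (src in sort(unique(regions$source))) {
    reg <- regions[regions$source == src, ]
    j <- dplyr::left_join(
      points[, c("protein_ac", "position")],
      reg[, c("protein_ac", "start", "end")],
      by = "protein_ac", relationship = "many-to-many"
    )
    j$inside <- !is.na(j$start) & j$position >= j$start & j$position <= j$end
    hit <- dplyr::summarise(
      dplyr::group_by(j, .data$protein_ac, .data$position),
      inside = any(.data$inside), .groups = "drop"
    )
    points <- dplyr::left_join(points, hit, by = c("protein_ac", "position"))
    names(points)[names(points) == "inside"] <- paste0("inside_", src)
  }
  points
}

#' Feature-level interface membership
#'
#' A multi-position sequence change is inside an interface if any of its
#' positions is inside a region of the given source class.
#'
#' @param features Mutations table.
#' @param regions Interface-region tibble.
#' @return One row per feature (`feature_ac`) with logical
#'   `inside_<source>` columns.
#' @export
feature_interface_membership <- function(features, regions) {
  points <- split_point_changes(features)
  pts <- interface_membership(points, regions)
  cols <- grep("^inside_", names(pts), value = TRUE)
  dplyr::summarise(
    dplyr::group_by(pts, .data$feature_ac),
    dplyr::across(dplyr::all_of(cols), any),
    .groups = "drop"
  )
}
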