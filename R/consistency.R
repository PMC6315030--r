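#' Group repeated evidence for the same sequence change and partners
#'
#' The unit of consistency assessment is the evidence group: all features
#' describing one sequence change on one protein, tested against the same
#' set of interaction partners. Partner identity is proteoform-sensitive — a
#' phosphorylated partner is a different partner from its unmodified form —
#' and segment tuples are compared after sorting by start position.
#'
#' @param features Mutations table (one row per segment).
#' @return A tibble with one row per evidence group: `group_id`,
#'   `protein_ac`, `change_key`, `partner_set`, `feature_acs` (list-column),
#'   `categories` (list-column of effect categories), `n_evidences`.
#' @export
group_evidence <- function(features) {
  feats <- collapse_features(features)
  feats$category <- effect_category(feats$feature_type)
  key <- paste(feats$protein_ac, feats$change_key, feats$partner_set, sep = "\r")
  feats$.group <- factor(key, levels = unique(key)) # first-appearance order
  out <- dplyr::summarise(
    dplyr::group_by(feats, .data$.group),
    protein_ac = dplyr::first(.data$protein_ac),
    change_key = dplyr::first(.data$change_key),
    partner_set = dplyr::first(.data$partner_set),
    feature_acs = list(.data$feature_ac),
    categories = list(.data$category),
    n_evidences = dplyr::n(),
    .groups = "drop"
  )
  out$.group <- NULL
  out <- tibble::add_column(out, group_id = seq_len(nrow(out)), .before = 1)
  out
}

#' Classify the agreement of an evidence group
#'
#' Effects are compared through their direction semantics. With a single
#' evidence the group is `"single"`. Effects with unknown direction
#' (category `undefined`) are excluded from the vote; a multi-tested group
#' whose evidence is all undefined is `"unclassifiable"`. Among the voting
#' members: both a negative- and a positive-direction effect present is a
#' `"conflict"` (directly antagonistic, e.g. disrupting vs increasing);
#' exactly one non-neutral direction plus at least one no-effect annotation
#' is a `"mild_conflict"` (e.g. decreasing vs no effect, including 50/50
#' splits); otherwise the group is `"consistent"` — all effects in one
#' direction (mixed negative categories such as disrupting plus decreasing
#' count as agreement, as do mixed positive ones, or all-neutral groups).
#' Antagonism dominates: a group holding negative, positive and neutral
#' evidence is a conflict.
#'
#' @param group Either a character vector of effect categories or one row of
#'   the tibble returned by [group_evidence()].
#' @return A list of class `consistency_call`: `class` (`"single"`,
#'   `"consistent"`, `"mild_conflict"`, `"conflict"` or `"unclassifiable"`)
#'   and `directions_seen`.
#' @export
#' @examples
#' classify_group(c("disrupting", "decreasing")) # consistent
#' classify_group(c("disrupting", "increasing")) # conflict
classify_group <- function(group) {
  categories <- if (is.character(group)) {
    group
  } else if (!is.null(group$categories)) {
    unlist(group$categories)
  } else {
    stop("cannot extract effect categories from 'group'", call. = FALSE)
  }
  dirs <- effect_direction(categories)
  voting <- dirs[dirs != "unknown"]
  call <- function(class) {
    structure(
      list(class = class, directions_seen = sort(unique(dirs))),
      class = "consistency_call"
    )
  }
  if (length(categories) == 1L) {
    return(call("single"))
  }
  if (length(voting) == 0L) {
    return(call("unclassifiable"))
  }
  has_neg <- "negative" %in% voting
  has_pos <- "positive" %in% voting
  has_neu <- "neutral" %in% voting
  if (has_neg && has_pos) {
    return(call("conflict"))
  }
  if ((has_neg || has_pos) && has_neu) {
    return(call("mild_conflict"))
  }
  call("consistent")
}

#' Consistency report over multiply-tested evidence groups
#'
#' Groups with two or more evidences (excluding groups whose evidence is all
#' of undefined direction, which carry no comparable effect statement) are
#' classified and tallied. Percentages are computed half-up to one decimal.
#'
#' @param features Mutations table.
#' @return A list of class `consistency_report`: `schema_version`,
#'   `grouping_key` (documentation of the group key convention),
#'   `n_groups_total`, `n_single`, `n_multi_tested` (the denominator),
#'   `n_consistent`, `n_mild_conflict`, `n_conflict`, `n_non_consistent`,
#'   `pct_non_consistent`, `pct_conflict` and `conflict_groups` (tibble of
#'   the antagonistic group keys).
#' @export
consistency_report <- function(features) {
  groups <- group_evidence(features)
  groups$class <- vapply(
    groups$categories, function(cats) classify_group(cats)$class, character(1)
  )
  multi <- groups[groups$n_evidences >= 2L & groups$class != "unclassifiable", ]
  n_multi <- nrow(multi)
  n_cons <- sum(multi$class == "consistent")
  n_mild <- sum(multi$class == "mild_conflict")
  n_conf <- sum(multi$class == "conflict")
  pct <- function(n) {
    if (n_multi == 0) NA_real_ else round_half_up(100 * n / n_multi, 1)
  }
  structure(
    list(
      schema_version = "1.0",
      grouping_key = "(protein_ac, ordered segment tuple, partner multiset incl. proteoform tags)",
      n_groups_total = nrow(groups),
      n_single = sum(groups$n_evidences == 1L),
      n_multi_tested = n_multi,
      n_consistent = n_cons,
      n_mild_conflict = n_mild,
      n_conflict = n_conf,
      n_non_consistent = n_mild + n_conf,
      pct_non_consistent = pct(n_mild + n_conf),
      pct_conflict = pct(n_conf),
      conflict_groups = multi[
        multi$class == "conflict",
        c("protein_ac", "change_key", "partner_set")
      ]
    ),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("Evidence-consistency report\n")
  cat(sprintf(
    "  groups: %d total, %d single-tested, %d multi-tested\n",
    x$n_groups_total, x$n_single, x$n_multi_tested
  ))
  cat(sprintf(
    "  multi-tested: %d consistent, %d mild conflict, %d conflict\n",
    x$n_consistent, x$n_mild_conflict, x$n_conflict
  ))
  cat(sprintf(
    "  non-consistent: %d (%.1f%%), antagonistic: %d (%.1f%%)\n",
    x$n_non_consistent, x$pct_non_consistent, x$n_conflict, x$pct_conflict
  ))
  invisible(x)
}
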