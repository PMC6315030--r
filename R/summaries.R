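#' Distribution of annotations by effect category
#'
#' One count per effect category over annotations (multi-row features count
#' once, since a mutation annotation is identified by its unique feature
#' accession). Percentages are computed as `100 * count / total` and rounded
#' half-up to one decimal — the printing convention of dataset reports.
#' Counts may also be supplied directly as a named numeric vector, e.g. to
#' recompute the shares of a published per-category breakdown.
#'
#' @param x Either a mutations table or a named numeric vector of
#'   per-category counts.
#' @return A tibble (`category`, `count`, `percentage`) ordered by the
#'   canonical category order, with attribute `total`. Percentages sum to
#'   100 within 0.1 (rounding).
#' @export
#' @examples
#' effect_distribution(c(disrupting = 1, no_effect = 1))
effect_distribution <- function(x) {
  if (is.numeric(x)) {
    counts <- x
  } else {
    per_feature <- unique(tibble::as_tibble(x)[, c("feature_ac", "feature_type")])
    cats <- effect_category(per_feature$feature_type)
    counts <- table(factor(cats, levels = EFFECT_CATEGORIES))
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  total <- sum(counts)
  if (total == 0) stop("empty dataset: no annotations to summarize", call. = FALSE)
  keep <- intersect(EFFECT_CATEGORIES, names(counts))
  extra <- setdiff(names(counts), EFFECT_CATEGORIES)
  counts <- counts[c(keep, extra)]
  out <- tibble::tibble(
    category = names(counts),
    count = as.numeric(counts),
    percentage = round_half_up(100 * as.numeric(counts) / total, 1)
  )
  attr(out, "total") <- total
  out
}

#' Amino acid replacement matrix
#'
#' Counts of substitutions indexed by (original residue, resulting residue),
#' computed over split point changes; insertions and deletions are excluded
#' and counted separately by the caller. Optional normalization divides by
#' the scope total: `"original"` (rows sum to 1), `"resulting"` (columns sum
#' to 1), or `"effect"` (per-effect-category frequencies, adding an `effect`
#' column).
#'
#' @param features Mutations table.
#' @param normalize_by One of `"none"`, `"original"`, `"resulting"`,
#'   `"effect"`.
#' @return A tidy tibble with columns `original`, `resulting` (plus `effect`
#'   for `normalize_by = "effect"`), `count` and `freq`. The total count
#'   equals the number of substitution point changes.
#' @export
replacement_matrix <- function(features,
                               normalize_by = c("none", "original", "resulting", "effect")) {
  normalize_by <- match.arg(normalize_by)
  points <- split_point_changes(features)
  attr(points, "excluded") <- NULL
  if (normalize_by == "effect") {
    eff <- unique(tibble::as_tibble(features)[, c("feature_ac", "feature_type")])
    eff$effect <- effect_category(eff$feature_type)
    points <- dplyr::left_join(
      points, eff[, c("feature_ac", "effect")],
      by = "feature_ac"
    )
    out <- dplyr::count(points, .data$effect, .data$original, .data$resulting,
      name = "count"
    )
    out <- dplyr::mutate(dplyr::group_by(out, .data$effect),
      freq = .data$count / sum(.data$count)
    )
    return(dplyr::ungroup(out))
  }
  out <- dplyr::count(points, .data$original, .data$resulting, name = "count")
  out$freq <- switch(normalize_by,
    none = out$count / sum(out$count),
    original = out$count / stats::ave(out$count, out$original, FUN = sum),
    resulting = out$count / stats::ave(out$count, out$resulting, FUN = sum)
  )
  out
}

#' Annotations per publication
#'
#' Histogram of the number of mutation annotations contributed by each
#' source publication, plus the share of publications below a size
#' threshold and the share of annotations those publications hold —
#' literature-curated datasets are dominated by small papers reporting a
#' handful of mutations each.
#'
#' @param features Mutations table.
#' @param threshold Publication size cut-off (default 100 annotations).
#' @return A list: `histogram` (tibble `pubmed_id`, `n_annotations`),
#'   `threshold`, `n_publications`, `n_annotations`,
#'   `pct_publications_under` and `pct_annotations_under` (half-up, one
#'   decimal).
#' @export
per_publication_counts <- function(features, threshold = 100) {
  per_feature <- unique(tibble::as_tibble(features)[, c("feature_ac", "pubmed_id")])
  hist <- dplyr::count(per_feature, .data$pubmed_id, name = "n_annotations")
  under <- hist$n_annotations < threshold
  list(
    histogram = hist,
    threshold = threshold,
    n_publications = nrow(hist),
    n_annotations = sum(hist$n_annotations),
    pct_publications_under = if (nrow(hist) == 0) {
      NA_real_
    } else {
      round_half_up(100 * sum(under) / nrow(hist), 1)
    },
    pct_annotations_under = if (nrow(hist) == 0) {
      NA_real_
    } else {
      round_half_up(100 * sum(hist$n_annotations[under]) / sum(hist$n_annotations), 1)
    }
  )
}

#' Per-organism summary table
#'
#' One row per taxon with the number of annotations, distinct sequence
#' changes, affected proteins, affected interactions and source
#' publications, plus a totals row computed with set semantics: distinct
#' counts over the union of identifiers, not the sum of per-organism rows
#' (identifiers shared across organisms are counted once).
#'
#' @param features Mutations table.
#' @return A tibble with columns `taxid`, `annotations`, `sequence_changes`,
#'   `proteins`, `interactions`, `publications`; the last row has
#'   `taxid = "total"`.
#' @export
per_organism_summary <- function(features) {
  feats <- collapse_features(features)
  feats$change_id <- paste(feats$protein_ac, feats$change_key, sep = "\r")
  summarize_set <- function(d, label) {
    tibble::tibble(
      taxid = label,
      annotations = dplyr::n_distinct(d$feature_ac),
      sequence_changes = dplyr::n_distinct(d$change_id),
      proteins = dplyr::n_distinct(d$protein_ac),
      interactions = dplyr::n_distinct(d$interaction_id),
      publications = dplyr::n_distinct(d$pubmed_id)
    )
  }
  rows <- lapply(
    split(feats, feats$protein_taxid),
    function(d) summarize_set(d, d$protein_taxid[1])
  )
  per_org <- dplyr::bind_rows(rows)
  per_org <- per_org[order(-per_org$annotations), ]
  dplyr::bind_rows(per_org, summarize_set(feats, "total"))
}
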