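#' Controlled-vocabulary effect terms and their direction semantics
#'
#' The effect a sequence change has on an interaction is recorded with a
#' PSI-MI controlled-vocabulary feature type ("MI:NNNN"). The toolkit works
#' with six collapsed categories — disrupting, decreasing, increasing,
#' causing, no_effect, undefined — each carrying a direction semantic:
#' negative (binding lost or weakened), positive (binding gained or
#' strengthened), neutral (no detectable effect) or unknown (no wild-type
#' comparison available). Finer child terms (rate/strength variants such as
#' "mutation decreasing rate") collapse onto their parent category.
#'
#' @param extra Optional tibble of additional rows (`term`, `mi_id`,
#'   `category`, `direction`) appended to the packaged table, so that new
#'   vocabulary terms can be adopted without a package update.
#' @return A tibble with columns `term`, `mi_id`, `category`, `direction`.
#' @export
#' @examples
#' effect_vocabulary()
effect_vocabulary <- function(extra = NULL) {
  tbl <- tibble::tribble(
    ~term,                           ~mi_id,    ~category,     ~direction,
    "mutation",                      "MI:0118", "undefined",   "unknown",
    "mutation disrupting",           "MI:0573", "disrupting",  "negative",
    "mutation disrupting strength",  "MI:1128", "disrupting",  "negative",
    "mutation disrupting rate",      "MI:1129", "disrupting",  "negative",
    "mutation decreasing",           "MI:0119", "decreasing",  "negative",
    "mutation decreasing strength",  "MI:1133", "decreasing",  "negative",
    "mutation decreasing rate",      "MI:1130", "decreasing",  "negative",
    "mutation increasing",           "MI:0382", "increasing",  "positive",
    "mutation increasing strength",  "MI:1132", "increasing",  "positive",
    "mutation increasing rate",      "MI:1131", "increasing",  "positive",
    "mutation causing",              "MI:2227", "causing",     "positive",
    "mutation with no effect",       "MI:2226", "no_effect",   "neutral"
  )
  if (!is.null(extra)) tbl <- dplyr::bind_rows(tbl, tibble::as_tibble(extra))
  tbl
}

EFFECT_CATEGORIES <- c(
  "disrupting", "decreasing", "increasing", "causing", "no_effect", "undefined"
)

EFFECT_DIRECTION_MAP <- c(
  disrupting = "negative", decreasing = "negative",
  increasing = "positive", causing = "positive",
  no_effect = "neutral", undefined = "unknown"
)

# split "mutation disrupting(MI:0573)" into name / MI id parts
split_feature_type <- function(x) {
  m <- regmatches(x, regexec("^\\s*(.*?)\\s*(?:\\((MI:\\d+)\\))?\\s*$", x,
    perl = TRUE
  ))
  list(
    name = vapply(m, function(g) g[2], character(1)),
    mi_id = vapply(m, function(g) g[3], character(1))
  )
}

#' Map feature-type terms to effect categories
#'
#' Accepts a character vector of feature types in any of the forms
#' `"mutation disrupting(MI:0573)"`, `"mutation disrupting"` or `"MI:0573"`,
#' and returns the collapsed six-level effect category. Lookup is by MI
#' identifier first, then by term name.
#'
#' @param x Character vector of feature-type strings.
#' @param vocabulary Vocabulary table, see [effect_vocabulary()].
#' @return Character vector of categories; `NA` where the term is unknown.
#' @export
#' @examples
#' effect_category(c("mutation decreasing rate(MI:1130)", "MI:0573"))
effect_category <- function(x, vocabulary = effect_vocabulary()) {
  parts <- split_feature_type(x)
  mi_idx <- match(parts$mi_id, vocabulary$mi_id)
  name_idx <- match(tolower(parts$name), tolower(vocabulary$term))
  direct_idx <- match(parts$name, vocabulary$mi_id) # bare "MI:0573" input
  idx <- ifelse(!is.na(mi_idx), mi_idx, ifelse(!is.na(direct_idx), direct_idx, name_idx))
  vocabulary$category[idx]
}

#' Direction semantic of an effect category
#'
#' The direction map is total and fixed: disrupting and decreasing are
#' negative, increasing and causing are positive, no_effect is neutral and
#' undefined is unknown. Downstream consistency classification compares
#' directions, so that e.g. "disrupting" and "decreasing" agree.
#'
#' @param category Character vector of effect categories.
#' @return Character vector of directions
#'   (`"negative"`, `"positive"`, `"neutral"`, `"unknown"`).
#' @export
#' @examples
#' effect_direction(c("disrupting", "causing", "no_effect"))
effect_direction <- function(category) {
  bad <- setdiff(unique(category), names(EFFECT_DIRECTION_MAP))
  if (length(bad) > 0) {
    stop("unknown effect category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(EFFECT_DIRECTION_MAP[category])
}
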