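#' @name hgvs_labels
#' @title HGVS-style protein-change labels
#'
#' @description
#' Mutation features are named with HGVS-style protein-change short labels
#' such as `"p.Arg725Glu"`. The supported grammar covers the forms found in
#' curated interaction records: single substitutions, contiguous
#' multi-residue substitutions (`"p.Cys_Ser215-216Ala_Ala"`), discontiguous
#' multi-position variants in bracket notation (`"p.[Asn31His;Ala60Val]"`),
#' simple deletions (`"p.Arg12del"`, `"p.Cys12_Ser13del"`) and simple
#' insertions (`"p.Lys2_Gly3insGlnSer"`). Coordinates are 1-based inclusive
#' throughout (UniProt feature convention).
NULL

# three-letter <-> one-letter residue names; includes Sec and ambiguity codes
AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
  Sec = "U", Asx = "B", Glx = "Z", Xaa = "X"
)
AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

RX_AA3 <- "[A-Z][a-z]{2}"

three_to_one <- function(tokens) {
  out <- AA_THREE_TO_ONE[tokens]
  if (anyNA(out)) {
    stop("unknown residue name: ", paste(tokens[is.na(out)], collapse = ", "),
      call. = FALSE
    )
  }
  paste(out, collapse = "")
}

one_to_three <- function(code, sep = "") {
  letters1 <- strsplit(code, "")[[1]]
  out <- AA_ONE_TO_THREE[letters1]
  if (anyNA(out)) {
    stop("no three-letter name for residue code: ",
      paste(letters1[is.na(out)], collapse = ", "),
      call. = FALSE
    )
  }
  paste(out, collapse = sep)
}

new_segments <- function(start = integer(), end = integer(),
                         original = character(), resulting = character(),
                         flank_left = NA_character_, flank_right = NA_character_) {
  tibble::tibble(
    start = as.integer(start), end = as.integer(end),
    original = original, resulting = resulting,
    flank_left = flank_left, flank_right = flank_right
  )
}

# split a concatenated or underscore-separated run of three-letter names
split_aa3_run <- function(x) {
  regmatches(x, gregexpr(RX_AA3, x))[[1]]
}

parse_simple_change <- function(body) {
  # insertion: Lys2_Gly3insGlnSer
  m <- regexec(sprintf("^(%s)(\\d+)_(%s)(\\d+)ins((?:%s)+)$", RX_AA3, RX_AA3, RX_AA3), body)[[1]]
  if (m[1] != -1L) {
    g <- regmatches(body, list(m))[[1]]
    p1 <- as.integer(g[3]); p2 <- as.integer(g[5])
    if (p2 != p1 + 1L) {
      stop("insertion flanks must be adjacent positions: ", body, call. = FALSE)
    }
    return(new_segments(p1, p2,
      original = "", resulting = three_to_one(split_aa3_run(g[6])),
      flank_left = AA_THREE_TO_ONE[[g[2]]], flank_right = AA_THREE_TO_ONE[[g[4]]]
    ))
  }
  # two-residue deletion: Cys12_Ser13del
  m <- regexec(sprintf("^(%s)(\\d+)_(%s)(\\d+)del$", RX_AA3, RX_AA3), body)[[1]]
  if (m[1] != -1L) {
    g <- regmatches(body, list(m))[[1]]
    p1 <- as.integer(g[3]); p2 <- as.integer(g[5])
    if (p2 != p1 + 1L) {
      stop(
        "deletion ranges longer than two residues are not representable in ",
        "this label grammar: ", body,
        call. = FALSE
      )
    }
    return(new_segments(p1, p2, original = three_to_one(c(g[2], g[4])), resulting = ""))
  }
  # single deletion: Arg12del
  m <- regexec(sprintf("^(%s)(\\d+)del$", RX_AA3), body)[[1]]
  if (m[1] != -1L) {
    g <- regmatches(body, list(m))[[1]]
    p <- as.integer(g[3])
    return(new_segments(p, p, original = three_to_one(g[2]), resulting = ""))
  }
  # single substitution: Arg725Glu
  m <- regexec(sprintf("^(%s)(\\d+)(%s)$", RX_AA3, RX_AA3), body)[[1]]
  if (m[1] != -1L) {
    g <- regmatches(body, list(m))[[1]]
    p <- as.integer(g[3])
    return(new_segments(p, p,
      original = three_to_one(g[2]), resulting = three_to_one(g[4])
    ))
  }
  # contiguous multi-residue substitution: Cys_Ser215-216Ala_Ala
  m <- regexec(sprintf(
    "^((?:%s)(?:_(?:%s))*)(\\d+)-(\\d+)((?:%s)(?:_(?:%s))*)$",
    RX_AA3, RX_AA3, RX_AA3, RX_AA3
  ), body)[[1]]
  if (m[1] != -1L) {
    g <- regmatches(body, list(m))[[1]]
    p1 <- as.integer(g[3]); p2 <- as.integer(g[4])
    if (p2 < p1) stop("range end before start: ", body, call. = FALSE)
    original <- three_to_one(split_aa3_run(g[2]))
    if (nchar(original) != p2 - p1 + 1L) {
      stop(
        "original residue count does not match range length: ", body,
        call. = FALSE
      )
    }
    return(new_segments(p1, p2,
      original = original, resulting = three_to_one(split_aa3_run(g[5]))
    ))
  }
  stop("unrecognized protein-change syntax: '", body, "'", call. = FALSE)
}

parse_label_strict <- function(label) {
  if (!startsWith(label, "p.")) {
    stop("label must start with 'p.': '", label, "'", call. = FALSE)
  }
  body <- substring(label, 3L)
  if (grepl("^\\[.*\\]$", body)) {
    inner <- strsplit(substring(body, 2L, nchar(body) - 1L), ";", fixed = TRUE)[[1]]
    if (length(inner) < 2L) {
      stop("bracketed multi-variant label needs at least two changes: ", label,
        call. = FALSE
      )
    }
    segments <- dplyr::bind_rows(lapply(inner, parse_simple_change))
    segments <- segments[order(segments$start), ]
    list(segments = segments, variant_form = "multi_bracket")
  } else {
    segments <- parse_simple_change(body)
    form <- if (segments$end[1] > segments$start[1] && segments$original[1] != "" &&
      segments$resulting[1] != "") {
      "contiguous_multi"
    } else {
      "single"
    }
    list(segments = segments, variant_form = form)
  }
}

# lenient-mode repairs for legacy free-text labels
repair_label <- function(label) {
  repairs <- character(0)
  fixed <- trimws(label)
  fixed <- gsub("\\s+", "", fixed)
  if (fixed != label) repairs <- c(repairs, "removed stray whitespace")
  dedashed <- gsub("–", "-", fixed)
  if (dedashed != fixed) repairs <- c(repairs, "replaced en-dash with hyphen")
  fixed <- dedashed
  # residue names in wrong case (arg, ARG -> Arg); leaves del/ins untouched
  rx <- sprintf(
    "(?i)(?<![A-Za-z])(%s)(?![A-Za-z])",
    paste(names(AA_THREE_TO_ONE), collapse = "|")
  )
  recased <- fixed
  hits <- gregexpr(rx, recased, perl = TRUE)
  toks <- regmatches(recased, hits)[[1]]
  if (length(toks) > 0) {
    proper <- paste0(toupper(substr(toks, 1, 1)), tolower(substr(toks, 2, 3)))
    if (!identical(proper, toks)) {
      regmatches(recased, hits) <- list(proper)
      repairs <- c(repairs, "recased residue names")
    }
  }
  fixed <- recased
  if (grepl("^P\\.", fixed)) {
    fixed <- sub("^P\\.", "p.", fixed)
    repairs <- c(repairs, "lowercased 'p.' prefix")
  }
  list(label = fixed, repairs = repairs)
}

#' Parse an HGVS-style protein-change label
#'
#' @param label A protein-change string beginning with `"p."`.
#' @param strict If `TRUE` (default), malformed labels raise an error. In
#'   lenient mode (`strict = FALSE`), a small set of legacy-label repairs is
#'   attempted (stray whitespace, en-dash ranges, mis-cased residue names) and
#'   the result carries a non-empty `warnings` element exactly when strict
#'   parsing of the original string would have failed; unrepairable labels
#'   return zero segments plus the failure message.
#' @return A list of class `hgvs_parse` with elements `segments` (tibble with
#'   columns `start`, `end`, `original`, `resulting` and, for insertions,
#'   `flank_left`/`flank_right`), `variant_form` (`"single"`,
#'   `"contiguous_multi"` or `"multi_bracket"`) and `warnings`.
#' @export
#' @examples
#' parse_hgvs_label("p.Arg725Glu")$segments
#' parse_hgvs_label("p.[Asn31His;Ala60Val]")$segments
parse_hgvs_label <- function(label, strict = TRUE) {
  stopifnot(is.character(label), length(label) == 1L)
  if (strict) {
    res <- parse_label_strict(label)
    res$warnings <- character(0)
    class(res) <- "hgvs_parse"
    return(res)
  }
  res <- tryCatch(parse_label_strict(label), error = function(e) e)
  if (!inherits(res, "error")) {
    res$warnings <- character(0)
    class(res) <- "hgvs_parse"
    return(res)
  }
  rep <- repair_label(label)
  res2 <- tryCatch(parse_label_strict(rep$label), error = function(e) e)
  if (!inherits(res2, "error")) {
    res2$warnings <- c(rep$repairs, if (length(rep$repairs) == 0) conditionMessage(res))
    class(res2) <- "hgvs_parse"
    return(res2)
  }
  out <- list(
    segments = new_segments(),
    variant_form = "single",
    warnings = c(rep$repairs, conditionMessage(res2))
  )
  class(out) <- "hgvs_parse"
  out
}

format_segment_body <- function(start, end, original, resulting,
                                flank_left = NA, flank_right = NA) {
  if (original != "" && resulting != "") {
    if (start == end && nchar(original) == 1L) {
      paste0(one_to_three(original), start, one_to_three(resulting))
    } else {
      paste0(
        one_to_three(original, sep = "_"), start, "-", end,
        one_to_three(resulting, sep = "_")
      )
    }
  } else if (resulting == "" && original != "") {
    if (start == end) {
      paste0(one_to_three(original), start, "del")
    } else if (end == start + 1L && nchar(original) == 2L) {
      paste0(
        one_to_three(substr(original, 1, 1)), start, "_",
        one_to_three(substr(original, 2, 2)), end, "del"
      )
    } else {
      stop(
        "deletions spanning more than two residues cannot be expressed ",
        "in the label grammar (span ", start, "-", end, ")",
        call. = FALSE
      )
    }
  } else if (original == "" && resulting != "") {
    if (is.na(flank_left) || is.na(flank_right)) {
      stop(
        "insertion segments need flank_left/flank_right residues to be ",
        "formatted as a label",
        call. = FALSE
      )
    }
    paste0(
      one_to_three(flank_left), start, "_", one_to_three(flank_right), end,
      "ins", one_to_three(resulting)
    )
  } else {
    stop("segment with empty original and resulting sequence", call. = FALSE)
  }
}

#' Format change segments as an HGVS-style label
#'
#' Inverse of [parse_hgvs_label()]: a single substitution yields
#' `"p.Thr2Ala"`, a contiguous multi-residue substitution the underscore/range
#' form, and multiple segments the bracketed semicolon form. For canonical
#' labels, `format_hgvs_label(parse_hgvs_label(x)$segments) == x`.
#'
#' @param segments Tibble of change segments (`start`, `end`, `original`,
#'   `resulting`, optionally `flank_left`/`flank_right` for insertions).
#' @return A single label string.
#' @export
#' @examples
#' format_hgvs_label(data.frame(start = 2, end = 2, original = "T", resulting = "A"))
format_hgvs_label <- function(segments) {
  segments <- tibble::as_tibble(segments)
  if (nrow(segments) == 0L) stop("empty segment list", call. = FALSE)
  if (!"flank_left" %in% names(segments)) segments$flank_left <- NA_character_
  if (!"flank_right" %in% names(segments)) segments$flank_right <- NA_character_
  segments <- segments[order(segments$start), ]
  bodies <- mapply(
    format_segment_body,
    segments$start, segments$end, segments$original, segments$resulting,
    segments$flank_left, segments$flank_right
  )
  if (length(bodies) == 1L) {
    paste0("p.", bodies)
  } else {
    paste0("p.[", paste(bodies, collapse = ";"), "]")
  }
}

#' Check agreement between a feature's label and its stored segments
#'
#' Curated records store the sequence change twice: as an HGVS-style label
#' and as explicit range/original/resulting columns. Legacy labels were
#' manually typed and prone to typographical errors, so any disagreement is
#' reported as data (issues), never silently resolved.
#'
#' @param features A mutations table (one row per contiguous segment, rows of
#'   one feature sharing `feature_ac`), see [read_mutations_table()].
#' @return A tibble of issues (`feature_ac`, `severity`, `code`, `message`);
#'   zero rows means every label agrees with its stored segments.
#' @export
validate_label_consistency <- function(features) {
  issues <- list()
  add <- function(ac, severity, code, message) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      feature_ac = ac, severity = severity, code = code, message = message
    )
  }
  for (ac in unique(features$feature_ac)) {
    rows <- features[features$feature_ac == ac, ]
    label <- rows$feature_label[1]
    parsed <- parse_hgvs_label(label, strict = FALSE)
    if (nrow(parsed$segments) == 0L) {
      add(ac, "error", "label-unparseable", paste0(
        "label '", label, "' could not be parsed: ",
        paste(parsed$warnings, collapse = "; ")
      ))
      next
    }
    if (length(parsed$warnings) > 0) {
      add(ac, "warning", "label-nonstandard", paste0(
        "label '", label, "' needed repairs: ",
        paste(parsed$warnings, collapse = "; ")
      ))
    }
    stored <- rows[order(rows$start), c("start", "end", "original_seq", "resulting_seq")]
    lab <- parsed$segments[order(parsed$segments$start), ]
    if (nrow(stored) != nrow(lab)) {
      add(ac, "error", "segment-count-mismatch", sprintf(
        "label '%s' describes %d segment(s) but %d row(s) are stored",
        label, nrow(lab), nrow(stored)
      ))
      next
    }
    for (i in seq_len(nrow(stored))) {
      if (stored$start[i] != lab$start[i] || stored$end[i] != lab$end[i]) {
        add(ac, "error", "range-mismatch", sprintf(
          "label '%s' gives range %d-%d but columns store %d-%d",
          label, lab$start[i], lab$end[i], stored$start[i], stored$end[i]
        ))
      } else {
        if (stored$original_seq[i] != lab$original[i]) {
          add(ac, "error", "original-mismatch", sprintf(
            "label '%s' gives original '%s' at %d but columns store '%s'",
            label, lab$original[i], lab$start[i], stored$original_seq[i]
          ))
        }
        if (stored$resulting_seq[i] != lab$resulting[i]) {
          add(ac, "error", "resulting-mismatch", sprintf(
            "label '%s' gives resulting '%s' at %d but columns store '%s'",
            label, lab$resulting[i], lab$start[i], stored$resulting_seq[i]
          ))
        }
      }
    }
  }
  if (length(issues) == 0L) {
    tibble::tibble(
      feature_ac = character(), severity = character(),
      code = character(), message = character()
    )
  } else {
    dplyr::bind_rows(issues)
  }
}
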