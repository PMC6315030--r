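#' @name mutations_tsv
#' @title The tab-delimited mutations flat file
#'
#' @description
#' Mutation annotations are exchanged as a UTF-8, tab-delimited table with a
#' header row. Each line represents a single continuous section of affected
#' sequence; a feature spanning several discontiguous positions is spread
#' over several lines sharing the same `feature_ac`. Coordinates are 1-based
#' inclusive; ranges are written `"725-725"` (an en-dash is accepted on
#' read); `"-"` denotes an empty original (insertion) or resulting
#' (deletion) sequence.
#'
#' Dialect columns, in order: `feature_ac`, `feature_label`, `feature_range`,
#' `original_seq`, `resulting_seq`, `feature_type` (term name plus MI id),
#' `feature_annotation`, `protein_ac`, `protein_symbol`, `protein_taxid`,
#' `interaction_id`, `partner_acs` (`";"`-separated accessions, each with an
#' optional `"|proteoform"` suffix), `detection_method`, `pubmed_id`,
#' `source_db`. This column list is a documented dialect (version
#' `r MUT_TSV_DIALECT`) of the public flat-file layout, not a claim of
#' byte-compatibility with any specific release.
NULL

MUT_TSV_DIALECT <- "ppimutr-1"

MUT_TSV_COLUMNS <- c(
  "feature_ac", "feature_label", "feature_range", "original_seq",
  "resulting_seq", "feature_type", "feature_annotation", "protein_ac",
  "protein_symbol", "protein_taxid", "interaction_id", "partner_acs",
  "detection_method", "pubmed_id", "source_db"
)

# in-memory layout: feature_range split into integer start/end
MUT_COLUMNS <- c(
  "feature_ac", "feature_label", "start", "end", "original_seq",
  "resulting_seq", "feature_type", "feature_annotation", "protein_ac",
  "protein_symbol", "protein_taxid", "interaction_id", "partner_acs",
  "detection_method", "pubmed_id", "source_db"
)

# metadata columns that must agree across the rows of one multi-segment feature
MUT_META_COLUMNS <- setdiff(
  MUT_COLUMNS, c("start", "end", "original_seq", "resulting_seq")
)

#' Read a mutations flat file
#'
#' @param path Path to a tab-delimited mutations file (dialect described in
#'   [mutations_tsv]).
#' @return A tibble with one row per contiguous segment and the in-memory
#'   columns (`feature_range` split into integer `start`/`end`, `"-"` cells
#'   decoded to empty strings). Rows sharing a `feature_ac` form one
#'   multi-segment feature; their metadata columns are checked for agreement
#'   and a read error listing the offending rows is raised if they conflict.
#' @export
read_mutations_table <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  missing <- setdiff(MUT_TSV_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  m <- regexec("^\\s*(\\d+)\\s*[-–]\\s*(\\d+)\\s*$", raw$feature_range)
  parts <- regmatches(raw$feature_range, m)
  bad <- which(lengths(parts) == 0L)
  if (length(bad) > 0 && nrow(raw) > 0) {
    stop("non-numeric feature range on data row(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  tbl <- tibble::as_tibble(raw)
  tbl$start <- vapply(parts, function(g) as.integer(g[2]), integer(1))
  tbl$end <- vapply(parts, function(g) as.integer(g[3]), integer(1))
  if (nrow(tbl) > 0 && any(tbl$end < tbl$start)) {
    stop("feature range end before start on data row(s): ",
      paste(which(tbl$end < tbl$start), collapse = ", "),
      call. = FALSE
    )
  }
  tbl$original_seq <- ifelse(tbl$original_seq == "-", "", tbl$original_seq)
  tbl$resulting_seq <- ifelse(tbl$resulting_seq == "-", "", tbl$resulting_seq)
  tbl <- tbl[, MUT_COLUMNS]
  # rows of one feature must carry identical metadata
  for (ac in unique(tbl$feature_ac[duplicated(tbl$feature_ac)])) {
    rows <- which(tbl$feature_ac == ac)
    meta <- tbl[rows, MUT_META_COLUMNS]
    if (nrow(unique(meta)) != 1L) {
      stop(
        "unmergeable duplicate rows for feature ", ac,
        " (conflicting metadata) on data row(s): ",
        paste(rows, collapse = ", "),
        call. = FALSE
      )
    }
  }
  tbl
}

#' Write a mutations flat file
#'
#' One row is written per contiguous segment, so multi-segment features emit
#' several rows with identical `feature_ac` and label;
#' `read_mutations_table()` of the written file restores the input table.
#'
#' @param features In-memory mutations table, see [read_mutations_table()].
#' @param path Output path.
#' @return Invisibly, the number of data rows written (the total segment
#'   count across features).
#' @export
write_mutations_table <- function(features, path) {
  out <- tibble::as_tibble(features)
  out$feature_range <- paste0(out$start, "-", out$end)
  out$original_seq <- ifelse(out$original_seq == "", "-", out$original_seq)
  out$resulting_seq <- ifelse(out$resulting_seq == "", "-", out$resulting_seq)
  out <- out[, MUT_TSV_COLUMNS]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(nrow(out))
}

#' Read a proteome from FASTA
#'
#' @param path FASTA file of protein sequences. The accession is taken as the
#'   first whitespace-delimited token of each header; isoform-suffixed
#'   accessions (`"P12345-2"`) are kept verbatim as distinct proteins.
#' @return Named character vector of uppercase residue strings.
#' @export
read_proteome_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write a proteome to FASTA
#'
#' @param proteome Named character vector of residue strings.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_proteome_fasta <- function(proteome, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

#' Validate a mutations table against a proteome
#'
#' Desk-scale counterpart of the quality-control step applied to curated
#' records: every finding is reported as an issue, never as an exception, so
#' a whole dataset can be screened in one pass. Checks per feature: range
#' within the protein length, stored original residues equal to the protein
#' sequence at the stated coordinates, segment length equal to range length,
#' label/column concordance (via [validate_label_consistency()]) and unknown
#' effect terms. Features on proteins absent from `proteome` yield a
#' `"protein-unavailable"` warning.
#'
#' @param features Mutations table.
#' @param proteome Named character vector of sequences
#'   (see [read_proteome_fasta()]).
#' @param vocabulary Effect vocabulary, see [effect_vocabulary()].
#' @return Tibble of issues (`feature_ac`, `severity`, `code`, `message`).
#' @export
validate_dataset <- function(features, proteome,
                             vocabulary = effect_vocabulary()) {
  issues <- list()
  add <- function(ac, severity, code, message) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      feature_ac = ac, severity = severity, code = code, message = message
    )
  }
  for (i in seq_len(nrow(features))) {
    row <- features[i, ]
    seq <- unname(proteome[row$protein_ac])
    if (is.na(seq)) {
      add(
        row$feature_ac, "warning", "protein-unavailable",
        paste0("protein ", row$protein_ac, " not present in supplied proteome")
      )
      next
    }
    if (row$end > nchar(seq)) {
      add(row$feature_ac, "error", "out-of-bounds", sprintf(
        "range %d-%d exceeds %s length %d",
        row$start, row$end, row$protein_ac, nchar(seq)
      ))
      next
    }
    span <- row$end - row$start + 1L
    if (row$original_seq != "" && nchar(row$original_seq) != span) {
      add(row$feature_ac, "error", "range-length-mismatch", sprintf(
        "original sequence '%s' does not span range %d-%d",
        row$original_seq, row$start, row$end
      ))
      next
    }
    if (row$original_seq != "" &&
      substr(seq, row$start, row$end) != row$original_seq) {
      add(row$feature_ac, "error", "sequence-mismatch", sprintf(
        "original '%s' at %d-%d but %s has '%s'",
        row$original_seq, row$start, row$end, row$protein_ac,
        substr(seq, row$start, row$end)
      ))
    }
  }
  per_feature <- unique(features[, c("feature_ac", "feature_type")])
  unknown <- is.na(effect_category(per_feature$feature_type, vocabulary))
  for (j in which(unknown)) {
    add(
      per_feature$feature_ac[j], "error", "unknown-effect-term",
      paste0("feature type '", per_feature$feature_type[j], "' is not in the effect vocabulary")
    )
  }
  out <- dplyr::bind_rows(c(list(validate_label_consistency(features)), issues))
  out[order(out$feature_ac, out$code), ]
}

# --- auxiliary tables -------------------------------------------------------

#' Read or write the auxiliary tab-delimited tables
#'
#' Variant catalogues (`protein_ac`, `position`, `reference`, `alternate`,
#' `disease_linked` as 0/1, `external_id`, `source`), phosphosite tables
#' (`protein_ac`, `position`, `residue`) and interface-region tables
#' (`protein_ac`, `start`, `end`, `source` with source `"predicted"` or
#' `"curated"`). All coordinates are 1-based inclusive.
#'
#' @param path File path.
#' @param x Table to write.
#' @return The read functions return tibbles with typed columns; the write
#'   functions return `path` invisibly.
#' @name aux_tables
NULL

#' @rdname aux_tables
#' @export
read_variant_catalogue <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_ac = readr::col_character(), position = readr::col_integer(),
      reference = readr::col_character(), alternate = readr::col_character(),
      disease_linked = readr::col_integer(),
      external_id = readr::col_character(), source = readr::col_character()
    ),
    na = character(), progress = FALSE
  )
  tbl$disease_linked <- tbl$disease_linked == 1L
  tbl
}

#' @rdname aux_tables
#' @export
write_variant_catalogue <- function(x, path) {
  x$disease_linked <- as.integer(x$disease_linked)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname aux_tables
#' @export
read_phosphosite_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_ac = readr::col_character(), position = readr::col_integer(),
      residue = readr::col_character()
    ),
    na = character(), progress = FALSE
  )
}

#' @rdname aux_tables
#' @export
write_phosphosite_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname aux_tables
#' @export
read_interface_regions <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_ac = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), source = readr::col_character()
    ),
    na = character(), progress = FALSE
  )
}

#' @rdname aux_tables
#' @export
write_interface_regions <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

# --- feature-level view -----------------------------------------------------

# canonical key for a sequence change: segments sorted by start
change_key <- function(start, end, original, resulting) {
  ord <- order(start)
  paste(
    sprintf("%d:%d:%s>%s", start[ord], end[ord], original[ord], resulting[ord]),
    collapse = "|"
  )
}

# canonical key for a partner multiset (proteoform tags kept verbatim)
partner_key <- function(partner_acs) {
  vapply(strsplit(partner_acs, ";", fixed = TRUE), function(p) {
    paste(sort(trimws(p)), collapse = ";")
  }, character(1))
}

# one row per feature: metadata + segments list-column + canonical keys
collapse_features <- function(features) {
  tbl <- tibble::as_tibble(features)
  # keep first-appearance feature order, sort segments by start within feature
  ord <- order(match(tbl$feature_ac, unique(tbl$feature_ac)), tbl$start)
  tbl <- tbl[ord, ]
  first_idx <- which(!duplicated(tbl$feature_ac))
  g <- factor(tbl$feature_ac, levels = tbl$feature_ac[first_idx])
  meta <- tbl[first_idx, MUT_META_COLUMNS]
  meta$segments <- unname(split(
    tbl[, c("start", "end", "original_seq", "resulting_seq")], g
  ))
  meta$n_segments <- tabulate(g)
  # vectorized key for the common single-segment case
  key <- sprintf(
    "%d:%d:%s>%s",
    tbl$start[first_idx], tbl$end[first_idx],
    tbl$original_seq[first_idx], tbl$resulting_seq[first_idx]
  )
  multi <- which(meta$n_segments > 1L)
  key[multi] <- vapply(meta$segments[multi], function(s) {
    change_key(s$start, s$end, s$original_seq, s$resulting_seq)
  }, character(1))
  meta$change_key <- key
  meta$partner_set <- partner_key(meta$partner_acs)
  meta
}
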