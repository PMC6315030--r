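# hand-built features mirroring the published flat-file example: six
# features, one of which (EBI-4370347) spans two positions over two rows and
# carries a deliberate label/column conflict (stored original "D" against
# label Asn31) that the toolkit must flag, not resolve
table1_features <- function(faithful = TRUE) {
  rows <- tibble::tribble(
    ~feature_ac,    ~feature_label,             ~start, ~end, ~original_seq, ~resulting_seq, ~feature_type,
    "EBI-10828532", "p.Arg725Glu",              725L,   725L, "R",           "E",            "mutation(MI:0118)",
    "EBI-985220",   "p.Ile114Gly",              114L,   114L, "I",           "G",            "mutation increasing(MI:0382)",
    "EBI-4370347",  "p.[Asn31His;Ala60Val]",    31L,    31L,  "D",           "H",            "mutation increasing(MI:0382)",
    "EBI-4370347",  "p.[Asn31His;Ala60Val]",    60L,    60L,  "A",           "V",            "mutation increasing(MI:0382)",
    "EBI-10688294", "p.Thr2Ala",                2L,     2L,   "T",           "A",            "mutation decreasing rate(MI:1130)",
    "EBI-9635600",  "p.Cys_Ser215-216Ala_Ala",  215L,   216L, "CS",          "AA",           "mutation disrupting(MI:0573)"
  )
  if (!faithful) rows$original_seq[3] <- "N" # repaired label/column conflict
  rows$feature_annotation <- c("", "", "kd: 11e-9M", "kd: 11e-9M", "", "")
  rows$protein_ac <- c("P10001", "P10002", "P10003", "P10003", "P10004", "P10005")
  rows$protein_symbol <- paste0("GEN", match(rows$protein_ac, unique(rows$protein_ac)))
  rows$protein_taxid <- "9606"
  rows$interaction_id <- paste0("EBI-I", match(rows$feature_ac, unique(rows$feature_ac)))
  rows$partner_acs <- c("P20001", "P20002", "P20003", "P20003", "P20004", "P20005")
  rows$detection_method <- "two hybrid(MI:0018)"
  rows$pubmed_id <- c("11111111", "22222222", "33333333", "33333333", "44444444", "55555555")
  rows$source_db <- "IntAct"
  rows[, ppimutr:::MUT_COLUMNS]
}

# synthetic proteome agreeing with the stored columns of table1_features()
table1_proteome <- function(faithful = TRUE) {
  set.seed(1234)
  plant <- function(len, at, what) {
    s <- paste(sample(c(
      "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
    ), len, replace = TRUE), collapse = "")
    for (k in seq_along(at)) {
      substr(s, at[k], at[k] + nchar(what[k]) - 1L) <- what[k]
    }
    s
  }
  c(
    P10001 = plant(760, 725, "R"),
    P10002 = plant(300, 114, "I"),
    P10003 = plant(120, c(31, 60), c(if (faithful) "D" else "N", "A")),
    P10004 = plant(80, 2, "T"),
    P10005 = plant(260, 215, "CS")
  )
}

# one-row feature builder for hand-made grouping/consistency cases
mk_feature <- function(ac, type, protein = "P00001", partners = "P00002",
                       start = 10L, end = start, original = "R",
                       resulting = "A", label = NULL,
                       interaction = paste0("I-", ac), pub = "99999999",
                       taxid = "9606") {
  tibble::tibble(
    feature_ac = ac,
    feature_label = label %||% format_hgvs_label(
      data.frame(start = start, end = end, original = original, resulting = resulting)
    ),
    start = as.integer(start), end = as.integer(end),
    original_seq = original, resulting_seq = resulting,
    feature_type = type,
    feature_annotation = "",
    protein_ac = protein, protein_symbol = "GEN", protein_taxid = taxid,
    interaction_id = interaction, partner_acs = partners,
    detection_method = "two hybrid(MI:0018)", pubmed_id = pub,
    source_db = "IntAct"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mini fixture cached for the whole test session
mini_fx <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_fixture(mini_fixture_spec(), seed = 42)
    cache
  }
})
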