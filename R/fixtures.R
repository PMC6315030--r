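#' @name synth_fixtures
#' @title Seeded synthetic fixtures with retrievable ground truth
#'
#' @description
#' Every pipeline stage is testable offline against generated data whose
#' injected properties are known exactly: a synthetic proteome, a mutations
#' table with controlled effect-category counts, per-organism composition
#' and evidence-group structure, a variant catalogue with a controlled
#' full/positional/partial match structure, phosphosite and interface
#' tables with known class labels, and an old/new proteome pair with known
#' shifts for the coordinate-update pipeline. Generation is deterministic
#' under a fixed seed; identical `(spec, seed)` produce identical outputs.
NULL

#' Per-organism composition of the default fixture
#'
#' Eight rows — seven main model organisms plus one pseudo-taxon `"others"`
#' standing for the long tail of species — giving, per organism, the number
#' of annotations, distinct sequence changes, affected proteins, affected
#' interactions and source publications the generator realizes exactly.
#' The defaults emulate the composition of the public curated dataset.
#'
#' @return A tibble with columns `taxid`, `annotations`, `changes`,
#'   `proteins`, `interactions`, `publications`.
#' @export
default_organism_table <- function() {
  tibble::tribble(
    ~taxid,    ~annotations, ~changes, ~proteins, ~interactions, ~publications,
    "9606",    16861L,       7955L,    2095L,     8268L,         2219L,
    "10090",   2236L,        1406L,    482L,      1248L,         509L,
    "559292",  2029L,        1144L,    363L,      1069L,         326L,
    "3702",    1172L,        546L,     187L,      590L,          189L,
    "83333",   979L,         614L,     143L,      374L,          148L,
    "10116",   562L,         354L,     142L,      341L,          160L,
    "7227",    359L,         232L,     100L,      214L,          92L,
    "others",  3670L,        2396L,    841L,      1195L,         855L
  )
}

#' Fixture generation parameters
#'
#' The defaults are the study conditions of the emulated dataset: the
#' per-category effect counts (27,868 annotations in total), the
#' per-organism composition of [default_organism_table()], 65 deletion and
#' 83 insertion annotations, an evidence-group scenario of 7,212
#' multiply-tested groups of which 71 mix a directional effect with
#' no-effect reports and 19 are directly antagonistic, and a human
#' variant-overlap scenario of 16,765 annotations over 8,820 distinct
#' changes in 1,990 proteins, of which 4,804 annotations (1,073 changes)
#' are fully matched and 2,671 annotations (1,415 changes) match
#' positionally or partially. Counts not fixed by those conditions
#' (phosphosite, interface and coordinate-update fixture sizes, protein
#' lengths) use modest desk-scale defaults.
#'
#' Feasibility is checked eagerly: mutually impossible counts (for example
#' more multiply-tested groups than spare annotations, or an effect budget
#' too small for the required antagonistic pairs) raise an error naming the
#' violated constraint.
#'
#' @param effects Named counts of annotations per effect category.
#' @param organisms Per-organism composition table
#'   (see [default_organism_table()]).
#' @param consistency List: `n_multi_groups`, `n_mild`, `n_conflict`.
#' @param indels List: `n_deletions`, `n_insertions` (taken from
#'   single-tested changes).
#' @param n_multi_segment Number of two-segment (bracket-label) features.
#' @param variants Variant-overlap scenario: `n_annotations`, `n_changes`,
#'   `n_proteins`, `n_full_annotations`, `n_full_changes`,
#'   `n_pos_partial_annotations`, `n_pos_partial_changes`, `n_decoys`.
#' @param phospho Phosphosite scenario: `n_proteins`, `n_disrupting`,
#'   `n_mimetic`, `n_other`, `n_off_site`.
#' @param interfaces Interface scenario: `n_proteins`, `n_inside`,
#'   `n_outside`.
#' @param qc Coordinate-update scenario: `n_unchanged`, `n_shifted`,
#'   `n_scrambled`, `shift_offset`, `context`.
#' @param protein_length Two-element range of synthetic protein lengths
#'   (residues); background sequences are drawn uniformly over the 20
#'   standard residues.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(effects = c(
                           disrupting = 10976, decreasing = 8553,
                           increasing = 2256, causing = 188,
                           no_effect = 3057, undefined = 2838
                         ),
                         organisms = default_organism_table(),
                         consistency = list(
                           n_multi_groups = 7212, n_mild = 71, n_conflict = 19
                         ),
                         indels = list(n_deletions = 65, n_insertions = 83),
                         n_multi_segment = 100,
                         variants = list(
                           n_annotations = 16765, n_changes = 8820,
                           n_proteins = 1990,
                           n_full_annotations = 4804, n_full_changes = 1073,
                           n_pos_partial_annotations = 2671,
                           n_pos_partial_changes = 1415,
                           n_decoys = 500
                         ),
                         phospho = list(
                           n_proteins = 40, n_disrupting = 60, n_mimetic = 30,
                           n_other = 20, n_off_site = 20
                         ),
                         interfaces = list(
                           n_proteins = 30, n_inside = 60, n_outside = 40
                         ),
                         qc = list(
                           n_unchanged = 60, n_shifted = 25, n_scrambled = 15,
                           shift_offset = 2, context = 10
                         ),
                         protein_length = c(300, 800)) {
  spec <- structure(
    list(
      effects = effects, organisms = organisms, consistency = consistency,
      indels = indels, n_multi_segment = n_multi_segment, variants = variants,
      phospho = phospho, interfaces = interfaces, qc = qc,
      protein_length = protein_length
    ),
    class = "fixture_spec"
  )
  validate_fixture_spec(spec)
  spec
}

#' A small fixture specification for fast checks
#'
#' Same structure as [fixture_spec()] at a fraction of the size: two
#' organisms, 180 annotations over 120 changes, 40 multiply-tested groups
#' (6 mixed with no-effect, 3 antagonistic) and a 150-annotation variant
#' scenario. Intended for unit tests and interactive exploration where the
#' full-scale defaults would be unnecessarily slow.
#'
#' @return A list of class `fixture_spec`.
#' @export
mini_fixture_spec <- function() {
  fixture_spec(
    effects = c(
      disrupting = 70, decreasing = 50, increasing = 20, causing = 5,
      no_effect = 20, undefined = 15
    ),
    organisms = tibble::tribble(
      ~taxid,  ~annotations, ~changes, ~proteins, ~interactions, ~publications,
      "9606",  120L,         80L,      20L,       60L,           15L,
      "10090", 60L,          40L,      10L,       30L,           8L
    ),
    consistency = list(n_multi_groups = 40, n_mild = 6, n_conflict = 3),
    indels = list(n_deletions = 3, n_insertions = 3),
    n_multi_segment = 4,
    variants = list(
      n_annotations = 150, n_changes = 90, n_proteins = 25,
      n_full_annotations = 30, n_full_changes = 18,
      n_pos_partial_annotations = 24, n_pos_partial_changes = 16,
      n_decoys = 40
    ),
    phospho = list(
      n_proteins = 8, n_disrupting = 12, n_mimetic = 6, n_other = 4,
      n_off_site = 6
    ),
    interfaces = list(n_proteins = 6, n_inside = 12, n_outside = 8),
    qc = list(
      n_unchanged = 10, n_shifted = 5, n_scrambled = 3,
      shift_offset = 2, context = 10
    ),
    protein_length = c(120, 250)
  )
}

validate_fixture_spec <- function(spec) {
  fail <- function(...) stop("infeasible fixture spec: ", ..., call. = FALSE)
  eff <- spec$effects
  orgs <- spec$organisms
  cons <- spec$consistency
  if (!setequal(names(eff), EFFECT_CATEGORIES)) {
    fail("effects must name all six categories")
  }
  if (sum(eff) != sum(orgs$annotations)) {
    fail(sprintf(
      "effect counts sum to %d but organism annotations sum to %d",
      sum(eff), sum(orgs$annotations)
    ))
  }
  with(orgs, {
    if (any(changes < proteins)) fail("each protein needs at least one sequence change")
    if (any(annotations < changes)) fail("each sequence change needs at least one annotation")
    if (any(interactions > annotations)) fail("more interactions than annotations")
    if (any(publications > annotations)) fail("more publications than annotations")
  })
  extras <- sum(orgs$annotations) - sum(orgs$changes)
  if (cons$n_multi_groups > extras) {
    fail("n_multi_groups exceeds the spare annotations available for re-testing")
  }
  if (cons$n_multi_groups > sum(orgs$changes)) {
    fail("n_multi_groups exceeds the number of sequence changes")
  }
  if (cons$n_mild + cons$n_conflict > cons$n_multi_groups) {
    fail("n_mild + n_conflict exceeds n_multi_groups")
  }
  neg <- sum(eff[c("disrupting", "decreasing")])
  pos <- sum(eff[c("increasing", "causing")])
  if (cons$n_conflict > pos) fail("not enough positive-direction budget for conflicts")
  if (cons$n_conflict + cons$n_mild > neg) {
    fail("not enough negative-direction budget for conflicts and mild conflicts")
  }
  if (cons$n_mild > eff[["no_effect"]]) fail("not enough no-effect budget for mild conflicts")
  n_singles <- sum(orgs$changes) - cons$n_multi_groups
  if (eff[["undefined"]] > n_singles) {
    fail("undefined annotations exceed single-tested changes")
  }
  if (spec$indels$n_deletions + spec$indels$n_insertions + spec$n_multi_segment > n_singles) {
    fail("indel and multi-segment counts exceed single-tested changes")
  }
  v <- spec$variants
  if (v$n_changes < v$n_proteins) fail("variant scenario: fewer changes than proteins")
  if (v$n_annotations < v$n_changes) fail("variant scenario: fewer annotations than changes")
  if (v$n_full_changes + v$n_pos_partial_changes > v$n_changes) {
    fail("variant scenario: matched changes exceed total changes")
  }
  if (v$n_full_annotations < v$n_full_changes) {
    fail("variant scenario: full annotations not distributable over full changes")
  }
  if (v$n_pos_partial_annotations < v$n_pos_partial_changes) {
    fail("variant scenario: positional/partial annotations not distributable")
  }
  rest_ann <- v$n_annotations - v$n_full_annotations - v$n_pos_partial_annotations
  rest_chg <- v$n_changes - v$n_full_changes - v$n_pos_partial_changes
  if (rest_ann < rest_chg) {
    fail("variant scenario: unmatched annotations not distributable over unmatched changes")
  }
  invisible(spec)
}

# term strings per category; parent term dominates, rate/strength children mixed in
CATEGORY_TERMS <- list(
  disrupting = c(
    "mutation disrupting(MI:0573)",
    "mutation disrupting strength(MI:1128)",
    "mutation disrupting rate(MI:1129)"
  ),
  decreasing = c(
    "mutation decreasing(MI:0119)",
    "mutation decreasing strength(MI:1133)",
    "mutation decreasing rate(MI:1130)"
  ),
  increasing = c(
    "mutation increasing(MI:0382)",
    "mutation increasing strength(MI:1132)",
    "mutation increasing rate(MI:1131)"
  ),
  causing = "mutation causing(MI:2227)",
  no_effect = "mutation with no effect(MI:2226)",
  undefined = "mutation(MI:0118)"
)

term_for_category <- function(categories) {
  vapply(categories, function(cat) {
    terms <- CATEGORY_TERMS[[cat]]
    if (length(terms) == 1L) terms else sample(terms, 1, prob = c(0.8, 0.1, 0.1))
  }, character(1), USE.NAMES = FALSE)
}

DETECTION_METHODS <- c(
  "two hybrid(MI:0018)", "anti bait coimmunoprecipitation(MI:0006)",
  "pull down(MI:0096)", "surface plasmon resonance(MI:0107)"
)
SOURCE_DBS <- c("IntAct", "MINT", "DIP", "UniProt")

sample_other_residue <- function(original, exclude = character(0)) {
  vapply(original, function(o) {
    sample(setdiff(AA_STANDARD, c(o, exclude)), 1)
  }, character(1), USE.NAMES = FALSE)
}

# draw k categories from 1-2 category budgets (mutated in the caller)
draw_categories <- function(budget, cats, k) {
  rem <- budget[cats]
  if (sum(rem) < k) {
    stop("infeasible fixture spec: effect budget exhausted for ",
      paste(cats, collapse = "/"),
      call. = FALSE
    )
  }
  if (length(cats) == 1L) {
    return(rep(cats, k))
  }
  n1 <- stats::rbinom(1, k, rem[1] / sum(rem))
  n1 <- min(n1, rem[1])
  n2 <- k - n1
  if (n2 > rem[2]) {
    n2 <- rem[2]
    n1 <- k - n2
  }
  sample(c(rep(cats[1], n1), rep(cats[2], n2)))
}

DIRECTION_CATS <- list(
  negative = c("disrupting", "decreasing"),
  positive = c("increasing", "causing"),
  neutral = "no_effect"
)

fast_sub_label <- function(pos, original, resulting) {
  paste0(
    "p.", unname(AA_ONE_TO_THREE[original]), pos,
    unname(AA_ONE_TO_THREE[resulting])
  )
}

# ---------------------------------------------------------------------------

generate_main <- function(spec) {
  orgs <- spec$organisms
  cons <- spec$consistency
  n_org <- nrow(orgs)
  extras <- orgs$annotations - orgs$changes

  # allocate multiply-tested groups to organisms: every organism with spare
  # annotations needs at least one, the rest proportional to its spare count
  base <- as.integer(extras > 0)
  if (sum(base) > cons$n_multi_groups && cons$n_multi_groups > 0) {
    stop("infeasible fixture spec: too few multi-tested groups to absorb ",
      "spare annotations in every organism",
      call. = FALSE
    )
  }
  caps <- pmin(orgs$changes, extras)
  m_alloc <- if (cons$n_multi_groups == 0) {
    rep(0L, n_org)
  } else {
    base + allocate_proportional(
      cons$n_multi_groups - sum(base), pmax(extras, 1e-9), caps - base
    )
  }

  proteome <- character(0)
  symbols <- character(0)
  chg_list <- vector("list", n_org)
  prot_counter <- 0L
  for (o in seq_len(n_org)) {
    np <- orgs$proteins[o]
    nc <- orgs$changes[o]
    acs <- sprintf("P%05d", prot_counter + seq_len(np))
    prot_counter <- prot_counter + np
    cpp <- distribute_counts(nc, np)
    lens <- sample(spec$protein_length[1]:spec$protein_length[2], np, replace = TRUE)
    lens <- pmax(lens, 3L * cpp + 20L)
    seqs <- vapply(lens, random_residues, character(1))
    names(seqs) <- acs
    proteome <- c(proteome, seqs)
    symbols <- c(symbols, stats::setNames(sprintf("GEN%d", seq_along(acs) + length(symbols)), acs))
    pos_list <- mapply(function(len, k) sample(2:(len - 2L), k), lens, cpp,
      SIMPLIFY = FALSE
    )
    mult <- rep(1L, nc)
    if (m_alloc[o] > 0) {
      mi <- sample.int(nc, m_alloc[o])
      mult[mi] <- 1L + distribute_counts(orgs$annotations[o] - nc, m_alloc[o])
    } else if (orgs$annotations[o] > nc) {
      stop("infeasible fixture spec: organism ", orgs$taxid[o],
        " has spare annotations but no multi-tested group allocation",
        call. = FALSE
      )
    }
    chg_list[[o]] <- tibble::tibble(
      taxid = orgs$taxid[o],
      protein_ac = rep(acs, cpp),
      pos = as.integer(unlist(pos_list, use.names = FALSE)),
      multiplicity = mult
    )
  }
  chg <- dplyr::bind_rows(chg_list)
  chg$chg_id <- seq_len(nrow(chg))
  chg$len <- nchar(proteome[chg$protein_ac])
  chg$kind <- "sub"

  # indels and two-segment features live on single-tested changes
  singles <- which(chg$multiplicity == 1L)
  special <- sample(
    singles,
    spec$indels$n_deletions + spec$indels$n_insertions + spec$n_multi_segment
  )
  del_idx <- utils::head(special, spec$indels$n_deletions)
  ins_idx <- special[spec$indels$n_deletions + seq_len(spec$indels$n_insertions)]
  seg2_idx <- utils::tail(special, spec$n_multi_segment)
  chg$kind[del_idx] <- "del"
  chg$kind[ins_idx] <- "ins"
  chg$kind[seg2_idx] <- "sub2"

  # segments: base is one single-residue substitution per change
  chg$start <- chg$pos
  chg$end <- chg$pos
  chg$original <- substr(proteome[chg$protein_ac], chg$pos, chg$pos)
  chg$resulting <- sample_other_residue(chg$original)
  # deletions span one or two residues
  del_span <- sample(1:2, length(del_idx), replace = TRUE)
  chg$end[del_idx] <- chg$pos[del_idx] + del_span - 1L
  chg$original[del_idx] <- substr(
    proteome[chg$protein_ac[del_idx]], chg$start[del_idx], chg$end[del_idx]
  )
  chg$resulting[del_idx] <- ""
  # insertions between pos and pos+1
  chg$end[ins_idx] <- chg$pos[ins_idx] + 1L
  chg$original[ins_idx] <- ""
  chg$resulting[ins_idx] <- vapply(
    sample(1:3, length(ins_idx), replace = TRUE), random_residues, character(1)
  )

  # second segment for bracket features, at a distinct position
  pos2 <- ifelse(chg$pos[seg2_idx] + 13L <= chg$len[seg2_idx] - 2L,
    chg$pos[seg2_idx] + 13L, chg$pos[seg2_idx] - 13L
  )
  seg2 <- tibble::tibble(
    chg_id = chg$chg_id[seg2_idx],
    start = as.integer(pos2), end = as.integer(pos2),
    original = substr(proteome[chg$protein_ac[seg2_idx]], pos2, pos2)
  )
  seg2$resulting <- sample_other_residue(seg2$original)

  seg_tbl <- dplyr::bind_rows(
    tibble::tibble(
      chg_id = chg$chg_id, start = chg$start, end = chg$end,
      original = chg$original, resulting = chg$resulting
    ),
    seg2
  )
  seg_tbl <- seg_tbl[order(seg_tbl$chg_id, seg_tbl$start), ]

  # labels
  lab <- fast_sub_label(chg$pos, substr(chg$original, 1, 1), chg$resulting)
  aa3 <- function(x) unname(AA_ONE_TO_THREE[x])
  one_del <- del_idx[del_span == 1L]
  two_del <- del_idx[del_span == 2L]
  lab[one_del] <- paste0("p.", aa3(chg$original[one_del]), chg$pos[one_del], "del")
  lab[two_del] <- paste0(
    "p.", aa3(substr(chg$original[two_del], 1, 1)), chg$start[two_del], "_",
    aa3(substr(chg$original[two_del], 2, 2)), chg$end[two_del], "del"
  )
  lab[ins_idx] <- paste0(
    "p.", aa3(substr(proteome[chg$protein_ac[ins_idx]], chg$start[ins_idx], chg$start[ins_idx])),
    chg$start[ins_idx], "_",
    aa3(substr(proteome[chg$protein_ac[ins_idx]], chg$end[ins_idx], chg$end[ins_idx])),
    chg$end[ins_idx], "ins",
    vapply(chg$resulting[ins_idx], one_to_three, character(1))
  )
  first_lo <- pmin(chg$pos[seg2_idx], as.integer(pos2))
  sub_body <- function(p, i) {
    s <- seg_tbl[seg_tbl$chg_id == i & seg_tbl$start == p, ]
    paste0(aa3(s$original), p, aa3(s$resulting))
  }
  lab[seg2_idx] <- vapply(seq_along(seg2_idx), function(k) {
    i <- chg$chg_id[seg2_idx[k]]
    ps <- sort(c(chg$pos[seg2_idx[k]], as.integer(pos2[k])))
    paste0("p.[", sub_body(ps[1], i), ";", sub_body(ps[2], i), "]")
  }, character(1))
  chg$label <- lab

  # partners: one or two same-organism proteins, occasionally a proteoform
  n_partners <- sample(1:2, nrow(chg), replace = TRUE, prob = c(0.7, 0.3))
  org_pools <- split(names(proteome), rep(orgs$taxid, orgs$proteins))
  chg$partner_acs <- vapply(seq_len(nrow(chg)), function(i) {
    pool <- org_pools[[chg$taxid[i]]]
    p <- sample(pool, n_partners[i])
    tag <- stats::runif(length(p)) < 0.05
    p[tag] <- paste0(p[tag], "|phosphorylated")
    paste(p, collapse = ";")
  }, character(1))

  # effect-category assignment honouring both the per-category totals and
  # the injected evidence-group classes
  budget <- spec$effects
  multi_idx <- which(chg$multiplicity >= 2L)
  mult2 <- multi_idx[chg$multiplicity[multi_idx] == 2L]
  if (length(mult2) < cons$n_conflict + cons$n_mild) {
    stop("infeasible fixture spec: not enough multiplicity-2 groups for the ",
      "requested conflict and mild-conflict injections",
      call. = FALSE
    )
  }
  picked <- sample(mult2, cons$n_conflict + cons$n_mild)
  conflict_idx <- utils::head(picked, cons$n_conflict)
  mild_idx <- utils::tail(picked, cons$n_mild)
  consistent_idx <- setdiff(multi_idx, picked)

  categories <- vector("list", nrow(chg))
  class_of <- rep(NA_character_, nrow(chg))
  for (i in conflict_idx) {
    members <- c(
      draw_categories(budget, DIRECTION_CATS$negative, 1L),
      draw_categories(budget, DIRECTION_CATS$positive, 1L)
    )
    for (m in members) budget[m] <- budget[m] - 1
    categories[[i]] <- sample(members)
    class_of[i] <- "conflict"
  }
  for (i in mild_idx) {
    members <- c(draw_categories(budget, DIRECTION_CATS$negative, 1L), "no_effect")
    for (m in members) budget[m] <- budget[m] - 1
    categories[[i]] <- sample(members)
    class_of[i] <- "mild_conflict"
  }
  # consistent groups processed largest first so budgets never dead-end
  consistent_idx <- consistent_idx[order(-chg$multiplicity[consistent_idx])]
  for (i in consistent_idx) {
    m <- chg$multiplicity[i]
    dir_left <- vapply(DIRECTION_CATS, function(cats) sum(budget[cats]), numeric(1))
    ok <- names(dir_left)[dir_left >= m]
    if (length(ok) == 0L) {
      stop("infeasible fixture spec: effect budget cannot host a consistent ",
        "group of size ", m,
        call. = FALSE
      )
    }
    dir <- ok[which.max(dir_left[ok])]
    members <- draw_categories(budget, DIRECTION_CATS[[dir]], m)
    for (cat in unique(members)) budget[cat] <- budget[cat] - sum(members == cat)
    categories[[i]] <- members
    class_of[i] <- "consistent"
  }
  single_idx <- which(chg$multiplicity == 1L)
  leftover <- rep(names(budget), budget)
  if (length(leftover) != length(single_idx)) {
    stop("internal error: effect budget does not match single-tested changes")
  }
  leftover <- sample(leftover)
  for (k in seq_along(single_idx)) {
    categories[[single_idx[k]]] <- leftover[k]
    class_of[single_idx[k]] <- "single"
  }
  chg$class <- class_of

  # expand to annotations
  ann <- chg[rep(seq_len(nrow(chg)), chg$multiplicity), c("chg_id", "taxid")]
  ann$category <- unlist(categories, use.names = FALSE)
  ann$feature_ac <- sprintf("EBI-%07d", seq_len(nrow(ann)))
  ann$feature_type <- term_for_category(ann$category)
  ann$detection_method <- sample(DETECTION_METHODS, nrow(ann), replace = TRUE)
  ann$source_db <- sample(SOURCE_DBS, nrow(ann), replace = TRUE)
  ann$interaction_id <- NA_character_
  ann$pubmed_id <- NA_character_
  int_counter <- 0L
  pub_counter <- 0L
  for (o in seq_len(n_org)) {
    idx <- which(ann$taxid == orgs$taxid[o])
    ints <- sprintf("EBI-I%07d", int_counter + seq_len(orgs$interactions[o]))
    int_counter <- int_counter + orgs$interactions[o]
    pubs <- sprintf("%d", 10000000L + pub_counter + seq_len(orgs$publications[o]))
    pub_counter <- pub_counter + orgs$publications[o]
    ann$interaction_id[idx] <- sample(
      rep(ints, distribute_counts(length(idx), length(ints)))
    )
    ann$pubmed_id[idx] <- sample(
      rep(pubs, distribute_counts(length(idx), length(pubs)))
    )
  }
  ann$feature_annotation <- ifelse(
    stats::runif(nrow(ann)) < 0.02,
    sprintf("kd: %.1fe-9M", stats::runif(nrow(ann), 1, 99)), ""
  )

  # annotation x segment rows
  seg_n <- as.integer(table(factor(seg_tbl$chg_id, levels = chg$chg_id)))
  ann$seg_n <- seg_n[ann$chg_id]
  rows <- ann[rep(seq_len(nrow(ann)), ann$seg_n), ]
  seg_of <- split(seq_len(nrow(seg_tbl)), seg_tbl$chg_id)
  seg_rows <- unlist(lapply(
    seq_len(nrow(ann)), function(k) seg_of[[as.character(ann$chg_id[k])]]
  ), use.names = FALSE)
  rows$start <- seg_tbl$start[seg_rows]
  rows$end <- seg_tbl$end[seg_rows]
  rows$original_seq <- seg_tbl$original[seg_rows]
  rows$resulting_seq <- seg_tbl$resulting[seg_rows]
  rows$feature_label <- chg$label[rows$chg_id]
  rows$protein_ac <- chg$protein_ac[rows$chg_id]
  rows$protein_symbol <- unname(symbols[rows$protein_ac])
  rows$protein_taxid <- rows$taxid
  rows$partner_acs <- chg$partner_acs[rows$chg_id]
  mutations <- unname_cols(tibble::as_tibble(rows[, MUT_COLUMNS]))

  truth_changes <- tibble::tibble(
    protein_ac = chg$protein_ac,
    change_key = vapply(seq_len(nrow(chg)), function(i) {
      s <- seg_tbl[seg_of[[as.character(i)]], ]
      change_key(s$start, s$end, s$original, s$resulting)
    }, character(1)),
    kind = chg$kind,
    multiplicity = chg$multiplicity,
    class = chg$class
  )
  list(
    mutations = mutations,
    proteome = proteome,
    truth = list(
      effects = spec$effects,
      organisms = orgs,
      consistency = list(
        n_multi_groups = cons$n_multi_groups,
        n_mild = cons$n_mild,
        n_conflict = cons$n_conflict,
        n_non_consistent = cons$n_mild + cons$n_conflict
      ),
      changes = truth_changes,
      annotations = tibble::tibble(
        feature_ac = ann$feature_ac, category = ann$category
      )
    )
  )
}

# ---------------------------------------------------------------------------

generate_variant_fixture <- function(spec) {
  v <- spec$variants
  np <- v$n_proteins
  nc <- v$n_changes
  acs <- sprintf("Q%05d", seq_len(np))
  cpp <- distribute_counts(nc, np)
  lens <- sample(spec$protein_length[1]:spec$protein_length[2], np, replace = TRUE)
  lens <- pmax(lens, 3L * cpp + 15L)
  seqs <- stats::setNames(vapply(lens, random_residues, character(1)), acs)
  # change positions on a stride-3 grid so no two changes (including the
  # second residue of two-position changes) or decoys ever share a position
  pos_list <- mapply(
    function(len, k) sort(sample(seq(3L, len - 4L, by = 3L), k)),
    lens, cpp,
    SIMPLIFY = FALSE
  )
  chg <- tibble::tibble(
    protein_ac = rep(acs, cpp),
    pos = as.integer(unlist(pos_list, use.names = FALSE))
  )
  chg$chg_id <- seq_len(nc)

  n_positional <- floor(v$n_pos_partial_changes / 2)
  n_partial <- v$n_pos_partial_changes - n_positional
  strata <- sample(nc)
  full_idx <- strata[seq_len(v$n_full_changes)]
  positional_idx <- strata[v$n_full_changes + seq_len(n_positional)]
  partial_idx <- strata[v$n_full_changes + n_positional + seq_len(n_partial)]
  chg$stratum <- "none"
  chg$stratum[full_idx] <- "full"
  chg$stratum[positional_idx] <- "positional"
  chg$stratum[partial_idx] <- "partial"

  # partial changes span two contiguous residues, all others one
  chg$span <- ifelse(chg$stratum == "partial", 2L, 1L)
  chg$start <- chg$pos
  chg$end <- chg$pos + chg$span - 1L
  chg$original <- substr(seqs[chg$protein_ac], chg$start, chg$end)
  res1 <- sample_other_residue(substr(chg$original, 1, 1))
  res2 <- sample_other_residue(substr(chg$original, 2, 2)[chg$span == 2L])
  chg$resulting <- res1
  chg$resulting[chg$span == 2L] <- paste0(res1[chg$span == 2L], res2)

  aa3 <- function(x) unname(AA_ONE_TO_THREE[x])
  chg$label <- fast_sub_label(
    chg$pos, substr(chg$original, 1, 1), substr(chg$resulting, 1, 1)
  )
  two <- chg$span == 2L
  chg$label[two] <- paste0(
    "p.", aa3(substr(chg$original[two], 1, 1)), "_",
    aa3(substr(chg$original[two], 2, 2)), chg$start[two], "-", chg$end[two],
    aa3(substr(chg$resulting[two], 1, 1)), "_", aa3(substr(chg$resulting[two], 2, 2))
  )

  # annotation multiplicities per stratum, exact totals
  chg$multiplicity <- 0L
  chg$multiplicity[full_idx] <- distribute_counts(v$n_full_annotations, length(full_idx))
  pp_idx <- c(positional_idx, partial_idx)
  chg$multiplicity[pp_idx] <- distribute_counts(v$n_pos_partial_annotations, length(pp_idx))
  none_idx <- which(chg$stratum == "none")
  rest_ann <- v$n_annotations - v$n_full_annotations - v$n_pos_partial_annotations
  chg$multiplicity[none_idx] <- distribute_counts(rest_ann, length(none_idx))

  # catalogue: exact-match rows for full changes (every position), an
  # alternate-residue mismatch for positional changes, a first-position-only
  # match for partial changes, plus decoys on the unused position grid
  cat_rows <- list(
    tibble::tibble(
      protein_ac = chg$protein_ac[full_idx], position = chg$pos[full_idx],
      reference = chg$original[full_idx], alternate = chg$resulting[full_idx]
    ),
    tibble::tibble(
      protein_ac = chg$protein_ac[positional_idx],
      position = chg$pos[positional_idx],
      reference = chg$original[positional_idx],
      alternate = vapply(positional_idx, function(i) {
        sample(setdiff(AA_STANDARD, c(chg$original[i], chg$resulting[i])), 1)
      }, character(1))
    ),
    tibble::tibble(
      protein_ac = chg$protein_ac[partial_idx],
      position = chg$pos[partial_idx],
      reference = substr(chg$original[partial_idx], 1, 1),
      alternate = substr(chg$resulting[partial_idx], 1, 1)
    )
  )
  decoy_prot <- sample(acs, v$n_decoys, replace = TRUE)
  decoy_pos <- vapply(decoy_prot, function(a) {
    as.integer(sample(seq(2L, nchar(seqs[[a]]) - 1L, by = 3L), 1))
  }, integer(1), USE.NAMES = FALSE)
  decoy_ref <- substr(seqs[decoy_prot], decoy_pos, decoy_pos)
  cat_rows[[4]] <- tibble::tibble(
    protein_ac = decoy_prot, position = decoy_pos,
    reference = decoy_ref, alternate = sample_other_residue(decoy_ref)
  )
  catalogue <- dplyr::bind_rows(cat_rows)
  catalogue$disease_linked <- stats::runif(nrow(catalogue)) < 0.2
  catalogue$external_id <- sprintf("rs%07d", sample.int(9999999, nrow(catalogue)))
  catalogue$source <- sample(c("UniProt", "ClinVar", "gnomAD"), nrow(catalogue),
    replace = TRUE
  )
  catalogue <- catalogue[sample(nrow(catalogue)), ]

  # expand to annotations
  ann <- chg[rep(seq_len(nc), chg$multiplicity), ]
  ann$feature_ac <- sprintf("EBI-V%06d", seq_len(nrow(ann)))
  ann$category <- sample(names(spec$effects), nrow(ann),
    replace = TRUE, prob = spec$effects / sum(spec$effects)
  )
  mutations <- tibble::tibble(
    feature_ac = ann$feature_ac,
    feature_label = ann$label,
    start = ann$start, end = ann$end,
    original_seq = ann$original, resulting_seq = ann$resulting,
    feature_type = term_for_category(ann$category),
    feature_annotation = "",
    protein_ac = ann$protein_ac,
    protein_symbol = paste0("HG", match(ann$protein_ac, acs)),
    protein_taxid = "9606",
    interaction_id = sprintf("EBI-IV%06d", seq_len(nrow(ann))),
    partner_acs = sample(acs, nrow(ann), replace = TRUE),
    detection_method = sample(DETECTION_METHODS, nrow(ann), replace = TRUE),
    pubmed_id = sprintf("%d", 20000000L + sample.int(400, nrow(ann), replace = TRUE)),
    source_db = sample(SOURCE_DBS, nrow(ann), replace = TRUE)
  )
  mutations <- unname_cols(mutations)
  catalogue <- unname_cols(catalogue)
  list(
    mutations = mutations,
    proteome = seqs,
    catalogue = catalogue,
    truth = list(
      changes = tibble::tibble(
        protein_ac = chg$protein_ac,
        change_key = change_key_vec(chg$start, chg$end, chg$original, chg$resulting),
        stratum = chg$stratum,
        multiplicity = chg$multiplicity
      ),
      annotations = tibble::tibble(
        feature_ac = ann$feature_ac, stratum = ann$stratum
      ),
      counts = v
    )
  )
}

# per-change key for single-segment changes (vectorized)
change_key_vec <- function(start, end, original, resulting) {
  sprintf("%d:%d:%s>%s", start, end, original, resulting)
}

# ---------------------------------------------------------------------------

generate_qc_fixture <- function(spec) {
  q <- spec$qc
  n <- q$n_unchanged + q$n_shifted + q$n_scrambled
  status <- c(
    rep("unchanged", q$n_unchanged),
    rep("shifted", q$n_shifted),
    rep("scrambled", q$n_scrambled)
  )
  acs <- sprintf("U%05d", seq_len(n))
  lens <- sample(spec$protein_length[1]:spec$protein_length[2], n, replace = TRUE)
  old <- stats::setNames(vapply(lens, random_residues, character(1)), acs)
  pos <- vapply(lens, function(len) {
    sample(seq(q$context + 5L, len - q$context - 5L), 1)
  }, numeric(1)) |> as.integer()
  original <- substr(old, pos, pos)
  resulting <- sample_other_residue(original)

  new <- old
  offsets <- integer(n)
  for (i in which(status == "shifted")) {
    repeat {
      cand <- paste0(random_residues(q$shift_offset), old[[i]])
      window <- substr(old[[i]], pos[i] - q$context, pos[i] + q$context)
      if (length(match_positions(window, cand)) == 1L) {
        new[[i]] <- cand
        offsets[i] <- q$shift_offset
        break
      }
    }
  }
  for (i in which(status == "scrambled")) {
    win_start <- pos[i] - q$context - 2L
    win_end <- pos[i] + q$context + 2L
    repeat {
      cand <- paste0(
        substr(old[[i]], 1, win_start - 1L),
        random_residues(win_end - win_start + 1L),
        substr(old[[i]], win_end + 1L, nchar(old[[i]]))
      )
      window <- substr(old[[i]], pos[i] - q$context, pos[i] + q$context)
      if (length(match_positions(window, cand)) == 0L) {
        new[[i]] <- cand
        break
      }
    }
  }
  category <- sample(names(spec$effects), n,
    replace = TRUE, prob = spec$effects / sum(spec$effects)
  )
  mutations <- tibble::tibble(
    feature_ac = sprintf("EBI-Q%06d", seq_len(n)),
    feature_label = fast_sub_label(pos, original, resulting),
    start = pos, end = pos,
    original_seq = original, resulting_seq = resulting,
    feature_type = term_for_category(category),
    feature_annotation = "",
    protein_ac = acs,
    protein_symbol = paste0("QC", seq_len(n)),
    protein_taxid = "9606",
    interaction_id = sprintf("EBI-IQ%06d", seq_len(n)),
    partner_acs = sample(acs, n, replace = TRUE),
    detection_method = sample(DETECTION_METHODS, n, replace = TRUE),
    pubmed_id = sprintf("%d", 30000000L + sample.int(50, n, replace = TRUE)),
    source_db = sample(SOURCE_DBS, n, replace = TRUE)
  )
  mutations <- unname_cols(mutations)
  list(
    mutations = mutations,
    old_proteome = old,
    new_proteome = new,
    truth = tibble::tibble(
      feature_ac = mutations$feature_ac,
      injected = status,
      status = ifelse(injected == "scrambled", "flagged", injected),
      offset = ifelse(
        injected == "shifted", offsets,
        ifelse(injected == "unchanged", 0L, NA)
      )
    )
  )
}

# ---------------------------------------------------------------------------

generate_phospho_fixture <- function(spec) {
  p <- spec$phospho
  n_on <- p$n_disrupting + p$n_mimetic + p$n_other
  n_off_sty <- ceiling(p$n_off_site / 2)
  n_off_other <- p$n_off_site - n_off_sty
  n_points <- n_on + p$n_off_site
  acs <- sprintf("S%05d", seq_len(p$n_proteins))
  ppp <- distribute_counts(n_points, p$n_proteins)
  lens <- pmax(
    sample(spec$protein_length[1]:spec$protein_length[2], p$n_proteins, replace = TRUE),
    3L * ppp + 15L
  )
  seqs <- vapply(lens, random_residues, character(1))
  pos_list <- mapply(
    function(len, k) sample(seq(3L, len - 3L, by = 3L), k),
    lens, ppp,
    SIMPLIFY = FALSE
  )
  pts <- tibble::tibble(
    protein_ac = rep(acs, ppp),
    position = as.integer(unlist(pos_list, use.names = FALSE))
  )
  cls <- sample(c(
    rep("phospho_disrupting", p$n_disrupting),
    rep("phospho_mimetic", p$n_mimetic),
    rep("other_at_phosphosite", p$n_other),
    rep("na_off_site", n_off_sty),
    rep("na_not_sty", n_off_other)
  ))
  pts$injected <- cls
  # plant S/T/Y where the scenario needs a phosphorylatable original
  needs_sty <- cls != "na_not_sty"
  pts$original <- ifelse(needs_sty, sample(c("S", "T", "Y"), n_points, replace = TRUE), "")
  not_sty <- which(!needs_sty)
  pts$original[not_sty] <- vapply(not_sty, function(i) {
    sample(setdiff(AA_STANDARD, c("S", "T", "Y")), 1)
  }, character(1))
  for (i in seq_len(n_points)) {
    substr(seqs[match(pts$protein_ac[i], acs)], pts$position[i], pts$position[i]) <- pts$original[i]
  }
  pts$resulting <- NA_character_
  pick <- function(idx, choices) {
    vapply(idx, function(i) {
      sample(setdiff(choices, pts$original[i]), 1)
    }, character(1))
  }
  pts$resulting[cls == "phospho_disrupting"] <-
    pick(which(cls == "phospho_disrupting"), c("A", "G", "V", "F"))
  pts$resulting[cls == "phospho_mimetic"] <-
    pick(which(cls == "phospho_mimetic"), c("E", "D"))
  pts$resulting[cls == "other_at_phosphosite"] <- pick(
    which(cls == "other_at_phosphosite"),
    setdiff(AA_STANDARD, c("A", "G", "V", "F", "E", "D"))
  )
  off <- cls %in% c("na_off_site", "na_not_sty")
  pts$resulting[off] <- sample_other_residue(pts$original[off])
  pts$feature_ac <- sprintf("EBI-P%06d", seq_len(n_points))
  pts$expected <- ifelse(startsWith(cls, "na_"), "not_applicable", cls)

  sites <- pts[pts$injected %in%
    c("phospho_disrupting", "phospho_mimetic", "other_at_phosphosite"), ]
  sites <- tibble::tibble(
    protein_ac = sites$protein_ac, position = sites$position,
    residue = sites$original
  )
  list(
    points = unname_cols(pts[, c(
      "feature_ac", "protein_ac", "position", "original", "resulting"
    )]),
    sites = sites[order(sites$protein_ac, sites$position), ],
    proteome = stats::setNames(seqs, acs),
    truth = pts[, c("feature_ac", "expected", "injected")]
  )
}

# ---------------------------------------------------------------------------

generate_interface_fixture <- function(spec) {
  ifc <- spec$interfaces
  acs <- sprintf("I%05d", seq_len(ifc$n_proteins))
  lens <- sample(
    spec$protein_length[1]:spec$protein_length[2], ifc$n_proteins,
    replace = TRUE
  )
  # one region per protein, alternating source class
  reg_start <- vapply(lens, function(len) sample(20:(len %/% 2), 1), numeric(1))
  reg_end <- reg_start + vapply(lens, function(len) sample(15:40, 1), numeric(1))
  reg_end <- pmin(reg_end, lens - 20L)
  regions <- tibble::tibble(
    protein_ac = acs,
    start = as.integer(reg_start), end = as.integer(reg_end),
    source = rep_len(c("predicted", "curated"), ifc$n_proteins)
  )
  prot_in <- sample(ifc$n_proteins, ifc$n_inside, replace = TRUE)
  pos_in <- vapply(prot_in, function(i) {
    as.integer(sample(regions$start[i]:regions$end[i], 1))
  }, integer(1))
  prot_out <- sample(ifc$n_proteins, ifc$n_outside, replace = TRUE)
  pos_out <- vapply(prot_out, function(i) {
    as.integer(sample(c(
      2:(regions$start[i] - 2L),
      (regions$end[i] + 2L):(lens[i] - 1L)
    ), 1))
  }, integer(1))
  pts <- tibble::tibble(
    feature_ac = sprintf("EBI-R%06d", seq_len(ifc$n_inside + ifc$n_outside)),
    protein_ac = acs[c(prot_in, prot_out)],
    position = c(pos_in, pos_out),
    original = "A", resulting = "G",
    inside = c(rep(TRUE, ifc$n_inside), rep(FALSE, ifc$n_outside)),
    region_source = regions$source[c(prot_in, prot_out)]
  )
  list(
    points = unname_cols(pts[, c("feature_ac", "protein_ac", "position", "original", "resulting")]),
    regions = regions,
    truth = tibble::tibble(
      feature_ac = pts$feature_ac,
      inside_predicted = pts$inside & pts$region_source == "predicted",
      inside_curated = pts$inside & pts$region_source == "curated"
    )
  )
}

# ---------------------------------------------------------------------------

#' Generate the full synthetic fixture set
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed; identical `(spec, seed)` pairs produce
#'   byte-identical outputs.
#' @return A list of class `ppimut_fixture` with elements `main` (mutations
#'   table, proteome, ground truth for effects, organisms and evidence-group
#'   classes), `variants` (standalone mutations table, proteome, catalogue
#'   and per-change mapping strata), `qc` (old/new proteome pair and
#'   expected remap statuses), `phospho` (points, site table and expected
#'   classes), `interfaces` (points, region table and expected membership),
#'   plus the `spec` and `seed` used.
#' @export
generate_fixture <- function(spec = fixture_spec(), seed = 1L) {
  validate_fixture_spec(spec)
  set.seed(as.integer(seed))
  structure(
    list(
      main = generate_main(spec),
      variants = generate_variant_fixture(spec),
      qc = generate_qc_fixture(spec),
      phospho = generate_phospho_fixture(spec),
      interfaces = generate_interface_fixture(spec),
      spec = spec,
      seed = as.integer(seed)
    ),
    class = "ppimut_fixture"
  )
}

#' Write a generated fixture to disk
#'
#' Materializes the fixture as the same plain-text formats the rest of the
#' toolkit consumes: FASTA proteomes, tab-delimited mutations tables,
#' variant/phosphosite/interface tables, and ground truth as TSV.
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_fixture <- function(fixture, dir) {
  sub <- function(...) {
    d <- file.path(dir, ...)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }
  d <- sub("main")
  write_mutations_table(fixture$main$mutations, file.path(d, "mutations.tsv"))
  write_proteome_fasta(fixture$main$proteome, file.path(d, "proteome.fasta"))
  readr::write_tsv(fixture$main$truth$changes, file.path(d, "truth_changes.tsv"),
    progress = FALSE
  )
  d <- sub("variants")
  write_mutations_table(fixture$variants$mutations, file.path(d, "mutations.tsv"))
  write_proteome_fasta(fixture$variants$proteome, file.path(d, "proteome.fasta"))
  write_variant_catalogue(fixture$variants$catalogue, file.path(d, "catalogue.tsv"))
  readr::write_tsv(fixture$variants$truth$changes, file.path(d, "truth_changes.tsv"),
    progress = FALSE
  )
  d <- sub("qc")
  write_mutations_table(fixture$qc$mutations, file.path(d, "mutations.tsv"))
  write_proteome_fasta(fixture$qc$old_proteome, file.path(d, "old.fasta"))
  write_proteome_fasta(fixture$qc$new_proteome, file.path(d, "new.fasta"))
  readr::write_tsv(fixture$qc$truth, file.path(d, "truth.tsv"), progress = FALSE)
  d <- sub("phospho")
  readr::write_tsv(fixture$phospho$points, file.path(d, "points.tsv"), progress = FALSE)
  write_phosphosite_table(fixture$phospho$sites, file.path(d, "sites.tsv"))
  readr::write_tsv(fixture$phospho$truth, file.path(d, "truth.tsv"), progress = FALSE)
  d <- sub("interfaces")
  readr::write_tsv(fixture$interfaces$points, file.path(d, "points.tsv"),
    progress = FALSE
  )
  write_interface_regions(fixture$interfaces$regions, file.path(d, "regions.tsv"))
  readr::write_tsv(fixture$interfaces$truth, file.path(d, "truth.tsv"),
    progress = FALSE
  )
  invisible(dir)
}

# ---------------------------------------------------------------------------

#' Inject controlled corruption into a mutations table
#'
#' Exercises the validator the way legacy manually-typed records did:
#' `"label_typo"` rewrites the label with a wrong resulting residue (or a
#' shifted position for indels), `"range_shift"` moves a segment off by one
#' so its original residues no longer match the sequence, and
#' `"residue_mismatch"` replaces the stored original residue with one that
#' contradicts the protein. Every corruption is chosen so that
#' [validate_dataset()] against `proteome` is guaranteed to flag the
#' feature; the returned log lists exactly what was done where.
#'
#' @param features Mutations table (must validate cleanly against
#'   `proteome`).
#' @param proteome Named character vector of sequences.
#' @param modes Subset of `c("label_typo", "range_shift",
#'   "residue_mismatch")`.
#' @param rate Fraction of features to corrupt, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list: `features` (corrupted table) and `log` (tibble
#'   `feature_ac`, `mode`). `rate = 0` returns the input unchanged.
#' @export
corrupt_dataset <- function(features, proteome,
                            modes = c("label_typo", "range_shift", "residue_mismatch"),
                            rate = 0.1, seed = 1L) {
  known <- c("label_typo", "range_shift", "residue_mismatch")
  if (length(setdiff(modes, known)) > 0) {
    stop("unknown corruption mode: ", paste(setdiff(modes, known), collapse = ", "),
      call. = FALSE
    )
  }
  stopifnot(rate >= 0, rate <= 1)
  set.seed(as.integer(seed))
  tbl <- tibble::as_tibble(features)
  acs <- unique(tbl$feature_ac)
  n_hit <- round(rate * length(acs))
  if (n_hit == 0L) {
    return(list(features = tbl, log = tibble::tibble(
      feature_ac = character(), mode = character()
    )))
  }
  hit <- sample(acs, n_hit)
  log <- vector("list", length(hit))
  for (k in seq_along(hit)) {
    ac <- hit[k]
    rows <- which(tbl$feature_ac == ac)
    # prefer a substitution/deletion row (has original residues to corrupt)
    subrows <- rows[tbl$original_seq[rows] != ""]
    mode <- sample(rep(modes, 2), 1)
    if (length(subrows) == 0L) mode <- "label_typo"
    r <- if (length(subrows) > 0) subrows[1] else rows[1]
    seq <- unname(proteome[tbl$protein_ac[r]])
    applied <- mode
    if (mode == "residue_mismatch") {
      wrong <- sample(setdiff(AA_STANDARD, substr(seq, tbl$start[r], tbl$start[r])), 1)
      old <- tbl$original_seq[r]
      substr(old, 1, 1) <- wrong
      tbl$original_seq[r] <- old
    } else if (mode == "range_shift") {
      shifted <- FALSE
      for (delta in c(1L, -1L)) {
        ns <- tbl$start[r] + delta
        ne <- tbl$end[r] + delta
        bad <- ns < 1L || ne > nchar(seq) ||
          substr(seq, ns, ne) != tbl$original_seq[r]
        if (bad) {
          tbl$start[r] <- ns
          tbl$end[r] <- ne
          shifted <- TRUE
          break
        }
      }
      if (!shifted) { # both shifts happen to match the sequence; mismatch instead
        applied <- "residue_mismatch"
        wrong <- sample(setdiff(AA_STANDARD, substr(seq, tbl$start[r], tbl$start[r])), 1)
        old <- tbl$original_seq[r]
        substr(old, 1, 1) <- wrong
        tbl$original_seq[r] <- old
      }
    } else { # label_typo
      parsed <- parse_hgvs_label(tbl$feature_label[rows[1]], strict = FALSE)
      segs <- parsed$segments
      if (nrow(segs) > 0 && any(segs$resulting != "")) {
        i <- which(segs$resulting != "")[1]
        wrong <- sample(setdiff(AA_STANDARD, c(
          substr(segs$resulting[i], 1, 1), substr(segs$original[i], 1, 1)
        )), 1)
        res <- segs$resulting[i]
        substr(res, 1, 1) <- wrong
        segs$resulting[i] <- res
      } else if (nrow(segs) > 0) { # pure deletion label: bump the position
        segs$start <- segs$start + 1L
        segs$end <- segs$end + 1L
      }
      tbl$feature_label[rows] <- format_hgvs_label(segs)
    }
    log[[k]] <- tibble::tibble(feature_ac = ac, mode = applied)
  }
  list(features = tbl, log = dplyr::bind_rows(log))
}
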