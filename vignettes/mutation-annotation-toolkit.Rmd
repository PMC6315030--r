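---
title: "Models and procedures of the mutation-annotation toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and procedures of the mutation-annotation toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppimutr)
```

## The data model

A *mutation feature* is an annotated sequence change on an interaction
participant: one or more contiguous *change segments* (1-based inclusive
coordinates, original and resulting residue strings), an HGVS-style short
label, a controlled-vocabulary *effect* term, and provenance (protein
accession and taxon, interaction evidence id, partner proteins, detection
method, publication, source database). In the flat file each segment is one
row; rows of one feature share the feature accession. In memory the same
layout is kept as a tibble with one row per segment — the tidyverse-natural
form for a line-oriented exchange format — and feature-level views are
derived on demand.

Two conventions apply everywhere and are worth stating once:

* **Coordinates are 1-based inclusive** on both ends, the protein feature
  convention of sequence databases. Region membership tests, ranges in
  labels and the flat file all follow it.
* **Proteoform sensitivity.** A partner accession may carry a proteoform
  tag (`"P12345|phosphorylated"`); two partner references are equal only if
  accession *and* tag are equal, because a phosphorylated protein can
  behave as a different interactor than its unmodified form.
  Isoform-suffixed accessions (`"P12345-2"`) are likewise kept verbatim.

### Effect vocabulary

Effects arrive as PSI-MI terms (`"mutation disrupting(MI:0573)"` and
children). The packaged vocabulary collapses rate/strength child terms onto
six categories, each with a direction semantic:

| category   | direction | meaning                                    |
|------------|-----------|--------------------------------------------|
| disrupting | negative  | interaction abolished                      |
| decreasing | negative  | interaction weakened (incl. rate/strength) |
| increasing | positive  | interaction strengthened                   |
| causing    | positive  | interaction newly created                  |
| no_effect  | neutral   | tested, no detectable change               |
| undefined  | unknown   | no wild-type comparison available          |

Six categories are used because that is the granularity at which such
datasets are reported and compared; the table is an argument
(`effect_vocabulary(extra = ...)`) so newly adopted terms can be mapped
without a package release. `undefined` is deliberately *unknown*-direction:
it never votes in consistency calls and maps to `unknown` in the simplified
loss/gain scheme.

## Label grammar

The supported protein-change grammar covers what this class of data
actually contains — overwhelmingly substitutions, with a marginal number of
deletions and insertions: single substitutions (`p.Arg725Glu`), contiguous
multi-residue substitutions with an explicit range
(`p.Cys_Ser215-216Ala_Ala`), discontiguous multi-position variants in
bracket notation (`p.[Asn31His;Ala60Val]`), simple deletions (`p.Arg12del`,
`p.Cys12_Ser13del`) and simple insertions (`p.Lys2_Gly3insGlnSer`).
Frameshifts, extensions, duplications and nucleotide-level notation are out
of scope.

Parsing is strict by default; lenient mode exists for legacy hand-typed
labels and applies exactly three repairs — stray whitespace, en-dash
ranges, mis-cased residue names — reporting everything else unrepaired. The
contract is: the lenient warning list is non-empty exactly when strict
parsing would have raised.

Two representational choices deserve a note:

* **Insertions.** An insertion label names its flanking residues
  (`Lys2_Gly3`), which are properties of the protein, not of the change
  segment (whose original string is empty). Parsed insertion segments
  therefore carry `flank_left`/`flank_right` columns, and formatting an
  insertion requires them; after a coordinate shift they are re-read from
  the new sequence.
* **Deletions.** The label grammar names only the terminal residues of a
  deleted range, so only spans of one or two residues round-trip through
  labels; longer deletions would need the flat file's explicit original
  column, and the generator accordingly emits spans of at most two.

Bracketed labels are emitted with sub-changes ordered by position; that is
the canonical form for which `format(parse(x)) == x` holds.

## Validation and coordinate maintenance

`validate_dataset()` reports — as data, never as exceptions — out-of-bounds
ranges, disagreement between stored original residues and the protein
sequence, range/length inconsistencies, label/column conflicts and unknown
effect terms. Label conflicts are *flagged, not resolved*: the flat-file
example deliberately reproduced in the test helpers stores original `D`
under a label naming `Asn`, and the correct behaviour is an
`original-mismatch` issue, not a silent fix.

`remap_feature()` keeps coordinates synchronized with sequence releases.
For each segment the original residues plus a flank of `context` residues
on each side (truncated at the termini) are extracted from the old sequence
and searched for exact occurrences in the new one. A unique hit for every
segment, with one common offset, shifts the feature and re-emits its label
at the new coordinates; zero hits, multiple hits, or inconsistent
per-segment offsets flag it (`no-match`, `ambiguous-match`,
`inconsistent-offsets`), and flagged features are excluded from the emitted
table pending curator review. The default flank of 10 residues each side is
a design choice: a 21-residue window is long enough that a chance duplicate
in a proteome-scale search is unlikely, yet short enough to survive edits
that are not immediately adjacent to the feature. It is a tunable argument,
and ambiguity always flags rather than guesses — when curating, a false
shift is worse than a deferred one.

## Consistency classification

The unit of assessment is the *evidence group*: all features sharing
(protein, ordered segment tuple, partner multiset with proteoform tags).
Within a multiply-tested group, effects vote by direction after excluding
`undefined`:

* negative **and** positive present → **conflict** (directly antagonistic,
  e.g. disrupting vs increasing); antagonism dominates any additional
  neutral evidence;
* exactly one non-neutral direction plus at least one neutral →
  **mild conflict** (e.g. decreasing vs no effect), including 50/50 splits;
* otherwise → **consistent**: all one direction, where mixed negative
  categories (disrupting + decreasing) or mixed positive ones count as
  agreement, as do all-neutral groups.

Groups whose evidence is entirely `undefined` are excluded from the
multiply-tested denominator — they carry no comparable effect statement.
The report documents its grouping key verbatim (`grouping_key` field), so a
consumer can tell whether a published denominator counted groups or
(group, method) pairs; the toolkit counts groups.

## Variant mapping

Multi-position changes are split into individual point substitutions;
insertions and deletions carry no per-position substitution and are
reported unmapped by construction. Matching against a catalogue indexed by
(accession, position) is then:

* every position matched with the identical alternate residue → **full**;
* single-position feature, position matched, different alternate →
  **positional**;
* multi-position feature, at least one position matched but no full cover
  → **partial**, with `match_detail` separating "all positions matched but
  residues differ" from "some positions unmatched";
* nothing matched → **none**.

Single-position features can never be *partial*, multi-position features
never *positional*; the two non-full match kinds are reported together as
one positional/partial bucket at summary level, with the sub-distinction
preserved per call. A catalogue reference residue that contradicts the
feature's original residue demotes a would-be full point match and leaves a
`reference-mismatch` note — a defensive stance: if the two resources
disagree about the wild-type residue, the match is not trusted as full.
Accession strings are matched exactly, so isoform-level annotations only
match isoform-level catalogue rows; no canonical/isoform cross-walk is
attempted.

Summaries are computed at two granularities — per annotation and per
distinct sequence change — because repeated testing makes the two tell
different stories; percentages print half-up to the nearest integer at this
level.

## Rule-based classifiers

*Phosphosite rules.* At an annotated phosphosite, S/T/Y → A/G/V/F is
phospho-disrupting (removes the phosphorylatable hydroxyl; F mimics Y's
ring without the site), S/T/Y → E/D is phospho-mimetic (negative charge
mimicking the phosphate). Everything else at a site is
`other_at_phosphosite`; positions without a site annotation, or non-S/T/Y
originals, are `not_applicable`. Of the 380 cells of the substitution grid
at a phosphosite, exactly 12 are disrupting and 6 mimetic — the enumeration
is asserted in the tests. Sites come from an explicit table
(accession, position, residue); the toolkit never infers them.

*Affinity.* The fold-change phrase "over and under 50 percent of wild
type" is implemented as the asymmetric ratio pair on r = KD(mutant)/KD(wild
type): r > 1.5 → loss, r < 0.5 → gain, else no effect, with larger KD
meaning weaker binding. A symmetric reading (|Δ| > 50% on a normalized
scale) is also defensible, which is precisely why both thresholds are
configuration rather than constants; the defaults are documented, not
asserted as the only computation.

*Interfaces.* Membership is an inclusive-bounds interval test per region
source class (structure-derived *predicted* regions vs literature-curated
binding-associated regions); a multi-position change is inside if any of
its positions is.

## The synthetic-data generator

The generator's defaults *are* the study conditions of the emulated
resource, and its whole design goal is exact, retrievable ground truth:

* per-category effect counts (27,868 annotations: 10,976 disrupting, 8,553
  decreasing, 2,256 increasing, 188 causing, 3,057 no-effect, 2,838
  undefined), realized exactly by budgeted assignment;
* per-organism composition (eight rows: seven model organisms plus an
  `"others"` pseudo-taxon; annotations, distinct changes, proteins,
  interactions and publications per row realized exactly by constrained
  distribution of identifiers);
* evidence-group structure: exactly 7,212 multiply-tested groups, of which
  71 mix one direction with no-effect reports and 19 are antagonistic;
  annotation multiplicities beyond the minimum follow a truncated-geometric
  surplus, reflecting that most changes are tested once;
* 65 deletion and 83 insertion annotations, plus a small number of
  two-segment bracket-label features;
* a standalone human variant-overlap scenario: 16,765 annotations over
  8,820 distinct changes in 1,990 proteins, with 4,804 annotations (1,073
  changes) constructed fully matched and 2,671 annotations (1,415 changes)
  positional/partial. The 1,415 are split half into single-position
  changes with a different catalogue alternate (positional) and half into
  two-position changes with only the first position covered (partial); the
  split is a generator choice, as only the combined bucket is a stated
  condition. Change positions sit on a stride-3 grid and decoy catalogue
  rows on the complementary offsets, so no unintended (accession, position)
  collision can blur the injected strata;
* a coordinate-update scenario (unchanged / N-terminally extended /
  context-scrambled proteins with verified uniqueness or absence of the
  search window), and phosphosite/interface scenarios with per-point
  injected classes.

Quantities the conditions do not fix were chosen once as field-plausible
and are listed here so they are inspectable: protein lengths uniform in
300–800 residues (raised where a protein must host many changes), uniform
residue background over the 20 standard amino acids, 20% disease-flag rate
on catalogue rows, 1–2 interaction partners per change with a 5%
phosphorylated-proteoform rate, and desk-scale sizes for the QC, phospho
and interface fixtures. Feasibility of a specification is checked eagerly
(e.g. antagonistic groups need both a negative and a positive budget;
multiply-tested groups need spare annotations), and infeasible requests
fail with the violated constraint named.

What the generator does **not** emulate — and hence what passing tests do
and do not show about real data: no residue-composition or domain
structure, no correlation between effect and position, no disease
co-annotation structure, no literature bias (the real annotations-per-
publication distribution is far more skewed than the generator's), and no
shared interactions or publications across organisms. Recovery tests
demonstrate the *procedures* are correct under controlled conditions; they
are not evidence about biological distributions. For the same reason the
per-organism totals row of a generated dataset equals the column sums,
whereas in the real resource cross-organism interactions and publications
make the distinct-union totals smaller.

`corrupt_dataset()` closes the loop on the validator: label typos,
off-by-one ranges and residue mismatches are injected so that every logged
corruption is provably detectable, and the tests assert the corruption log
and the validator's error set coincide feature by feature.

## Numerical and formatting choices

* **Rounding** is half away from zero, centralized in `round_half_up()`:
  one decimal for effect shares and consistency percentages, nearest
  integer for mapping shares. One published share (disrupting,
  10,976/27,868) prints as 39.3 at one decimal where half-up arithmetic
  gives 39.4, and the corresponding non-consistent share prints 1.3% where
  90/7,212 gives 1.2%; no single rounding convention reproduces every
  printed value, so the toolkit computes, documents the convention, and
  flags these as known deviations rather than matching them by
  construction.
* **Ties and degenerate inputs.** Empty datasets raise an explicit
  empty-distribution error in `effect_distribution()`; a header-only flat
  file reads as an empty table; remapping against an identical proteome is
  the identity; `distribute_counts()` fails fast rather than silently
  violating a minimum-per-bin constraint.
* **Determinism.** All generator randomness flows from one `set.seed()`
  call on the user-supplied seed; identical (spec, seed) pairs produce
  byte-identical files.

## Problem sizes used in the checks

Unit tests run on a miniature specification (180 annotations, 40
multiply-tested groups, a 150-annotation variant scenario), cached per test
session. The acceptance-style checks and `scripts/acceptance.R` run the
full-scale specification above; generation plus both analyses complete in
well under a minute on a single core.

## Known limitations

Only the effect-term subset present in this data family is modelled, not
the full PSI-MI ontology. Remapping is exact-context search; sequence
updates that edit residues inside the context window flag the feature
rather than aligning around it (alignment-based remapping is explicitly out
of scope). Deletion labels longer than two residues and insertion segments
without flank information cannot be re-emitted as labels. The flat-file
dialect is versioned (`ppimutr-1`) and documented in
`?mutations_tsv`; it is not claimed byte-compatible with any external
release, whose fully expanded column list may differ.
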