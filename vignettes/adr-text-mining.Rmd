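---
title: "Mining adverse drug reactions from free-text clinical notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining adverse drug reactions from free-text clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrminer)
```

## The problem

Adverse drug reactions (ADRs) — and especially recurring ADRs, where a drug
stopped for a reaction is later re-prescribed — are preventable only if the
reaction is recorded in a structured ADR module that decision-support
systems can read. In practice, clinicians document reactions in free text:
"allergie: huiduitslag na amoxicilline" buried in a consult note. `adrminer`
is a rule-based extraction pipeline that turns such mentions into
structured, reviewable alerts: one row per unique
(patient, drug, reaction) association, with the trigger that found it, the
matched dictionary term, the surrounding paragraph, and a seriousness flag.

The design is deliberately lexicon-driven rather than model-driven: every
decision is inspectable, the dictionaries (a MedDRA-style ADR terminology,
a G-standard-style drug lexicon, trigger and negation word lists) are
supplied by the user, and the pipeline runs fast enough to screen a
hospital's note stream. The trade-off is the classic trigger-tool one: high
sensitivity comes with many false positives, and the refinement stages
exist to claw precision back.

## Pipeline model

The pipeline has two phases.

**Phase I, step A — candidate blocks.** Notes are segmented into text
blocks (see *Numerical choices*), and each block is screened by four
trigger strategies: `keyword` (whole-word positive triggers like
"allergie"), `preposition` (a preposition such as "wegens" whose next token
resolves in the drug lexicon), `field` (the note's category or form name is
a complication-style registration field), and `phrase` (multi-word
surfaces). Negative triggers mark blocks to be suppressed under the
`positive_minus_negative` policy. The strategy set is a pluggable registry:
the original clinical system's full rule base is not public, so the four
strategy *shapes* that are documented are implemented and users can extend
the lexicon.

**Phase I, step B — mention pairing.** Candidate blocks are scanned against
a longest-match-first index over all ADR surfaces (LLT names, PT names,
synonyms) and all drug surfaces (generic, brand, abbreviation, class).
Matching is whole-word, case-insensitive, on punctuation-stripped text. A
term mention and a drug mention in the same block form an ADR candidate
when the character gap between their nearest edges is at most
`max_distance` (default 43, inclusive); each term pairs with its nearest
drug, ties going to the drug occurring earlier. The 43-character default is
the empirically preferred separation for true drug-reaction pairs in
clinical text; a tighter 16-character rule loses valid pairs.

**Phase II — refinement.** Six stages, individually toggleable, applied in
a configurable order:

| stage | effect | default |
|---|---|---|
| `drug_filter` | drop candidates whose drug surface is on a negative list; positive list force-keeps | on |
| `term_filter` | same, keyed on the ADR term surface | on |
| `dedup` | one alert per (patient, drug, LLT); earliest kept | on |
| `negation` | drop candidates with a negation word within 10 characters of the term | off |
| variant matching | match one-letter typos at scan time (`use_variants`) | off |
| `seriousness` | flag alerts whose LLT/PT code is on the IME list | on |

The default on/off pattern is the configuration that maximised precision:
negation and variant matching are implemented, tested, and off, because
each *lowers* precision on realistic input (negation windows misfire on
Dutch word order more often than they catch true negations at this window
size; variant matching multiplies false drug hits). Both can be enabled per
run, and the synthetic generator makes their dose-response measurable.

## Evaluation

`compute_metrics()` implements sensitivity TP/(TP+FN), PPV TP/(TP+FP), and
the F-measure as their harmonic mean, with a zero-denominator convention of
0 plus a warning so batch runs never abort. Reports carry raw values plus
display roundings (percentages to the nearest integer, F to two decimals),
because published trigger-tool results are printed at that precision and
the two conventions can disagree by a point (299/326 = 91.7% prints as 92%
where a table rounds to 93%).

Note-level evaluation is the default — the natural unit is "an EHR note
containing a possible ADR", with set semantics on note ids so two alerts on
one gold note count once. Mention level (agreement on note, LLT code, and
drug id) is stricter and is what the synthetic gold standard is built for.
The serious stratum restricts gold rows to IME-listed reactions and, for
PPV, alerts to serious-flagged ones; serious-stratum PPV is an extension
beyond the usual sensitivity-only reporting and is labelled as such.

## The synthetic generator

Licensed terminologies and real notes cannot ship, so `generate_lexicons()`
provides a closed-vocabulary toy world — 33 ADR terms across 9 retained
system organ classes (plus 4 rows in the excluded classes to exercise the
loader), 29 drugs with brands, abbreviations and class names, trigger and
negation lexicons — and `generate_corpus()` plants drug-reaction sentences
into template-built Dutch-flavoured notes. Every plant places a positive
trigger, a term surface, and a drug surface with an exact character gap
drawn from `gap_range`; corruptions mirror the three real-world failure
modes: a negation word directly before the term, a one-letter typo
(substitution or insertion) in the drug, and a copy-paste duplicate in a
later note of the same patient.

Key generator choices:

* **Defaults are the study conditions.** 30 patients x 20 notes at
  `adr_rate` 0.15, `serious_fraction` 0.2 (the roughly one-in-five share of
  potentially serious reactions in manually reviewed note sets),
  `duplicate_rate` 0.1, negation and typo rates 0. Real corpora are far
  sparser (hundreds of ADR notes per tens of thousands of notes); the
  per-note rate here is a desk-scale choice so that property tests see
  enough events, and nothing in the pipeline is sensitive to prevalence.
* **Gold semantics follow the final configuration.** Negated plants are
  excluded from gold (so enabling the negation stage should remove exactly
  those alerts), duplicates collapse onto the original note (so
  deduplication is measurable), and typo'd plants stay in gold (they are
  real reactions, just misspelled — which is precisely why variant matching
  restores sensitivity).
* **Planted combinations are unique per patient**, so deduplication never
  merges two distinct gold events.
* **The closed vocabulary is collision-safe**: lexicon surfaces are
  pairwise at least three edits apart and filler words at least two edits
  from every surface, so a one-edit typo can never cross-match another
  entry. Planted gaps are measured on normalized text, the same frame the
  matcher uses; the minimum gap is 1 because whole-word matching requires a
  separator.

What the generator does **not** emulate: realistic Dutch clinical prose
(morphology, abbreviations in context, dosing lines), OCR noise, scanned
documents, co-occurring mentions competing inside one block, terms absent
from the dictionary, or the real prevalence and co-occurrence structure of
reactions and drugs. Passing the recovery properties therefore shows the
machinery is correct — offsets, pairing, stages, evaluation — not that the
shipped toy lexicons would reach any particular sensitivity or precision on
real notes; on real corpora both depend almost entirely on dictionary
coverage and trigger curation.

```{r dose-response, eval = FALSE}
# dose-response of the typo rate, and its rescue by variant matching
sim <- generate_corpus(sim_config(typo_rate = 0.5, seed = 7))
g <- gold_table(sim$gold)
glance(evaluate_alerts(run_pipeline(sim$notes, sim$bundle), g, "mention"))
glance(evaluate_alerts(
  run_pipeline(sim$notes, sim$bundle, adr_config(use_variants = TRUE)),
  g, "mention"))
```

## Numerical choices

* **Coordinates.** All spans are 1-based inclusive, R's native `substr()`
  convention, used consistently in blocks, mentions, and offset maps. The
  quantities that carry meaning — edge-to-edge character gaps, the
  43-character pairing rule, the 10-character negation window — are
  convention-invariant: the gap is the count of characters strictly between
  two spans, 0 when they touch or overlap.
* **Thresholds are inclusive.** A gap of exactly 43 pairs; a negation word
  at exactly 10 characters cancels. "A maximum of 43" reads as an attained
  value.
* **Normalization.** Unicode punctuation (category `P*`, plus `©` and `•`)
  is removed; a punctuation run whose removal would glue two words together
  becomes a single space; digits and diacritics are preserved (dose strings
  carry context, Dutch uses diacritics meaningfully). The offset map sends
  every normalized position to its raw position, so any match can be
  located in the original note.
* **Block segmentation.** The retrieval unit "text block" has no canonical
  definition, so the default is documented and configurable: split on blank
  lines and on header lines ending in ":", then split blocks over
  `max_block_chars` (default 2000) at sentence-final periods. Blocks
  partition the note exactly — a property the tests enforce.
* **Longest match, left to right.** At the same offset the longer surface
  wins ("rash maculopapular" beats "rash"); within a block and surface
  kind, selected spans never overlap, but term and drug scans are
  independent so a term never blocks a drug. A surface owned by several
  records (the abbreviation "asa") resolves to *all* owners — losing
  candidates silently would cost sensitivity; downstream pairing keeps the
  nearest drug per owner.
* **One-edit variants.** Generated by substitution and insertion only —
  names "modified or added by one letter" — with deletion available behind
  `ops` for users who want classical distance-1. At scan time the same
  operation set is enforced by blocking the deletion cost in the
  edit-distance computation, and exact matches always beat variant matches
  at a span.
* **Tie-breaks and determinism.** Nearest-drug ties go to the earlier drug;
  deduplication keeps the earliest timestamp, then lowest note id, then
  block offset — first documentation is the clinically primary record.
  Index construction, matching, and the stage chain are fully
  deterministic: identical inputs give byte-identical alert files.
* **Degenerate inputs.** Empty notes are skipped with a message; an empty
  corpus or empty lexicon yields an empty alert table, not an error;
  zero-denominator metrics report 0 with a warning; `max_distance = 0`
  still pairs overlapping/adjacent spans (gap 0) with proximity score 100.
* **Proximity score.** Each candidate carries
  `round(100 * (1 - gap / max_distance))` clamped to 1..100. This is a
  ranking aid for reviewers working through an alert queue — closer pairs
  are likelier true associations — and never gates emission.

## Open design points, resolved

* **Negative-trigger scope.** Whether a negative trigger suppresses a whole
  note or one block is left open by the source material; suppression is
  block-level here (a family-history paragraph should not veto an ADR
  documented two paragraphs later).
* **Synonym granularity.** SNOMED-CT-derived synonyms attach at LLT level;
  nothing in the matcher depends on the choice, and PT-level synonym sets
  can be expressed by repeating the synonym on each LLT.
* **Deduplication key.** Keyed on LLT code, not the raw surface, so
  "pruritus" and "jeuk" for the same drug and patient collapse — that is
  what "the same ADR" means once mentions are coded.
* **Distance frame.** The 43-character separation is measured on
  normalized (punctuation-stripped) text, the same frame in which mentions
  are found.
* **Alert file.** The reviewer-facing CSV mirrors the notification table
  (patient, trigger, ADR text, paragraph, category, medication, LLT name
  and code, author, timestamp, seriousness, proximity score); the CLI can
  additionally write a machine-readable table with note and drug
  identifiers for downstream evaluation.

## Problem sizes in the test suite

The shipped tests run the default 600-note corpus only where a single pass
is needed; property suites use 100-300-note corpora, 20-40 random
replicates per invariant, and 1000 brute-force oracle comparisons for
pairing and variant expansion. These sizes make the full suite complete in
a few minutes on one CPU while still exercising every stage boundary
(threshold inclusivity, negation window edges, duplicate collapse, variant
rescue) at deterministic seeds.

## Limitations

Rule-based pairing by proximity cannot read context: beneficial effects
("koorts verdwenen na paracetamol"), hypotheticals, and instructions all
pair like reactions, which is why precision on real text depends on curated
negative term/drug lists. The negation model is a fixed four-word window,
not syntax. Class-name drug mentions ("antibiotica") resolve to every class
member, deferring disambiguation to review. And all shipped dictionaries
are synthetic stand-ins: deploying on real notes requires licensed MedDRA /
SNOMED-CT / G-standard content mapped into the same TSV schemas.
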