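# adrminer

Rule-based detection of possible **adverse drug reactions (ADRs)** in
free-text clinical notes.

ADRs are frequently documented only as free text in electronic health
records ("allergie: huiduitslag na amoxicilline"), where clinical decision
support systems cannot see them. `adrminer` implements a two-phase
text-mining pipeline that surfaces these buried drug-event mentions as
structured, deduplicated alerts for pharmacovigilance review:

* **Phase I — identification.** Notes are segmented into text blocks;
  candidate blocks are flagged by configurable *trigger strategies*
  (keywords implying an ADR, prepositions followed by a drug name,
  complication-style registration fields, multi-word phrases, with positive
  and negative trigger lexicons). Inside candidate blocks, ADR terms from a
  MedDRA-style dictionary (LLT/PT/SOC hierarchy plus SNOMED-CT-derived
  synonyms) and drug names (generic, brand, abbreviation, class) are located
  on punctuation-stripped, lowercased text with full character-offset
  provenance, then paired by character proximity: a term and a drug form a
  candidate when at most **43 characters** separate their nearest edges
  (inclusive), each term pairing with its nearest drug.
* **Phase II — refinement.** Six toggleable stages turn candidates into
  unique alerts: positive/negative **drug-list** and **term-list** filters,
  **deduplication** (one alert per patient x drug x reaction, earliest
  kept — copy-paste between notes is endemic in EHRs), **one-edit variant
  matching** (one-letter typos such as "trimethoprim" for "trimetoprim",
  substitution or insertion only), a **negation window** (a candidate is
  dropped when "geen", "niet", "niks", or "nooit" sits within 10 characters
  of the term), and **seriousness** classification against the MedDRA
  Important-Medical-Event list. The default configuration enables the drug
  filter, term filter, deduplication, and seriousness; negation and variant
  matching are off, the configuration that maximised precision in practice.

The evaluation harness computes **sensitivity** TP/(TP+FN), **PPV**
TP/(TP+FP), and **F-measure** (their harmonic mean) at note or mention
level, with a separate stratum for potentially serious ADRs.

Because real MedDRA, SNOMED-CT, and G-standard content is licensed, the
package ships only the schemas plus a seeded synthetic-corpus generator
(`sim_config()`, `generate_lexicons()`, `generate_corpus()`) that plants
drug-reaction mentions — optionally negated, typo-corrupted, or
copy-paste-duplicated — together with the matching gold standard, so every
stage is testable end to end.

## Worked example

The package ships a small example corpus and toy lexicons:

```r
library(adrminer)

bundle <- load_lexicon_dir(system.file("extdata", "lexicons",
                                       package = "adrminer"))
notes  <- read_notes(system.file("extdata", "example_notes.csv",
                                 package = "adrminer"))
alerts <- run_pipeline(notes, bundle)
write_alerts(alerts)[, c("patient_id", "trigger_surface", "adr_text",
                         "medication", "llt_code", "serious")]
#> # A tibble: 3 × 6
#>   patient_id trigger_surface adr_text    medication   llt_code serious
#>   <chr>      <chr>           <chr>       <chr>        <chr>      <int>
#> 1 p002       allergie        vertigo     ibuprofen    L010           0
#> 2 p002       bijwerking      verwardheid ibuprofen    L015           0
#> 3 p002       allergie        koorts      amoxicilline L032           0
```

Each row is one unique drug-event association: the trigger that flagged the
block, the matched ADR term and its LLT code, the involved medication, the
surrounding paragraph (not shown), a seriousness flag, and a 1-100
proximity score (100 = term and drug adjacent).

Evaluation against a gold standard:

```r
gold <- read_gold(system.file("extdata", "example_gold.csv",
                              package = "adrminer"))
evaluate_alerts(alerts, gold, level = "note")
#> <adr_eval> note-level evaluation: 3 alerts vs 3 gold rows
#>   all     tp=3 fp=0 fn=0  sensitivity 100%  PPV 100%  F 1.00
```

`tidy()` / `glance()` return the metrics as tibbles, `autoplot()` plots
them, and `run_report(alerts)` shows per-stage candidate counts. On this
tiny clean corpus every planted mention is recovered; on corrupted corpora
(typos, negations) the stage toggles change the picture — see the vignette.

A synthetic corpus of any size is one call away:

```r
sim <- generate_corpus(sim_config(n_patients = 10, typo_rate = 0.2, seed = 7))
alerts <- run_pipeline(sim$notes, sim$bundle)
glance(evaluate_alerts(alerts, gold_table(sim$gold), "mention"))
```

## Command line

A thin wrapper over the same functions lives at
`inst/cli/adrminer.R`:

```sh
Rscript inst/cli/adrminer.R simulate --out-dir sim --seed 1
Rscript inst/cli/adrminer.R run --notes sim/notes.csv --lexicons sim/lexicons \
    --out alerts.csv --full-out alerts_full.csv --report report.json
Rscript inst/cli/adrminer.R evaluate --alerts alerts_full.csv \
    --gold sim/gold.csv --level mention --out metrics.json
```

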