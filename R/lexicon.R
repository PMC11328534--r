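#' Default excluded system organ classes
#'
#' Four MedDRA system organ classes (SOCs) carry no adverse-drug-reaction
#' content and are excluded when the ADR term dictionary is loaded:
#' "Social circumstances", "Surgical and medical procedures",
#' "Investigations", and "Product issues".
#'
#' @return Character vector of four SOC labels.
#' @export
default_excluded_socs <- function() {
  c(
    "Social circumstances",
    "Surgical and medical procedures",
    "Investigations",
    "Product issues"
  )
}

#' Default negation lexicon
#'
#' The four Dutch negation words used by the negation refinement stage:
#' "geen" (none), "niet" (not), "niks" (nothing), "nooit" (never). A
#' negation word within `window_chars` characters of an ADR term mention
#' cancels the candidate.
#'
#' @param window_chars Maximum edge-to-edge character gap at which a
#'   negation word cancels a term mention (default 10).
#' @return A tibble with columns `word` and attribute `window_chars`.
#' @export
default_negations <- function(window_chars = 10L) {
  stopifnot(window_chars >= 0)
  out <- tibble(word = c("geen", "niet", "niks", "nooit"))
  attr(out, "window_chars") <- as.integer(window_chars)
  out
}

#' Load an ADR term dictionary
#'
#' Reads a tab-separated ADR term table with a MedDRA-like hierarchy
#' (lower-level term LLT, preferred term PT, system organ class SOC) plus
#' pipe-delimited synonyms and an Important-Medical-Event flag. Rows whose
#' SOC is in `excluded_socs` are dropped; all surfaces are lowercased.
#'
#' @param path Path to a TSV file with columns `llt_code`, `llt_name`,
#'   `pt_code`, `pt_name`, `soc_name`, `synonyms` (pipe-delimited), and
#'   `is_ime` (0/1).
#' @param excluded_socs SOC labels to drop; defaults to the four classes
#'   unrelated to ADRs (see [default_excluded_socs()]).
#' @return A tibble of ADR terms; `synonyms` is a list-column, `is_ime`
#'   logical.
#' @export
load_adr_terms <- function(path, excluded_socs = default_excluded_socs()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  adr_terms(raw, excluded_socs = excluded_socs)
}

#' Validate an in-memory ADR term table
#'
#' Data-frame-first counterpart of [load_adr_terms()]; applies the same
#' normalization, validation, and SOC exclusion.
#'
#' @param df Data frame with the ADR-term table columns.
#' @inheritParams load_adr_terms
#' @return A tibble of validated ADR terms.
#' @export
adr_terms <- function(df, excluded_socs = default_excluded_socs()) {
  require_columns(
    df, c("llt_code", "llt_name", "pt_code", "pt_name", "soc_name"),
    "ADR term table"
  )
  out <- as_tibble(df)
  if (!"synonyms" %in% names(out)) out$synonyms <- ""
  if (!"is_ime" %in% names(out)) out$is_ime <- 0
  out <- out |>
    mutate(
      llt_code = as.character(.data$llt_code),
      pt_code = as.character(.data$pt_code),
      llt_name = normalize_surface(.data$llt_name),
      pt_name = normalize_surface(.data$pt_name),
      soc_name = stringr::str_trim(as.character(.data$soc_name)),
      synonyms = purrr::map(split_pipe(as.character(.data$synonyms)),
                            normalize_surface),
      is_ime = parse_flag(.data$is_ime)
    )
  if (any(!nzchar(out$llt_name))) {
    abort_schema("ADR term table: empty llt_name")
  }
  dup <- out$llt_code[duplicated(out$llt_code)]
  if (length(dup) > 0) {
    abort_schema(sprintf(
      "ADR term table: duplicate llt_code: %s",
      paste(unique(dup), collapse = ", ")
    ))
  }
  filter(out, !(.data$soc_name %in% excluded_socs))
}

#' Load a drug lexicon
#'
#' Reads a tab-separated drug table with generic names, brand names,
#' abbreviations, and class names (e.g. "antibiotica"), the shape of the
#' Dutch G-standard drug database. All surfaces are lowercased; a surface
#' shared by several drugs resolves to all of them downstream.
#'
#' @param path Path to a TSV with columns `drug_id`, `generic_name`,
#'   `brand_names`, `abbreviations`, `class_names` (each pipe-delimited).
#' @return A tibble of drug entries with list-columns for the surface sets.
#' @export
load_drug_lexicon <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  drug_lexicon(raw)
}

#' Validate an in-memory drug lexicon
#'
#' @param df Data frame with drug-lexicon columns.
#' @return A tibble of validated drug entries.
#' @export
drug_lexicon <- function(df) {
  require_columns(df, c("drug_id", "generic_name"), "drug lexicon")
  out <- as_tibble(df)
  for (col in c("brand_names", "abbreviations", "class_names")) {
    if (!col %in% names(out)) out[[col]] <- ""
  }
  out <- out |>
    mutate(
      drug_id = as.character(.data$drug_id),
      generic_name = normalize_surface(.data$generic_name),
      brand_names = purrr::map(split_pipe(as.character(.data$brand_names)),
                               normalize_surface),
      abbreviations = purrr::map(split_pipe(as.character(.data$abbreviations)),
                                 normalize_surface),
      class_names = purrr::map(split_pipe(as.character(.data$class_names)),
                               normalize_surface)
    )
  bad <- which(!nzchar(out$generic_name))
  if (length(bad) > 0) {
    abort_schema(sprintf(
      "drug lexicon: empty generic_name at row(s) %s",
      paste(bad, collapse = ", ")
    ))
  }
  out
}

#' Load a trigger lexicon
#'
#' Triggers are the Phase I screening cues: keywords implying an ADR,
#' prepositions expected to be followed by a drug name, and multi-word
#' phrases. Each entry carries a polarity (positive triggers select blocks,
#' negative triggers suppress them) and a strategy tag naming the detection
#' strategy it serves (`keyword`, `preposition`, or `phrase`).
#'
#' @param path Path to a TSV with columns `surface`, `polarity`
#'   (positive|negative), `strategy_tag`. Lines starting with `#` are
#'   ignored, so known-harmful triggers can ship disabled (e.g. the dosing
#'   shorthand "dd", whose inclusion floods the output with false
#'   positives).
#' @return A tibble of trigger entries.
#' @export
load_triggers <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  trigger_lexicon(raw)
}

#' Validate an in-memory trigger lexicon
#'
#' @param df Data frame with columns `surface`, `polarity`, `strategy_tag`.
#' @return A tibble of validated trigger entries.
#' @export
trigger_lexicon <- function(df) {
  require_columns(df, c("surface", "polarity"), "trigger lexicon")
  out <- as_tibble(df)
  if (!"strategy_tag" %in% names(out)) out$strategy_tag <- "keyword"
  out <- out |>
    mutate(
      surface = normalize_surface(.data$surface),
      polarity = stringr::str_to_lower(.data$polarity),
      strategy_tag = stringr::str_to_lower(.data$strategy_tag)
    )
  if (!all(out$polarity %in% c("positive", "negative"))) {
    abort_schema("trigger lexicon: polarity must be positive or negative")
  }
  both <- intersect(out$surface[out$polarity == "positive"],
                    out$surface[out$polarity == "negative"])
  if (length(both) > 0) {
    abort_schema(sprintf(
      "trigger lexicon: surface(s) in both polarities: %s",
      paste(both, collapse = ", ")
    ))
  }
  out
}

#' Load a negation lexicon
#'
#' @param path Path to a TSV with a single `word` column.
#' @param window_chars Negation window in characters (default 10).
#' @return A tibble with column `word` and attribute `window_chars`.
#' @export
load_negations <- function(path, window_chars = 10L) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  require_columns(raw, "word", "negation lexicon")
  out <- tibble(word = normalize_surface(raw$word))
  attr(out, "window_chars") <- as.integer(window_chars)
  out
}

#' Bundle all lexicons for a pipeline run
#'
#' Collects the dictionaries every matching stage consults: ADR terms,
#' drugs, triggers, negations, and the Phase II keep/drop surface lists.
#' Validates that each positive/negative list pair is disjoint and that no
#' retained ADR term sits in an excluded SOC.
#'
#' @param adr_terms Tibble from [adr_terms()] / [load_adr_terms()].
#' @param drugs Tibble from [drug_lexicon()] / [load_drug_lexicon()].
#' @param triggers Tibble from [trigger_lexicon()] / [load_triggers()].
#' @param negations Tibble from [default_negations()] / [load_negations()].
#' @param positive_term_list,negative_term_list Character vectors of ADR
#'   surfaces to force-keep / drop in the term-list refinement stage.
#' @param positive_drug_list,negative_drug_list Character vectors of drug
#'   surfaces to force-keep / drop in the drug-list refinement stage.
#' @param excluded_socs SOC labels excluded from matching.
#' @return A `lexicon_bundle` list.
#' @export
lexicon_bundle <- function(adr_terms,
                           drugs,
                           triggers = trigger_lexicon(
                             tibble(surface = character(),
                                    polarity = character(),
                                    strategy_tag = character())
                           ),
                           negations = default_negations(),
                           positive_term_list = character(),
                           negative_term_list = character(),
                           positive_drug_list = character(),
                           negative_drug_list = character(),
                           excluded_socs = default_excluded_socs()) {
  if (any(adr_terms$soc_name %in% excluded_socs)) {
    abort_schema("lexicon bundle: ADR terms remain in excluded SOCs")
  }
  check_disjoint <- function(pos, neg, what) {
    both <- intersect(normalize_surface(pos), normalize_surface(neg))
    if (length(both) > 0) {
      abort_schema(sprintf("%s positive/negative lists overlap: %s",
                           what, paste(both, collapse = ", ")))
    }
  }
  check_disjoint(positive_term_list, negative_term_list, "term")
  check_disjoint(positive_drug_list, negative_drug_list, "drug")
  structure(
    list(
      adr_terms = adr_terms,
      drugs = drugs,
      triggers = triggers,
      negations = negations,
      positive_term_list = normalize_surface(positive_term_list),
      negative_term_list = normalize_surface(negative_term_list),
      positive_drug_list = normalize_surface(positive_drug_list),
      negative_drug_list = normalize_surface(negative_drug_list),
      excluded_socs = excluded_socs
    ),
    class = "lexicon_bundle"
  )
}

#' @export
print.lexicon_bundle <- function(x, ...) {
  cat("<lexicon_bundle>\n")
  cat(sprintf("  ADR terms : %d (LLT)\n", nrow(x$adr_terms)))
  cat(sprintf("  drugs     : %d\n", nrow(x$drugs)))
  cat(sprintf("  triggers  : %d (%d positive, %d negative)\n",
              nrow(x$triggers),
              sum(x$triggers$polarity == "positive"),
              sum(x$triggers$polarity == "negative")))
  cat(sprintf("  negations : %s (window %d chars)\n",
              paste(x$negations$word, collapse = ", "),
              attr(x$negations, "window_chars") %||% 10L))
  invisible(x)
}

#' Load a full lexicon bundle from a directory
#'
#' Expects `adr_terms.tsv`, `drugs.tsv`, `triggers.tsv` and optionally
#' `negations.tsv`, `positive_terms.tsv`, `negative_terms.tsv`,
#' `positive_drugs.tsv`, `negative_drugs.tsv` (single `surface` column).
#'
#' @param dir Directory holding the lexicon TSV files.
#' @param excluded_socs SOC labels to exclude.
#' @param window_chars Negation window in characters.
#' @return A `lexicon_bundle`.
#' @export
load_lexicon_dir <- function(dir, excluded_socs = default_excluded_socs(),
                             window_chars = 10L) {
  p <- function(f) file.path(dir, f)
  read_list <- function(f) {
    if (!file.exists(p(f))) return(character())
    readr::read_tsv(p(f), col_types = readr::cols(.default = "c"),
                    progress = FALSE)$surface
  }
  negations <- if (file.exists(p("negations.tsv"))) {
    load_negations(p("negations.tsv"), window_chars)
  } else {
    default_negations(window_chars)
  }
  lexicon_bundle(
    adr_terms = load_adr_terms(p("adr_terms.tsv"), excluded_socs),
    drugs = load_drug_lexicon(p("drugs.tsv")),
    triggers = if (file.exists(p("triggers.tsv"))) {
      load_triggers(p("triggers.tsv"))
    } else {
      trigger_lexicon(tibble(surface = character(), polarity = character(),
                             strategy_tag = character()))
    },
    negations = negations,
    positive_term_list = read_list("positive_terms.tsv"),
    negative_term_list = read_list("negative_terms.tsv"),
    positive_drug_list = read_list("positive_drugs.tsv"),
    negative_drug_list = read_list("negative_drugs.tsv"),
    excluded_socs = excluded_socs
  )
}
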