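#' Pipeline configuration
#'
#' One object holding every tunable of the two-phase pipeline. Defaults
#' reproduce the final configuration: all four trigger strategies, the
#' `any_positive` selection policy, a 43-character inclusive pairing
#' threshold, exact (non-variant) matching, and the refinement chain with
#' drug/term list filters, deduplication, and seriousness enabled while
#' negation and variant matching stay off.
#'
#' @param trigger_policy Block selection policy, see
#'   [select_candidate_blocks()].
#' @param field_categories Note categories / form names treated as
#'   complication-style field triggers.
#' @param enabled_strategies Trigger strategies to run.
#' @param max_distance Maximum term-drug character gap, inclusive.
#' @param use_variants Match one-edit typo variants at scan time.
#' @param pairing_mode `"nearest"` or `"all"`, see [pair_candidates()].
#' @param stages Refinement stage settings from [default_stages()].
#' @param max_block_chars Block segmentation limit, see [segment_blocks()].
#' @return An `adr_config` list.
#' @export
adr_config <- function(trigger_policy = "any_positive",
                       field_categories = c("complicatie",
                                            "complicatieregistratie"),
                       enabled_strategies = c("keyword", "preposition",
                                              "field", "phrase"),
                       max_distance = 43L,
                       use_variants = FALSE,
                       pairing_mode = "nearest",
                       stages = default_stages(),
                       max_block_chars = 2000L) {
  structure(
    list(trigger_policy = trigger_policy,
         field_categories = field_categories,
         enabled_strategies = enabled_strategies,
         max_distance = as.integer(max_distance),
         use_variants = isTRUE(use_variants),
         pairing_mode = pairing_mode,
         stages = stages,
         max_block_chars = as.integer(max_block_chars)),
    class = "adr_config"
  )
}

#' Run the full ADR detection pipeline
#'
#' Executes the Figure-style flow: segment notes into blocks, flag
#' candidate blocks with trigger strategies, find ADR-term and drug
#' mentions in the candidates, pair them by character proximity, and
#' refine the candidates into unique alerts. The returned alerts carry the
#' trigger surface that selected the block, the matched term and drug, the
#' character distance and proximity score, the seriousness flag, and the
#' surrounding paragraph. A per-stage count log is attached as the
#' `"run_report"` attribute.
#'
#' @param notes Notes tibble from [read_notes()] / [notes_table()].
#' @param bundle A [lexicon_bundle()].
#' @param config An [adr_config()].
#' @return Alerts tibble (see [alert_columns()]) with a `run_report`
#'   attribute.
#' @export
run_pipeline <- function(notes, bundle, config = adr_config()) {
  blocks <- segment_blocks(notes, config$max_block_chars)
  index <- build_term_index(bundle)
  hits <- match_triggers(
    blocks, bundle$triggers, drug_index = index,
    field_categories = config$field_categories,
    enabled_strategies = config$enabled_strategies
  )
  selected <- select_candidate_blocks(hits, config$trigger_policy)
  cand_blocks <- filter(blocks, .data$block_id %in% selected)
  mentions <- find_mentions(cand_blocks, index,
                            use_variants = config$use_variants)
  cands <- pair_candidates(mentions, cand_blocks,
                           max_distance = config$max_distance,
                           mode = config$pairing_mode)
  cands <- attach_triggers(cands, hits)
  alerts <- run_stage_chain(cands, bundle, config$stages)
  report <- bind_rows(
    tibble(stage = c("segment", "trigger_select", "mention_scan", "pairing"),
           n_in = c(nrow(notes), nrow(blocks), length(selected),
                    nrow(mentions)),
           n_out = c(nrow(blocks), length(selected), nrow(mentions),
                     nrow(cands))),
    attr(alerts, "stage_log")
  )
  attr(alerts, "run_report") <- report
  alerts
}

# label each candidate with the nearest positive trigger hit in its block
attach_triggers <- function(cands, hits) {
  if (nrow(cands) == 0) return(cands)
  pos <- filter(hits, .data$polarity == "positive")
  if (nrow(pos) == 0) return(cands)
  nearest <- cands |>
    mutate(cand_uid = row_number()) |>
    select(dplyr::all_of(c("cand_uid", "block_id", "term_start",
                           "term_end"))) |>
    dplyr::inner_join(
      select(pos, dplyr::all_of(c("block_id", "surface", "start", "end"))),
      by = "block_id", relationship = "many-to-many"
    ) |>
    mutate(gap = dplyr::if_else(
      is.na(.data$start), .Machine$integer.max,
      span_gap(.data$term_start, .data$term_end, .data$start, .data$end)
    )) |>
    group_by(.data$cand_uid) |>
    arrange(.data$gap, .data$start) |>
    slice(1) |>
    ungroup()
  cands$trigger_surface[nearest$cand_uid] <- nearest$surface
  cands
}

#' Columns of the alert output table
#'
#' The notification row written for each unique ADR: patient number, the
#' trigger that fired, the matched ADR text, the surrounding paragraph, the
#' note category, the involved medication, the LLT term and code, the
#' registering healthcare professional, the timestamp, the seriousness
#' flag, and the proximity score.
#'
#' @return Character vector of column names.
#' @export
alert_columns <- function() {
  c("patient_id", "trigger_surface", "adr_text", "paragraph",
    "note_category", "medication", "llt_name", "llt_code", "author_role",
    "timestamp", "serious", "proximity_score")
}

#' Format alerts for output and write them as CSV
#'
#' @param alerts Alerts tibble from [run_pipeline()].
#' @param path Output CSV path; `NULL` returns the formatted tibble only.
#' @return The formatted alert tibble (invisibly when written).
#' @export
write_alerts <- function(alerts, path = NULL) {
  out <- alerts |>
    mutate(
      adr_text = .data$term_matched,
      note_category = .data$category,
      medication = .data$drug_surface,
      timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      serious = as.integer(.data$serious)
    ) |>
    select(dplyr::all_of(alert_columns()))
  if (is.null(path)) return(out)
  readr::write_csv(out, path, progress = FALSE)
  invisible(out)
}

#' Per-stage candidate counts of a pipeline run
#'
#' @param alerts Alerts tibble from [run_pipeline()].
#' @return The `run_report` tibble (stage, n_in, n_out).
#' @export
run_report <- function(alerts) {
  attr(alerts, "run_report") %||%
    tibble(stage = character(), n_in = integer(), n_out = integer())
}
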