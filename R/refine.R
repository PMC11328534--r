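#' Filter candidates by positive/negative drug lists
#'
#' Drops candidates whose matched drug surface is on the negative drug
#' list; surfaces on the positive list are always retained by this stage.
#' The two lists are curated keep/drop libraries of drug names.
#'
#' @param cands Candidates tibble from [pair_candidates()].
#' @param positive_drug_list,negative_drug_list Disjoint character vectors
#'   of drug surfaces.
#' @return The surviving candidates.
#' @export
filter_by_drug_lists <- function(cands, positive_drug_list = character(),
                                 negative_drug_list = character()) {
  check_disjoint_lists(positive_drug_list, negative_drug_list, "drug")
  filter(
    cands,
    .data$drug_surface %in% normalize_surface(positive_drug_list) |
      .data$drug_lex_surface %in% normalize_surface(positive_drug_list) |
      !(.data$drug_surface %in% normalize_surface(negative_drug_list) |
          .data$drug_lex_surface %in% normalize_surface(negative_drug_list))
  )
}

#' Filter candidates by positive/negative ADR-term lists
#'
#' Symmetric to [filter_by_drug_lists()], keyed on the matched ADR-term
#' surface. A negated term is retained by this stage: negation handling is
#' a separate stage.
#'
#' @param cands Candidates tibble.
#' @param positive_term_list,negative_term_list Disjoint character vectors
#'   of ADR-term surfaces.
#' @return The surviving candidates.
#' @export
filter_by_term_lists <- function(cands, positive_term_list = character(),
                                 negative_term_list = character()) {
  check_disjoint_lists(positive_term_list, negative_term_list, "term")
  filter(
    cands,
    .data$term_matched %in% normalize_surface(positive_term_list) |
      .data$term_surface %in% normalize_surface(positive_term_list) |
      !(.data$term_matched %in% normalize_surface(negative_term_list) |
          .data$term_surface %in% normalize_surface(negative_term_list))
  )
}

check_disjoint_lists <- function(pos, neg, what) {
  both <- intersect(normalize_surface(pos), normalize_surface(neg))
  if (length(both) > 0) {
    stop(sprintf("%s positive/negative lists overlap: %s", what,
                 paste(both, collapse = ", ")), call. = FALSE)
  }
}

#' Remove duplicate ADR candidates
#'
#' The same reaction to the same drug in the same patient — typically
#' produced by copy-paste between notes — is reported once. For each
#' deduplication key `(patient_id, drug_id, llt_code)` the earliest
#' candidate by timestamp is kept, ties broken by `note_id` then block
#' offset. Idempotent.
#'
#' @param cands Candidates tibble.
#' @return One candidate per deduplication key, in deterministic order.
#' @export
deduplicate <- function(cands) {
  cands |>
    arrange(.data$timestamp, .data$note_id, .data$block_id,
            .data$term_start, .data$drug_start) |>
    distinct(.data$patient_id, .data$drug_id, .data$llt_code,
             .keep_all = TRUE)
}

#' Drop candidates whose ADR term is negated
#'
#' A candidate is removed when one of the negation words ("geen", "niet",
#' "niks", "nooit" by default) occurs within `window_chars` characters of
#' the term mention — the edge-to-edge gap on the normalized text, in
#' either direction. Default window: 10 characters.
#'
#' @param cands Candidates tibble.
#' @param negations Negation lexicon (see [default_negations()]).
#' @param window_chars Window size; defaults to the lexicon's
#'   `window_chars` attribute.
#' @return Candidates whose term is not negated.
#' @export
filter_negated <- function(cands, negations = default_negations(),
                           window_chars = NULL) {
  window_chars <- window_chars %||% attr(negations, "window_chars") %||% 10L
  stopifnot(window_chars >= 0)
  if (nrow(cands) == 0) return(cands)
  negated <- purrr::pmap_lgl(
    list(cands$norm_text, cands$term_start, cands$term_end),
    function(norm_text, term_start, term_end) {
      for (w in negations$word) {
        loc <- str_locate_all(norm_text, word_pattern(w))[[1]]
        if (nrow(loc) == 0) next
        gaps <- span_gap(term_start, term_end,
                         as.integer(loc[, 1]), as.integer(loc[, 2]))
        if (any(gaps <= window_chars)) return(TRUE)
      }
      FALSE
    }
  )
  cands[!negated, ]
}

#' Flag potentially serious ADRs
#'
#' Marks a candidate serious when its LLT or PT code is on the Important
#' Medical Event (IME) list. No candidate is dropped.
#'
#' @param cands Candidates tibble.
#' @param ime_codes Character vector of LLT/PT codes on the IME list, or an
#'   ADR-term tibble with an `is_ime` column.
#' @return The candidates with a logical `serious` column.
#' @export
classify_seriousness <- function(cands, ime_codes) {
  if (is.data.frame(ime_codes)) {
    ime <- ime_codes |> filter(.data$is_ime)
    ime_codes <- unique(c(ime$llt_code, ime$pt_code))
  }
  mutate(cands, serious = .data$llt_code %in% ime_codes |
           .data$pt_code %in% ime_codes)
}

#' Default refinement stage configuration
#'
#' The final pipeline configuration enables the four stages that improved
#' sensitivity and/or PPV — drug-list filter, term-list filter,
#' deduplication, seriousness — and disables negation (it lowered PPV) and
#' one-edit variant matching. Variant matching is applied at scan time
#' ([find_mentions()]); its toggle lives in [adr_config()].
#'
#' @param drug_filter,term_filter,dedup,negation,seriousness Logical
#'   toggles per stage.
#' @param order Stage application order.
#' @return Named list of stage settings.
#' @export
default_stages <- function(drug_filter = TRUE, term_filter = TRUE,
                           dedup = TRUE, negation = FALSE,
                           seriousness = TRUE,
                           order = c("drug_filter", "term_filter", "negation",
                                     "dedup", "seriousness")) {
  unknown <- setdiff(order, c("drug_filter", "term_filter", "negation",
                              "dedup", "seriousness"))
  if (length(unknown) > 0) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  list(
    enabled = c(drug_filter = drug_filter, term_filter = term_filter,
                dedup = dedup, negation = negation,
                seriousness = seriousness),
    order = order
  )
}

#' Run the refinement stage chain
#'
#' Applies the enabled refinement stages in the configured order and
#' returns the resulting alerts. Filtering stages only ever drop rows;
#' seriousness only annotates. A per-stage input/output count log is
#' attached as the `"stage_log"` attribute.
#'
#' @param cands Candidates tibble.
#' @param bundle [lexicon_bundle()] supplying the stage lexicons.
#' @param stages Stage configuration from [default_stages()].
#' @return Alerts tibble with a `serious` column (FALSE when the
#'   seriousness stage is disabled) and a `stage_log` attribute.
#' @export
run_stage_chain <- function(cands, bundle, stages = default_stages()) {
  log <- list()
  out <- cands
  for (st in stages$order) {
    if (!isTRUE(stages$enabled[[st]])) next
    n_in <- nrow(out)
    out <- switch(
      st,
      drug_filter = filter_by_drug_lists(out, bundle$positive_drug_list,
                                         bundle$negative_drug_list),
      term_filter = filter_by_term_lists(out, bundle$positive_term_list,
                                         bundle$negative_term_list),
      dedup = deduplicate(out),
      negation = filter_negated(out, bundle$negations),
      seriousness = classify_seriousness(out, bundle$adr_terms),
      stop("unknown stage: ", st, call. = FALSE)
    )
    log[[length(log) + 1L]] <- tibble(stage = st, n_in = n_in,
                                      n_out = nrow(out))
  }
  if (!"serious" %in% names(out)) out$serious <- FALSE
  attr(out, "stage_log") <- if (length(log) > 0) {
    bind_rows(log)
  } else {
    tibble(stage = character(), n_in = integer(), n_out = integer())
  }
  out
}
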