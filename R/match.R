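#' Find ADR-term and drug mentions in text blocks
#'
#' Scans each block's normalized text against the surface index with a
#' longest-match, non-overlapping, left-to-right rule (per surface kind:
#' term and drug mentions do not block each other). With
#' `use_variants = TRUE`, tokens that match no surface exactly but sit in a
#' lexicon surface's one-edit variant set (one substitution or one
#' insertion — the typo model) are matched too and flagged `via_variant`.
#'
#' @param blocks Blocks tibble from [segment_blocks()]; a subset (e.g.
#'   trigger-selected candidate blocks) is typical.
#' @param index A [build_term_index()].
#' @param use_variants Also match one-edit typo variants (default `FALSE`,
#'   the final pipeline configuration).
#' @return A tibble of mentions: `block_id`, `note_id`, `kind` (term|drug),
#'   `id` (llt_code or drug_id), `surface` (lexicon surface),
#'   `matched_surface` (text actually matched), `surface_kind`, `pt_code`,
#'   `llt_name`, `start`, `end` (normalized-text span), `via_variant`,
#'   `ambiguous`.
#' @export
find_mentions <- function(blocks, index, use_variants = FALSE) {
  empty <- tibble(
    block_id = character(), note_id = character(), kind = character(),
    id = character(), surface = character(), matched_surface = character(),
    surface_kind = character(), pt_code = character(), llt_name = character(),
    start = integer(), end = integer(), via_variant = logical(),
    ambiguous = logical()
  )
  if (nrow(blocks) == 0 || nrow(index) == 0) return(empty)

  surfaces <- distinct(index, .data$surface, .data$kind)
  raw_hits <- purrr::pmap_dfr(surfaces, function(surface, kind) {
    loc <- locate_all_words(blocks$norm_text, surface)
    purrr::imap_dfr(loc, function(m, i) {
      if (nrow(m) == 0) return(NULL)
      tibble(block_row = i, surface = surface, kind = kind,
             start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             via_variant = FALSE)
    })
  })

  if (use_variants) {
    raw_hits <- bind_rows(raw_hits, variant_hits(blocks, index))
  }
  if (nrow(raw_hits) == 0) return(empty)

  # greedy longest-match, left-to-right, per block and kind; identical spans
  # (ambiguous surfaces) survive as one span with all owners re-joined below
  selected <- raw_hits |>
    distinct(.data$block_row, .data$kind, .data$surface, .data$start,
             .data$end, .data$via_variant) |>
    mutate(len = .data$end - .data$start + 1L,
           exact = !.data$via_variant) |>
    arrange(.data$block_row, .data$kind, .data$start,
            dplyr::desc(.data$exact), dplyr::desc(.data$len)) |>
    group_by(.data$block_row, .data$kind) |>
    filter(greedy_keep(.data$start, .data$end)) |>
    ungroup()

  selected |>
    left_join(
      select(index, dplyr::all_of(c("surface", "kind", "id", "surface_kind",
                                    "pt_code", "llt_name", "ambiguous"))),
      by = c("surface", "kind"), relationship = "many-to-many"
    ) |>
    mutate(
      block_id = blocks$block_id[.data$block_row],
      note_id = blocks$note_id[.data$block_row],
      matched_surface = str_sub(blocks$norm_text[.data$block_row],
                                .data$start, .data$end)
    ) |>
    arrange(.data$block_row, .data$start, .data$kind, .data$id) |>
    select(dplyr::all_of(c(
      "block_id", "note_id", "kind", "id", "surface", "matched_surface",
      "surface_kind", "pt_code", "llt_name", "start", "end", "via_variant",
      "ambiguous"
    )))
}

# keep spans that do not overlap an earlier-kept span; input ordered by
# start, exact-first, longest-first
greedy_keep <- function(start, end) {
  keep <- logical(length(start))
  last_end <- 0L
  kept_start <- kept_end <- integer(0)
  for (i in seq_along(start)) {
    if (all(start[i] > kept_end | end[i] < kept_start)) {
      keep[i] <- TRUE
      kept_start <- c(kept_start, start[i])
      kept_end <- c(kept_end, end[i])
    }
  }
  keep
}

# one-edit (substitution/insertion) token matches against single-word
# lexicon surfaces; returns rows shaped like the exact raw_hits
variant_hits <- function(blocks, index) {
  single <- distinct(
    filter(index, !str_detect(.data$surface, stringr::fixed(" "))),
    .data$surface, .data$kind
  )
  if (nrow(single) == 0) return(NULL)
  tok_loc <- str_locate_all(blocks$norm_text, "[\\p{L}\\p{N}][\\p{L}\\p{N}-]*")
  tokens <- purrr::imap_dfr(tok_loc, function(m, i) {
    if (nrow(m) == 0) return(NULL)
    tibble(block_row = i, start = as.integer(m[, 1]), end = as.integer(m[, 2]),
           token = str_sub(blocks$norm_text[i], m[, 1], m[, 2]))
  })
  if (nrow(tokens) == 0) return(NULL)
  utoks <- unique(tokens$token)
  d <- utils::adist(single$surface, utoks,
                    costs = list(insertions = 1L, deletions = 1000L,
                                 substitutions = 1L))
  pairs <- which(d == 1L, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(NULL)
  matches <- tibble(
    surface = single$surface[pairs[, 1]],
    kind = single$kind[pairs[, 1]],
    token = utoks[pairs[, 2]]
  )
  tokens |>
    dplyr::inner_join(matches, by = "token",
                      relationship = "many-to-many") |>
    mutate(via_variant = TRUE) |>
    select(dplyr::all_of(c("block_row", "surface", "kind", "start", "end",
                           "via_variant")))
}

#' Pair ADR-term mentions with nearby drug mentions
#'
#' Forms an ADR candidate from every term mention that has a drug mention
#' within `max_distance` characters in the same block. The distance is the
#' number of characters strictly between the two spans' nearer edges on the
#' normalized text (0 when they touch or overlap); the threshold is
#' inclusive, default 43 — the maximum term–drug distance observed for true
#' ADR mentions. With `mode = "nearest"` each term pairs only with its
#' nearest drug (ties broken toward the drug occurring earlier in the
#' text); `mode = "all"` emits every in-range pair. A per-candidate
#' `proximity_score` in 1..100 (100 = adjacent) is attached for ranking;
#' it never gates emission.
#'
#' @param mentions Mention tibble from [find_mentions()].
#' @param blocks Blocks tibble (supplies note metadata and the surrounding
#'   paragraph).
#' @param max_distance Maximum character gap, inclusive (default 43).
#' @param mode `"nearest"` (default) or `"all"`.
#' @return A candidates tibble, one row per (term mention, paired drug).
#' @export
pair_candidates <- function(mentions, blocks, max_distance = 43L,
                            mode = c("nearest", "all")) {
  mode <- match.arg(mode)
  stopifnot(max_distance >= 0)
  terms <- mentions |>
    filter(.data$kind == "term") |>
    mutate(term_uid = row_number())
  drugs <- filter(mentions, .data$kind == "drug")
  empty <- empty_candidates()
  if (nrow(terms) == 0 || nrow(drugs) == 0) return(empty)

  pairs <- dplyr::inner_join(
    terms |>
      select(dplyr::all_of(c("term_uid", "block_id", "note_id", "id",
                             "surface", "matched_surface", "surface_kind",
                             "pt_code", "llt_name", "start", "end",
                             "via_variant"))) |>
      rename(
        llt_code = "id", term_surface = "surface",
        term_matched = "matched_surface", term_surface_kind = "surface_kind",
        term_start = "start", term_end = "end", term_via_variant = "via_variant"
      ),
    drugs |>
      select(dplyr::all_of(c("block_id", "id", "surface", "matched_surface",
                             "surface_kind", "start", "end", "via_variant"))) |>
      rename(
        drug_id = "id", drug_lex_surface = "surface",
        drug_surface = "matched_surface", drug_surface_kind = "surface_kind",
        drug_start = "start", drug_end = "end",
        drug_via_variant = "via_variant"
      ),
    by = "block_id", relationship = "many-to-many"
  ) |>
    mutate(distance_chars = span_gap(.data$term_start, .data$term_end,
                                     .data$drug_start, .data$drug_end)) |>
    filter(.data$distance_chars <= max_distance)
  if (nrow(pairs) == 0) return(empty)

  if (mode == "nearest") {
    pairs <- pairs |>
      group_by(.data$term_uid) |>
      filter(.data$distance_chars == min(.data$distance_chars)) |>
      filter(.data$drug_start == min(.data$drug_start)) |>
      ungroup()
  }

  meta <- select(blocks, dplyr::all_of(c(
    "block_id", "patient_id", "form_name", "category", "author_role",
    "timestamp", "text", "norm_text"
  )))
  pairs |>
    left_join(meta, by = "block_id") |>
    mutate(
      proximity_score = proximity_score(.data$distance_chars, max_distance),
      paragraph = .data$text,
      trigger_surface = NA_character_
    ) |>
    arrange(.data$block_id, .data$term_start, .data$drug_start,
            .data$llt_code, .data$drug_id) |>
    select(dplyr::all_of(candidate_columns()))
}

proximity_score <- function(distance, max_distance) {
  if (max_distance == 0) return(rep(100L, length(distance)))
  as.integer(pmin(100, pmax(1, round(100 * (1 - distance / max_distance)))))
}

candidate_columns <- function() {
  c("patient_id", "note_id", "form_name", "category", "author_role",
    "timestamp", "block_id", "trigger_surface", "llt_code", "llt_name",
    "pt_code", "term_surface", "term_matched", "term_surface_kind",
    "term_start", "term_end", "term_via_variant", "drug_id",
    "drug_lex_surface", "drug_surface", "drug_surface_kind", "drug_start",
    "drug_end", "drug_via_variant", "distance_chars", "proximity_score",
    "paragraph", "norm_text")
}

empty_candidates <- function() {
  out <- tibble(
    patient_id = character(), note_id = character(), form_name = character(),
    category = character(), author_role = character(),
    timestamp = as.POSIXct(character()), block_id = character(),
    trigger_surface = character(), llt_code = character(),
    llt_name = character(), pt_code = character(), term_surface = character(),
    term_matched = character(), term_surface_kind = character(),
    term_start = integer(), term_end = integer(),
    term_via_variant = logical(), drug_id = character(),
    drug_lex_surface = character(), drug_surface = character(),
    drug_surface_kind = character(), drug_start = integer(),
    drug_end = integer(), drug_via_variant = logical(),
    distance_chars = integer(), proximity_score = integer(),
    paragraph = character(), norm_text = character()
  )
  out[, candidate_columns()]
}
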