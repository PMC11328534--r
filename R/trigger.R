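#' Match trigger strategies against text blocks
#'
#' Phase I screening: flags blocks that may contain an ADR using four
#' pluggable strategies.
#'
#' * `keyword` — whole-word match of a single-word trigger surface
#'   (e.g. "allergie", "bijwerking").
#' * `preposition` — a preposition trigger (e.g. "wegens", "door") whose
#'   next token resolves in the drug index (generic, brand, abbreviation,
#'   or class name).
#' * `field` — the block's note category or form name is in
#'   `field_categories` (e.g. a complication registration field); fires
#'   once per block regardless of text, with an empty span.
#' * `phrase` — whole-word match of a multi-word surface (e.g.
#'   "door medicatie", the Dutch "drug-induced" pattern).
#'
#' Negative triggers produce hits with `polarity = "negative"`, consumed by
#' [select_candidate_blocks()].
#'
#' @param blocks Blocks tibble from [segment_blocks()].
#' @param triggers Trigger lexicon tibble (see [trigger_lexicon()]).
#' @param drug_index A [build_term_index()] result (only drug rows are
#'   consulted, by the preposition strategy).
#' @param field_categories Character vector of note categories / form names
#'   that count as complication-style fields.
#' @param enabled_strategies Subset of
#'   `c("keyword", "preposition", "field", "phrase")`.
#' @return A tibble of trigger hits: `block_id`, `note_id`, `surface`,
#'   `strategy`, `polarity`, `start`, `end` (normalized-text span; `NA` for
#'   field hits).
#' @export
match_triggers <- function(blocks, triggers, drug_index = NULL,
                           field_categories = character(),
                           enabled_strategies = c("keyword", "preposition",
                                                  "field", "phrase")) {
  enabled_strategies <- match.arg(
    enabled_strategies, c("keyword", "preposition", "field", "phrase"),
    several.ok = TRUE
  )
  empty <- tibble(
    block_id = character(), note_id = character(), surface = character(),
    strategy = character(), polarity = character(),
    start = integer(), end = integer()
  )
  if (nrow(blocks) == 0) return(empty)
  hits <- list(empty)

  word_hits <- function(trig_rows, strategy_name) {
    if (nrow(trig_rows) == 0) return(empty)
    purrr::pmap_dfr(
      list(trig_rows$surface, trig_rows$polarity),
      function(surface, polarity) {
        loc <- locate_all_words(blocks$norm_text, surface)
        found <- purrr::imap_dfr(loc, function(m, i) {
          if (nrow(m) == 0) return(NULL)
          tibble(block_id = blocks$block_id[i], note_id = blocks$note_id[i],
                 start = as.integer(m[, 1]), end = as.integer(m[, 2]))
        })
        if (nrow(found) == 0) return(empty)
        mutate(found, surface = surface, strategy = strategy_name,
               polarity = polarity)
      }
    )
  }

  if ("keyword" %in% enabled_strategies) {
    kw <- filter(triggers, .data$strategy_tag == "keyword")
    hits[[length(hits) + 1L]] <- word_hits(kw, "keyword")
  }
  if ("phrase" %in% enabled_strategies) {
    ph <- filter(triggers, .data$strategy_tag == "phrase")
    hits[[length(hits) + 1L]] <- word_hits(ph, "phrase")
  }
  if ("preposition" %in% enabled_strategies) {
    pr <- filter(triggers, .data$strategy_tag == "preposition")
    if (nrow(pr) > 0) {
      drug_surfaces <- if (is.null(drug_index)) {
        character(0)
      } else {
        drug_index$surface[drug_index$kind == "drug"]
      }
      prep_hits <- purrr::pmap_dfr(
        list(pr$surface, pr$polarity),
        function(surface, polarity) {
          pat <- paste0(word_pattern(surface), "\\s+([\\p{L}\\p{N}-]+)")
          loc <- str_locate_all(blocks$norm_text, pat)
          purrr::imap_dfr(loc, function(m, i) {
            if (nrow(m) == 0) return(NULL)
            frag <- str_sub(blocks$norm_text[i], m[, 1], m[, 2])
            token <- stringr::str_match(
              frag, paste0(word_pattern(surface), "\\s+([\\p{L}\\p{N}-]+)")
            )[, 2]
            keep <- token %in% drug_surfaces
            if (!any(keep)) return(NULL)
            tibble(
              block_id = blocks$block_id[i], note_id = blocks$note_id[i],
              surface = surface, strategy = "preposition",
              polarity = polarity,
              start = as.integer(m[keep, 1]),
              end = as.integer(m[keep, 1]) + nchar(surface) - 1L
            )
          })
        }
      )
      hits[[length(hits) + 1L]] <- prep_hits
    }
  }
  if ("field" %in% enabled_strategies && length(field_categories) > 0) {
    fc <- normalize_surface(field_categories)
    in_field <- normalize_surface(dplyr::coalesce(blocks$category, "")) %in% fc |
      normalize_surface(dplyr::coalesce(blocks$form_name, "")) %in% fc
    if (any(in_field)) {
      hits[[length(hits) + 1L]] <- tibble(
        block_id = blocks$block_id[in_field],
        note_id = blocks$note_id[in_field],
        surface = dplyr::coalesce(blocks$category[in_field],
                                  blocks$form_name[in_field]),
        strategy = "field", polarity = "positive",
        start = NA_integer_, end = NA_integer_
      )
    }
  }
  bind_rows(hits) |>
    arrange(.data$block_id, .data$start, .data$surface) |>
    select(dplyr::all_of(c("block_id", "note_id", "surface", "strategy",
                           "polarity", "start", "end")))
}

#' Select candidate blocks from trigger hits
#'
#' @param hits Trigger-hit tibble from [match_triggers()].
#' @param policy `"any_positive"` (a block with at least one positive hit is
#'   selected) or `"positive_minus_negative"` (a block is selected only if
#'   it has a positive hit and no negative hit in the same block).
#' @return Character vector of selected `block_id`s.
#' @export
select_candidate_blocks <- function(hits,
                                    policy = c("any_positive",
                                               "positive_minus_negative")) {
  if (is.character(policy) &&
      !all(policy %in% c("any_positive", "positive_minus_negative"))) {
    stop("unknown trigger policy: ", paste(policy, collapse = ", "),
         call. = FALSE)
  }
  policy <- match.arg(policy)
  pos <- unique(hits$block_id[hits$polarity == "positive"])
  if (policy == "any_positive") return(sort(pos))
  neg <- unique(hits$block_id[hits$polarity == "negative"])
  sort(setdiff(pos, neg))
}
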