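#' Build a surface index over ADR terms and drugs
#'
#' Flattens every matchable surface — LLT names, PT names, synonyms,
#' generic/brand/abbreviation/class drug names — into one longest-match-first
#' lookup table. Each surface row points back to its owning record; a
#' surface shared by several records (e.g. the abbreviation "asa" used by
#' two drugs) yields one row per owner and is flagged ambiguous.
#'
#' @param bundle A [lexicon_bundle()].
#' @return A `term_index`: a tibble with columns `surface`, `kind`
#'   (term|drug), `id` (llt_code or drug_id), `surface_kind`, `pt_code`,
#'   `llt_name`, `nchar`, `ambiguous`, ordered by decreasing surface length.
#' @export
build_term_index <- function(bundle) {
  stopifnot(inherits(bundle, "lexicon_bundle"))
  at <- bundle$adr_terms
  term_rows <- if (nrow(at) == 0) {
    tibble(surface = character(), kind = character(), id = character(),
           surface_kind = character(), pt_code = character(),
           llt_name = character())
  } else {
    bind_rows(
      tibble(surface = at$llt_name, kind = "term", id = at$llt_code,
             surface_kind = "llt_name", pt_code = at$pt_code,
             llt_name = at$llt_name),
      tibble(surface = at$pt_name, kind = "term", id = at$llt_code,
             surface_kind = "pt_name", pt_code = at$pt_code,
             llt_name = at$llt_name),
      tibble(
        surface = unlist(at$synonyms),
        kind = "term",
        id = rep(at$llt_code, lengths(at$synonyms)),
        surface_kind = "synonym",
        pt_code = rep(at$pt_code, lengths(at$synonyms)),
        llt_name = rep(at$llt_name, lengths(at$synonyms))
      )
    )
  }
  dr <- bundle$drugs
  drug_surface_rows <- function(surfaces, kind_label) {
    tibble(
      surface = unlist(surfaces),
      kind = "drug",
      id = rep(dr$drug_id, lengths(surfaces)),
      surface_kind = kind_label,
      pt_code = NA_character_,
      llt_name = NA_character_
    )
  }
  drug_rows <- if (nrow(dr) == 0) {
    tibble(surface = character(), kind = character(), id = character(),
           surface_kind = character(), pt_code = character(),
           llt_name = character())
  } else {
    bind_rows(
      tibble(surface = dr$generic_name, kind = "drug", id = dr$drug_id,
             surface_kind = "generic", pt_code = NA_character_,
             llt_name = NA_character_),
      drug_surface_rows(dr$brand_names, "brand"),
      drug_surface_rows(dr$abbreviations, "abbreviation"),
      drug_surface_rows(dr$class_names, "class")
    )
  }
  idx <- bind_rows(term_rows, drug_rows) |>
    filter(nzchar(.data$surface)) |>
    distinct(.data$surface, .data$kind, .data$id, .keep_all = TRUE) |>
    mutate(nchar = nchar(.data$surface)) |>
    group_by(.data$surface, .data$kind) |>
    mutate(ambiguous = dplyr::n_distinct(.data$id) > 1) |>
    ungroup() |>
    arrange(dplyr::desc(.data$nchar), .data$surface, .data$kind, .data$id)
  class(idx) <- c("term_index", class(idx))
  idx
}
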