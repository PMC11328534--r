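`%||%` <- function(x, y) if (is.null(x)) y else x

abort_schema <- function(msg) stop(msg, call. = FALSE)

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_schema(sprintf(
      "%s: missing required column(s): %s", what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' @keywords internal
#' @noRd
split_pipe <- function(x) {
  out <- stringr::str_split(dplyr::coalesce(x, ""), stringr::fixed("|"))
  purrr::map(out, function(v) {
    v <- stringr::str_trim(v)
    unique(v[nzchar(v)])
  })
}

# 0/1, true/false, or logical -> logical
parse_flag <- function(x) {
  if (is.logical(x)) return(dplyr::coalesce(x, FALSE))
  v <- stringr::str_to_lower(stringr::str_trim(as.character(x)))
  dplyr::case_when(
    v %in% c("1", "true", "t", "yes") ~ TRUE,
    .default = FALSE
  )
}

normalize_surface <- function(x) {
  stringr::str_squish(stringr::str_to_lower(enc2utf8(x)))
}

# regex for a whole-word occurrence of a literal surface
word_pattern <- function(surface) {
  paste0("(?<![\\p{L}\\p{N}])", str_escape(surface), "(?![\\p{L}\\p{N}])")
}

# character gap between the nearer edges of two 1-based inclusive spans;
# 0 when adjacent or overlapping
span_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - e1 - 1L, s1 - e2 - 1L))
}

locate_all_words <- function(texts, surface) {
  str_locate_all(texts, word_pattern(surface))
}
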