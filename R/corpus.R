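#' Read clinical notes
#'
#' Reads a notes table (CSV or JSON-lines) with one record per note:
#' `patient_id`, `note_id`, `form_name`, `category`, `author_role`,
#' `timestamp` (ISO-8601), `text`. Record order is preserved; notes with
#' empty text are kept and flagged so the pipeline can skip them with a
#' message rather than fail.
#'
#' @param path Path to the notes file.
#' @param format `"auto"` (by extension), `"csv"`, or `"jsonl"`.
#' @return A tibble of notes with parsed `timestamp` and a logical
#'   `skippable` column marking empty-text notes.
#' @export
read_notes <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  raw <- if (format == "jsonl") {
    as_tibble(jsonlite::stream_in(file(path), verbose = FALSE))
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  notes_table(raw)
}

#' Validate an in-memory notes table
#'
#' @param df Data frame with the notes schema (see [read_notes()]).
#' @return A validated notes tibble.
#' @export
notes_table <- function(df) {
  require_columns(df, c("patient_id", "note_id", "text"), "notes table")
  out <- as_tibble(df)
  for (col in c("form_name", "category", "author_role")) {
    if (!col %in% names(out)) out[[col]] <- NA_character_
  }
  if (!"timestamp" %in% names(out)) out$timestamp <- NA_character_
  if (inherits(out$timestamp, "POSIXct")) {
    ts <- out$timestamp
    bad <- integer(0)
  } else {
    ts <- readr::parse_datetime(as.character(out$timestamp))
    bad <- which(is.na(ts) & !is.na(out$timestamp) & nzchar(out$timestamp))
  }
  if (length(bad) > 0) {
    abort_schema(sprintf(
      "notes table: malformed timestamp for note_id %s",
      paste(out$note_id[bad], collapse = ", ")
    ))
  }
  dup <- out$note_id[duplicated(out$note_id)]
  if (length(dup) > 0) {
    abort_schema(sprintf("notes table: duplicate note_id: %s",
                         paste(unique(dup), collapse = ", ")))
  }
  out |>
    mutate(
      dplyr::across(dplyr::all_of(
        c("patient_id", "note_id", "form_name", "category", "author_role")
      ), as.character),
      timestamp = ts,
      text = dplyr::coalesce(as.character(.data$text), ""),
      skippable = !nzchar(.data$text)
    ) |>
    select(dplyr::all_of(c("patient_id", "note_id", "form_name", "category",
                           "author_role", "timestamp", "text", "skippable")))
}

#' Write notes to CSV
#'
#' @param notes Notes tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_notes <- function(notes, path) {
  out <- notes
  out$skippable <- NULL
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Normalize text for matching, keeping offset provenance
#'
#' Lowercases the text and removes punctuation (Unicode `P*` classes plus
#' the section marks `©` and `•`); a punctuation run whose removal
#' would glue two words together is replaced by a single space. Digits and
#' diacritics are preserved. The returned offset map sends every normalized
#' character position (1-based) back to a raw-text position, so any matched
#' span can be located in the original note.
#'
#' @param raw A single string.
#' @return A list with `text` (normalized string) and `map` (integer vector;
#'   `map[i]` is the raw position of normalized character `i`).
#' @export
normalize_text <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1)
  if (is.na(raw) || !nzchar(raw)) {
    return(list(text = "", map = integer(0)))
  }
  chars <- strsplit(enc2utf8(raw), "")[[1]]
  is_punct <- grepl("^[\\p{P}©•]$", chars, perl = TRUE)
  if (!any(is_punct)) {
    return(list(text = stringr::str_to_lower(raw), map = seq_along(chars)))
  }
  is_space <- grepl("^\\s$", chars)
  runs <- rle(is_punct)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  pieces <- character(0)
  maps <- list()
  for (k in seq_along(runs$lengths)) {
    s <- run_start[k]; e <- run_end[k]
    if (!runs$values[k]) {
      pieces <- c(pieces, paste(chars[s:e], collapse = ""))
      maps[[length(maps) + 1L]] <- s:e
    } else if (s > 1 && e < length(chars) &&
               !is_space[s - 1] && !is_space[e + 1] &&
               !is_punct[e + 1]) {
      # removal would merge two words: keep a single space
      pieces <- c(pieces, " ")
      maps[[length(maps) + 1L]] <- s
    }
  }
  list(
    text = stringr::str_to_lower(paste(pieces, collapse = "")),
    map = as.integer(unlist(maps))
  )
}

#' Recover the raw-text span of a normalized span
#'
#' @param map Offset map from [normalize_text()].
#' @param start,end 1-based inclusive span in the normalized text.
#' @return Integer vector `c(start, end)` in raw-text coordinates.
#' @export
raw_span <- function(map, start, end) {
  c(map[start], map[end])
}

# per-note block boundaries: split before header lines (ending in ":") and
# after blank-line runs; blocks partition [1, nchar(text)]
note_line_blocks <- function(text) {
  n <- nchar(text)
  nl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  nl <- nl[nl > 0]
  starts <- c(1L, nl + 1L)
  starts <- starts[starts <= n]
  ends <- c(starts[-1] - 1L, n)
  line_str <- substring(text, starts, ends)
  line_core <- sub("\n$", "", line_str)
  blank <- grepl("^\\s*$", line_core)
  header <- grepl(":\\s*$", line_core) & !blank
  m <- length(starts)
  new_block <- header |
    c(FALSE, blank[-m] & !blank[-1]) # first non-blank after a blank run
  new_block[1] <- TRUE
  grp <- cumsum(new_block)
  tibble(
    start = vapply(split(starts, grp), min, integer(1), USE.NAMES = FALSE),
    end = vapply(split(ends, grp), max, integer(1), USE.NAMES = FALSE)
  )
}

# split [start, end] spans of a raw string longer than max_chars at
# sentence-final periods; hard cut when no sentence boundary exists
split_long_span <- function(text, start, end, max_chars) {
  len <- end - start + 1L
  if (len <= max_chars) return(tibble(start = start, end = end))
  piece <- substr(text, start, end)
  cuts <- gregexpr("\\.(?=\\s)", piece, perl = TRUE)[[1]]
  cuts <- cuts[cuts > 0]
  out_s <- integer(0); out_e <- integer(0)
  cs <- start
  while (end - cs + 1L > max_chars) {
    window_hi <- cs + max_chars - 1L
    cand <- cuts + start - 1L
    cand <- cand[cand > cs & cand <= window_hi]
    cut_at <- if (length(cand) > 0) max(cand) else window_hi
    out_s <- c(out_s, cs); out_e <- c(out_e, cut_at)
    cs <- cut_at + 1L
  }
  tibble(start = c(out_s, cs), end = c(out_e, end))
}

#' Segment notes into candidate text blocks
#'
#' Splits each note on blank lines and header lines (a line ending in
#' `":"` starts a new block); blocks longer than `max_block_chars` are
#' further split at sentence-final periods. The blocks of a note never
#' overlap and jointly cover its raw text. Each block carries the
#' normalized text and offset map used by all downstream matching.
#'
#' @param notes Notes tibble (see [read_notes()]).
#' @param max_block_chars Maximum block length in characters (default 2000).
#' @return A tibble of blocks: note metadata, `block_id`, raw `start`/`end`
#'   offsets (1-based inclusive), raw `text`, `norm_text`, and `norm_map`
#'   (list-column of offset maps).
#' @export
segment_blocks <- function(notes, max_block_chars = 2000L) {
  stopifnot(max_block_chars > 0)
  usable <- filter(notes, !.data$skippable)
  if (nrow(usable) < nrow(notes)) {
    message(sprintf("segment_blocks: skipping %d empty note(s)",
                    nrow(notes) - nrow(usable)))
  }
  if (nrow(usable) == 0) {
    return(tibble(
      patient_id = character(), note_id = character(),
      form_name = character(), category = character(),
      author_role = character(),
      timestamp = as.POSIXct(character()),
      block_id = character(), start = integer(), end = integer(),
      text = character(), norm_text = character(), norm_map = list()
    ))
  }
  blocks <- usable |>
    mutate(spans = purrr::map(.data$text, function(tx) {
      sp <- note_line_blocks(tx)
      purrr::pmap_dfr(sp, function(start, end) {
        split_long_span(tx, start, end, as.integer(max_block_chars))
      })
    })) |>
    tidyr::unnest("spans") |>
    group_by(.data$note_id) |>
    mutate(block_id = paste0(.data$note_id, "#", row_number())) |>
    ungroup() |>
    mutate(text = substr(.data$text, .data$start, .data$end))
  norm <- purrr::map(blocks$text, normalize_text)
  blocks |>
    mutate(
      norm_text = purrr::map_chr(norm, "text"),
      norm_map = purrr::map(norm, "map")
    ) |>
    select(dplyr::all_of(c(
      "patient_id", "note_id", "form_name", "category", "author_role",
      "timestamp", "block_id", "start", "end", "text", "norm_text",
      "norm_map"
    )))
}
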