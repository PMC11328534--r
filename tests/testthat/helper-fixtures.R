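# in-code fixtures and independent oracles shared across test files

mini_adr_table <- function() {
  tibble::tibble(
    llt_code = c("L1", "L2", "L3", "L4"),
    llt_name = c("rash", "rash maculopapular", "pain", "bloeddruk verhoogd"),
    pt_code = c("P1", "P2", "P3", "P4"),
    pt_name = c("rash", "rash maculopapular", "pain", "bloeddruk verhoogd"),
    soc_name = c("Skin and subcutaneous tissue disorders",
                 "Skin and subcutaneous tissue disorders",
                 "General disorders and administration site conditions",
                 "Investigations"),
    synonyms = c("uitslag", "", "pijn", ""),
    is_ime = c(0, 1, 0, 0)
  )
}

mini_drug_table <- function() {
  tibble::tibble(
    drug_id = c("D1", "D2", "D3", "D4", "D5"),
    generic_name = c("trimetoprim", "amoxicilline", "acetylsalicylzuur",
                     "carbasalaatcalcium", "metoprolol"),
    brand_names = c("monotrim", "clamoxyl", "aspirine", "", ""),
    abbreviations = c("", "", "asa", "asa", ""),
    class_names = c("antibiotica", "antibiotica", "", "", "betablokker")
  )
}

mini_trigger_table <- function() {
  tibble::tibble(
    surface = c("allergie", "wegens", "door medicatie", "voorgeschiedenis"),
    polarity = c("positive", "positive", "positive", "negative"),
    strategy_tag = c("keyword", "preposition", "phrase", "keyword")
  )
}

mini_bundle <- function(...) {
  lexicon_bundle(
    adr_terms = adr_terms(mini_adr_table()),
    drugs = drug_lexicon(mini_drug_table()),
    triggers = trigger_lexicon(mini_trigger_table()),
    ...
  )
}

# one-note corpus -> blocks tibble
make_blocks <- function(text, note_id = "n1", patient_id = "p1",
                        category = "consult",
                        timestamp = "2018-01-01T08:00:00Z") {
  notes <- notes_table(tibble::tibble(
    patient_id = patient_id, note_id = note_id, form_name = "Consult 2.0",
    category = category, author_role = "arts", timestamp = timestamp,
    text = text
  ))
  segment_blocks(notes)
}

# hand-built mention rows for pairing tests; spans are 1-based inclusive
mk_mention <- function(kind, id, start, end, block_id = "b1",
                       surface = "x", via_variant = FALSE) {
  tibble::tibble(
    block_id = block_id, note_id = "n1", kind = kind, id = id,
    surface = surface, matched_surface = surface, surface_kind = "generic",
    pt_code = if (kind == "term") paste0("P", id) else NA_character_,
    llt_name = if (kind == "term") surface else NA_character_,
    start = as.integer(start), end = as.integer(end),
    via_variant = via_variant, ambiguous = FALSE
  )
}

mk_block_meta <- function(block_id = "b1", norm_text = strrep("x", 200)) {
  tibble::tibble(
    block_id = block_id, patient_id = "p1", note_id = "n1",
    form_name = "Consult 2.0", category = "consult", author_role = "arts",
    timestamp = as.POSIXct("2018-01-01 08:00:00", tz = "UTC"),
    start = 1L, end = nchar(norm_text), text = norm_text,
    norm_text = norm_text, norm_map = list(seq_len(nchar(norm_text)))
  )
}

# independent brute-force one-edit enumerator (character-vector splicing,
# a different construction from the implementation under test)
bf_one_edit <- function(surface, alphabet, with_deletion = FALSE) {
  ch <- strsplit(surface, "")[[1]]
  out <- character(0)
  for (i in seq_along(ch)) {
    for (a in alphabet) {
      v <- ch; v[i] <- a
      out <- c(out, paste(v, collapse = ""))
    }
  }
  for (i in 0:length(ch)) {
    for (a in alphabet) {
      v <- append(ch, a, after = i)
      out <- c(out, paste(v, collapse = ""))
    }
  }
  if (with_deletion) {
    for (i in seq_along(ch)) {
      out <- c(out, paste(ch[-i], collapse = ""))
    }
  }
  setdiff(unique(out), surface)
}

# brute-force all-pairs proximity pairing oracle (nearest mode)
bf_pair_nearest <- function(terms, drugs, max_distance) {
  res <- list()
  for (i in seq_len(nrow(terms))) {
    best <- NULL
    for (j in seq_len(nrow(drugs))) {
      if (terms$block_id[i] != drugs$block_id[j]) next
      g <- if (drugs$start[j] > terms$end[i]) {
        drugs$start[j] - terms$end[i] - 1L
      } else if (terms$start[i] > drugs$end[j]) {
        terms$start[i] - drugs$end[j] - 1L
      } else {
        0L
      }
      if (g > max_distance) next
      if (is.null(best) || g < best$g ||
          (g == best$g && drugs$start[j] < best$start)) {
        best <- list(g = g, start = drugs$start[j], j = j)
      }
    }
    if (!is.null(best)) {
      res[[length(res) + 1L]] <- data.frame(
        term = i, drug = best$j, gap = best$g
      )
    }
  }
  do.call(rbind, res)
}
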