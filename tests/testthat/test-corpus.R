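test_that("notes round-trip through CSV and preserve order", {
  notes <- notes_table(tibble::tibble(
    patient_id = c("p1", "p1", "p2"),
    note_id = c("n1", "n2", "n3"),
    form_name = "Consult 2.0", category = "consult", author_role = "arts",
    timestamp = c("2018-01-01T08:00:00Z", "2018-01-02T08:00:00Z",
                  "2018-01-03T08:00:00Z"),
    text = c("eerste notitie", "", "derde notitie")
  ))
  expect_equal(notes$note_id, c("n1", "n2", "n3"))
  expect_equal(notes$skippable, c(FALSE, TRUE, FALSE))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_notes(notes, tf)
  back <- read_notes(tf)
  expect_equal(back, notes)
})

test_that("notes validation reports malformed timestamps by note id", {
  df <- tibble::tibble(patient_id = "p1", note_id = "nBAD",
                       form_name = NA, category = NA, author_role = NA,
                       timestamp = "not-a-time", text = "x")
  expect_error(notes_table(df), "nBAD")
  expect_error(notes_table(df[, c("patient_id", "note_id")]), "text")
})

test_that("normalization strips punctuation with a faithful offset map", {
  r <- normalize_text("Stop! Metoprolol.")
  expect_equal(r$text, "stop metoprolol")
  # normalized span of "metoprolol" maps back to the raw characters 7..16
  loc <- stringr::str_locate(r$text, "metoprolol")
  expect_equal(raw_span(r$map, loc[1], loc[2]), c(7L, 16L))
  expect_equal(substr("Stop! Metoprolol.", 7, 16), "Metoprolol")

  expect_equal(normalize_text(""), list(text = "", map = integer(0)))
  plain <- normalize_text("Geen Klachten")
  expect_equal(plain$text, "geen klachten")
  expect_equal(plain$map, 1:13)
})

test_that("punctuation that merges words is replaced by one space", {
  r <- normalize_text("koorts,braken")
  expect_equal(r$text, "koorts braken")
  r2 <- normalize_text("drug-induced")
  expect_equal(r2$text, "drug induced")
  # offset map is monotone non-decreasing
  expect_true(all(diff(r2$map) >= 0))
})

test_that("offset fidelity holds for random punctuated text", {
  withr::with_seed(13, {
    pieces <- c("Koorts", "na", "start!", "(amoxicilline)", "zie; brief.",
                "2dd", "stop,", "controle")
    for (rep in 1:20) {
      raw <- paste(sample(pieces, 6, replace = TRUE), collapse = " ")
      r <- normalize_text(raw)
      toks <- stringr::str_locate_all(r$text, "[a-z0-9]+")[[1]]
      for (i in seq_len(nrow(toks))) {
        rs <- raw_span(r$map, toks[i, 1], toks[i, 2])
        expect_equal(stringr::str_to_lower(substr(raw, rs[1], rs[2])),
                     substr(r$text, toks[i, 1], toks[i, 2]))
      }
    }
  })
})

test_that("segmentation partitions the note", {
  text <- paste0("anamnese:\nkoorts sinds gisteren\n\n",
                 "beleid:\nparacetamol gestart\n\nverder geen klachten")
  blocks <- make_blocks(text)
  expect_gt(nrow(blocks), 1)
  # jointly cover, never overlap
  expect_equal(blocks$start[1], 1L)
  expect_equal(blocks$end[nrow(blocks)], nchar(text))
  expect_true(all(blocks$start[-1] == blocks$end[-nrow(blocks)] + 1L))
  reassembled <- paste(substring(text, blocks$start, blocks$end),
                       collapse = "")
  expect_identical(reassembled, text)
})

test_that("short notes stay single blocks; long blocks split at sentences", {
  one <- make_blocks(strrep("a", 50))
  expect_equal(nrow(one), 1)
  expect_equal(one$text, strrep("a", 50))

  long_text <- paste(rep("dit is een zin met een afsluitend punt.", 10),
                     collapse = " ")
  notes <- notes_table(tibble::tibble(
    patient_id = "p1", note_id = "n1", form_name = NA, category = NA,
    author_role = NA, timestamp = "2018-01-01T00:00:00Z", text = long_text
  ))
  blocks <- segment_blocks(notes, max_block_chars = 100L)
  expect_true(all(nchar(blocks$text) <= 100))
  expect_identical(paste(blocks$text, collapse = ""), long_text)
})

test_that("empty notes are skipped with a message", {
  notes <- notes_table(tibble::tibble(
    patient_id = "p1", note_id = c("n1", "n2"), form_name = NA,
    category = NA, author_role = NA, timestamp = NA, text = c("iets", "")
  ))
  expect_message(blocks <- segment_blocks(notes), "skipping 1")
  expect_equal(unique(blocks$note_id), "n1")
})
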