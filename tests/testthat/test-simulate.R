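test_that("configuration validates probabilities and gap support", {
  expect_error(sim_config(adr_rate = 1.2), "adr_rate")
  expect_error(sim_config(gap_range = c(0, 43)))
  expect_error(sim_config(gap_range = c(1, 99)))
  expect_error(sim_config(n_patients = 0))
})

test_that("generation is deterministic in the seed", {
  cfg <- sim_config(n_patients = 4, notes_per_patient = 5, adr_rate = 0.4,
                    negation_rate = 0.2, typo_rate = 0.2, seed = 7)
  s1 <- generate_corpus(cfg)
  s2 <- generate_corpus(cfg)
  expect_identical(s1$notes, s2$notes)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$gold, s2$gold)
  s3 <- generate_corpus(sim_config(n_patients = 4, notes_per_patient = 5,
                                   adr_rate = 0.4, seed = 8))
  expect_false(identical(s1$notes$text, s3$notes$text))
})

test_that("lexicons are schema-valid with the required coverage", {
  bundle <- generate_lexicons()
  raw_terms <- adrminer:::sim_adr_term_table()
  expect_gte(nrow(raw_terms), 30)
  expect_gte(length(unique(raw_terms$soc_name)), 6)
  expect_true(all(default_excluded_socs() %in% raw_terms$soc_name))
  # exclusion applied inside the bundle
  expect_false(any(bundle$adr_terms$soc_name %in% default_excluded_socs()))
  expect_gte(nrow(bundle$drugs), 20)
  expect_gte(sum(bundle$adr_terms$is_ime), 5)
  expect_true(all(lengths(bundle$drugs$class_names) > 0))
})

test_that("gold and manifest stay mutually consistent", {
  sim <- generate_corpus(sim_config(n_patients = 8, notes_per_patient = 6,
                                    adr_rate = 0.5, negation_rate = 0.25,
                                    duplicate_rate = 0.3, seed = 19))
  expect_equal(nrow(sim$gold), sum(!sim$manifest$negated))
  # every gold row references a real note, term, and drug
  expect_true(all(sim$gold$note_id %in% sim$notes$note_id))
  expect_true(all(sim$gold$llt_code %in% sim$bundle$adr_terms$llt_code))
  expect_true(all(sim$gold$drug_id %in% sim$bundle$drugs$drug_id))
  # duplicates land in a later note of the same patient
  dups <- sim$manifest[!is.na(sim$manifest$duplicate_note_id), ]
  expect_gt(nrow(dups), 0)
  for (i in seq_len(nrow(dups))) {
    orig <- sim$notes[sim$notes$note_id == dups$note_id[i], ]
    copy <- sim$notes[sim$notes$note_id == dups$duplicate_note_id[i], ]
    expect_equal(orig$patient_id, copy$patient_id)
    expect_gt(copy$timestamp, orig$timestamp)
  }
  # planted (patient, term, drug) combinations are unique
  key <- paste(sim$manifest$patient_id, sim$manifest$llt_code,
               sim$manifest$drug_id)
  expect_false(any(duplicated(key)))
})

test_that("a zero ADR rate yields an empty gold standard", {
  sim <- generate_corpus(sim_config(n_patients = 3, notes_per_patient = 4,
                                    adr_rate = 0, seed = 2))
  expect_equal(nrow(sim$gold), 0)
  expect_equal(nrow(sim$manifest), 0)
  alerts <- run_pipeline(sim$notes, sim$bundle)
  expect_equal(nrow(alerts), 0)
})

test_that("written corpora are immediately consumable from disk", {
  sim <- generate_corpus(sim_config(n_patients = 4, notes_per_patient = 4,
                                    adr_rate = 0.5, seed = 23))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  notes <- read_notes(file.path(dir, "notes.csv"))
  bundle <- load_lexicon_dir(file.path(dir, "lexicons"))
  gold <- read_gold(file.path(dir, "gold.csv"))
  alerts <- run_pipeline(notes, bundle)
  ev <- evaluate_alerts(alerts, gold, "mention")
  expect_equal(glance(ev)$sensitivity, 1)
  # same-seed regeneration writes byte-identical files
  dir2 <- withr::local_tempdir()
  write_sim(generate_corpus(sim_config(n_patients = 4, notes_per_patient = 4,
                                       adr_rate = 0.5, seed = 23)), dir2)
  for (f in c("notes.csv", "gold.csv", "manifest.json")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("planted gaps drive retention as the threshold sweeps", {
  sim <- generate_corpus(sim_config(n_patients = 10, notes_per_patient = 8,
                                    adr_rate = 0.5, duplicate_rate = 0,
                                    gap_range = c(1L, 80L), seed = 29))
  gold <- gold_table(sim$gold)
  for (md in c(10L, 43L, 80L)) {
    alerts <- run_pipeline(sim$notes, sim$bundle,
                           adr_config(max_distance = md))
    sens <- glance(evaluate_alerts(alerts, gold, "mention"))$sensitivity
    expected <- mean(sim$manifest$gap <= md)
    expect_equal(sens, expected, tolerance = 0.02)
  }
})
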