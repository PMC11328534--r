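bundle <- mini_bundle()
idx <- build_term_index(bundle)

# candidates from a tiny two-patient corpus with a copy-paste duplicate
make_cands <- function() {
  notes <- notes_table(tibble::tibble(
    patient_id = c("p1", "p1", "p2"),
    note_id = c("n1", "n2", "n3"),
    form_name = "Consult 2.0", category = "consult", author_role = "arts",
    timestamp = c("2018-01-01T08:00:00Z", "2018-02-01T08:00:00Z",
                  "2018-03-01T08:00:00Z"),
    text = c("allergie rash na amoxicilline",
             "allergie rash na amoxicilline",   # duplicate in later note
             "allergie rash na amoxicilline")   # other patient
  ))
  blocks <- segment_blocks(notes)
  pair_candidates(find_mentions(blocks, idx), blocks)
}

test_that("drug list filters drop negative surfaces and keep positives", {
  cands <- make_cands()
  expect_equal(nrow(filter_by_drug_lists(cands)), nrow(cands)) # identity
  dropped <- filter_by_drug_lists(cands,
                                  negative_drug_list = "amoxicilline")
  expect_equal(nrow(dropped), 0)
  kept <- filter_by_drug_lists(cands,
                               positive_drug_list = "amoxicilline")
  expect_equal(nrow(kept), nrow(cands))
  expect_error(filter_by_drug_lists(cands, "amoxicilline", "amoxicilline"),
               "overlap")
})

test_that("term list filters are symmetric and stage-independent", {
  cands <- make_cands()
  expect_equal(nrow(filter_by_term_lists(cands,
                                         negative_term_list = "rash")), 0)
  # a negated term is still retained here: negation is its own stage
  neg_blocks <- make_blocks("allergie geen rash na amoxicilline")
  neg_cands <- pair_candidates(find_mentions(neg_blocks, idx), neg_blocks)
  expect_equal(nrow(filter_by_term_lists(neg_cands,
                                         positive_term_list = "rash")), 1)
  expect_equal(nrow(filter_by_term_lists(neg_cands[0, ])), 0)
})

test_that("deduplication keeps one earliest alert per patient-drug-LLT", {
  cands <- make_cands()
  expect_equal(nrow(cands), 3)
  dd <- deduplicate(cands)
  expect_equal(nrow(dd), 2) # p1 collapses, p2 survives
  expect_setequal(dd$patient_id, c("p1", "p2"))
  expect_equal(dd$note_id[dd$patient_id == "p1"], "n1") # earliest kept
  expect_identical(deduplicate(dd), dd) # idempotent
})

test_that("negation drops candidates only within the 10-character window", {
  gap_case <- function(filler) {
    blocks <- make_blocks(paste0("allergie geen", filler,
                                 "rash na amoxicilline"))
    pair_candidates(find_mentions(blocks, idx), blocks)
  }
  near <- gap_case(" ") # 1 char between "geen" and "rash"
  expect_equal(nrow(filter_negated(near)), 0)
  far <- gap_case(paste0(" ", strrep("x", 9), " ")) # 11 chars between
  expect_equal(nrow(filter_negated(far)), 1)
  at10 <- gap_case(paste0(" ", strrep("x", 8), " ")) # exactly 10
  expect_equal(nrow(filter_negated(at10)), 0)
  # window 0 drops only adjacent/overlapping negations
  expect_equal(nrow(filter_negated(near, window_chars = 0)), 1)
  clean <- make_blocks("allergie rash na amoxicilline")
  cc <- pair_candidates(find_mentions(clean, idx), clean)
  expect_equal(nrow(filter_negated(cc)), 1)
})

test_that("seriousness annotates from the IME list without dropping rows", {
  blocks <- make_blocks("allergie rash maculopapular na amoxicilline")
  cands <- pair_candidates(find_mentions(blocks, idx), blocks)
  out <- classify_seriousness(cands, bundle$adr_terms)
  expect_equal(nrow(out), nrow(cands))
  expect_true(out$serious[out$llt_code == "L2"]) # IME-listed
  plain <- classify_seriousness(make_cands(), bundle$adr_terms)
  expect_false(any(plain$serious)) # L1 not IME
  expect_equal(nrow(plain), 3)
})

test_that("the stage chain honours toggles, order, and subset semantics", {
  cands <- make_cands()
  off <- default_stages(drug_filter = FALSE, term_filter = FALSE,
                        dedup = FALSE, negation = FALSE, seriousness = FALSE)
  idchain <- run_stage_chain(cands, bundle, off)
  expect_equal(nrow(idchain), nrow(cands))
  expect_false(any(idchain$serious))

  default <- run_stage_chain(cands, bundle)
  expect_equal(nrow(default), 2)
  log <- attr(default, "stage_log")
  expect_true(all(log$n_out <= log$n_in))
  expect_equal(log$n_out[log$stage == "seriousness"],
               log$n_in[log$stage == "seriousness"])
  # only-dedup chain emits unique dedup keys
  dd_only <- run_stage_chain(cands, bundle, default_stages(
    drug_filter = FALSE, term_filter = FALSE, seriousness = FALSE
  ))
  key <- paste(dd_only$patient_id, dd_only$drug_id, dd_only$llt_code)
  expect_false(any(duplicated(key)))
  expect_error(default_stages(order = c("dedup", "bogus")), "unknown stage")
})

test_that("enabling negation removes exactly the negated planted alert", {
  sim <- generate_corpus(sim_config(n_patients = 8, notes_per_patient = 5,
                                    adr_rate = 0.4, negation_rate = 0.3,
                                    duplicate_rate = 0, seed = 17))
  n_negated <- sum(sim$manifest$negated)
  expect_gt(n_negated, 0)
  base_cfg <- adr_config()
  neg_cfg <- adr_config(stages = default_stages(negation = TRUE))
  a_base <- run_pipeline(sim$notes, sim$bundle, base_cfg)
  a_neg <- run_pipeline(sim$notes, sim$bundle, neg_cfg)
  expect_equal(nrow(a_base) - nrow(a_neg), n_negated)
  # with negation on, output matches gold exactly at mention level
  ev <- evaluate_alerts(a_neg, gold_table(sim$gold), "mention")
  expect_equal(glance(ev)$sensitivity, 1)
  expect_equal(glance(ev)$ppv, 1)
})
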