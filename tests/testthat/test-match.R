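bundle <- mini_bundle()
idx <- build_term_index(bundle)

test_that("mentions are found exactly and flagged by kind", {
  blocks <- make_blocks("rash na amoxicilline")
  m <- find_mentions(blocks, idx)
  expect_equal(sum(m$kind == "term"), 1)
  expect_equal(sum(m$kind == "drug"), 1)
  expect_equal(m$id[m$kind == "term"], "L1")
  expect_equal(m$id[m$kind == "drug"], "D2")
  expect_false(any(m$via_variant))
})

test_that("variant matching recovers one-letter typos when enabled", {
  blocks <- make_blocks("trimethoprim gestart wegens infectie")
  off <- find_mentions(blocks, idx, use_variants = FALSE)
  expect_equal(sum(off$kind == "drug"), 0)
  on <- find_mentions(blocks, idx, use_variants = TRUE)
  drug <- on[on$kind == "drug", ]
  expect_equal(drug$id, "D1")
  expect_equal(drug$surface, "trimetoprim")
  expect_equal(drug$matched_surface, "trimethoprim")
  expect_true(drug$via_variant)
})

test_that("exact matches beat variant matches at the same span", {
  blocks <- make_blocks("trimetoprim voor infectie")
  on <- find_mentions(blocks, idx, use_variants = TRUE)
  drug <- on[on$kind == "drug", ]
  expect_equal(nrow(drug), 1)
  expect_false(drug$via_variant)
})

test_that("pairing uses edge-to-edge gaps with an inclusive threshold", {
  # construct spans directly: term [11,14], drug [21,30] -> 6 chars between
  mentions <- rbind(mk_mention("term", "L1", 11, 14),
                    mk_mention("drug", "D1", 21, 30))
  cands <- pair_candidates(mentions, mk_block_meta(), max_distance = 43)
  expect_equal(cands$distance_chars, 6L)

  gap_case <- function(gap) {
    m <- rbind(mk_mention("term", "L1", 1, 4),
               mk_mention("drug", "D1", 5 + gap, 10 + gap))
    pair_candidates(m, mk_block_meta(), max_distance = 43)
  }
  expect_equal(nrow(gap_case(43)), 1) # at the threshold: paired
  expect_equal(gap_case(43)$distance_chars, 43L)
  expect_equal(nrow(gap_case(44)), 0) # one past: rejected
})

test_that("each term pairs with its nearest drug, ties to the earlier one", {
  mentions <- rbind(mk_mention("term", "L1", 20, 23),
                    mk_mention("drug", "D1", 29, 33),  # gap 5
                    mk_mention("drug", "D2", 5, 10))   # gap 9
  cands <- pair_candidates(mentions, mk_block_meta())
  expect_equal(nrow(cands), 1)
  expect_equal(cands$drug_id, "D1")
  expect_equal(cands$distance_chars, 5L)

  tie <- rbind(mk_mention("term", "L1", 20, 23),
               mk_mention("drug", "D1", 28, 32),  # gap 4, later
               mk_mention("drug", "D2", 12, 15))  # gap 4, earlier
  t_res <- pair_candidates(tie, mk_block_meta())
  expect_equal(t_res$drug_id, "D2")

  all_res <- pair_candidates(mentions, mk_block_meta(), mode = "all")
  expect_equal(nrow(all_res), 2)
})

test_that("overlapping spans have distance zero and proximity score 100", {
  mentions <- rbind(mk_mention("term", "L1", 5, 12),
                    mk_mention("drug", "D1", 10, 18))
  cands <- pair_candidates(mentions, mk_block_meta())
  expect_equal(cands$distance_chars, 0L)
  expect_equal(cands$proximity_score, 100L)
  # score stays within 1..100 at the far edge
  far <- rbind(mk_mention("term", "L1", 1, 4),
               mk_mention("drug", "D1", 48, 55))
  expect_equal(pair_candidates(far, mk_block_meta())$proximity_score, 1L)
})

test_that("raising max_distance never removes candidates", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      n <- sample(4:10, 1)
      spans <- sort(sample(1:150, 2 * n))
      kinds <- sample(rep(c("term", "drug"), n))
      mentions <- purrr::map_dfr(seq_len(n * 2), function(i) {
        mk_mention(kinds[i], paste0("X", i), spans[2 * i - 1],
                   pmin(spans[2 * i - 1] + sample(2:6, 1), 160))
      })
      prev <- -1
      for (md in c(5, 15, 43, 80)) {
        got <- nrow(pair_candidates(mentions, mk_block_meta(
          norm_text = strrep("x", 200)
        ), max_distance = md))
        expect_gte(got, prev)
        prev <- got
      }
    }
  })
})

test_that("pairing agrees with the brute-force all-pairs oracle", {
  withr::with_seed(99, {
    for (rep in 1:40) {
      n_t <- sample(1:6, 1); n_d <- sample(1:6, 1)
      mk_rand <- function(kind, k) {
        starts <- sample(1:120, k) # unique starts keep tie-breaks testable
        purrr::map_dfr(seq_len(k), function(i) {
          mk_mention(kind, paste0(kind, i), starts[i],
                     starts[i] + sample(2:8, 1))
        })
      }
      terms <- mk_rand("term", n_t)
      drugs <- mk_rand("drug", n_d)
      md <- sample(c(0, 5, 20, 43), 1)
      got <- pair_candidates(rbind(terms, drugs),
                             mk_block_meta(norm_text = strrep("x", 150)),
                             max_distance = md)
      want <- bf_pair_nearest(terms, drugs, md)
      expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
      if (!is.null(want)) {
        got_sorted <- got[order(got$term_start), ]
        want_sorted <- want[order(terms$start[want$term]), ]
        expect_equal(got_sorted$distance_chars, as.integer(want_sorted$gap))
        expect_equal(got_sorted$drug_start,
                     as.integer(drugs$start[want_sorted$drug]))
      }
    }
  })
})

test_that("every emitted candidate respects the distance bound", {
  sim <- generate_corpus(sim_config(n_patients = 5, notes_per_patient = 6,
                                    adr_rate = 0.5, seed = 31))
  alerts <- run_pipeline(sim$notes, sim$bundle)
  expect_true(all(alerts$distance_chars <= 43))
})
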