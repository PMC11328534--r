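#' Configuration for the synthetic corpus generator
#'
#' Defines the study conditions the generator emulates: a multi-entry,
#' Dutch-flavoured note corpus in which a fraction of notes carries a
#' planted drug-reaction mention, optionally corrupted the way real notes
#' are (a negation in front of the reaction, a one-letter typo in the drug
#' name, a copy-pasted duplicate in a later note of the same patient).
#'
#' Defaults: 30 patients x 20 notes at `adr_rate` 0.15 give a desk-scale
#' corpus with ~90 planted events; `serious_fraction` 0.2 mirrors the
#' roughly one-in-five share of potentially serious ADRs in manually
#' reviewed note sets; `negation_rate` and `typo_rate` default to 0,
#' matching the corruption-free baseline, and planted term-drug gaps are
#' uniform on 1..43 characters so every clean plant is recoverable under
#' the default pairing threshold.
#'
#' @param n_patients Number of patients (>= 1).
#' @param notes_per_patient Notes per patient.
#' @param adr_rate Probability a note carries a planted ADR.
#' @param negation_rate,typo_rate,duplicate_rate Probabilities, applied per
#'   planted ADR, of negating the mention, misspelling the drug by one
#'   letter, and copy-pasting the sentence into a later note.
#' @param serious_fraction Probability a planted term is drawn from the
#'   Important-Medical-Event subset.
#' @param gap_range Integer range (within 1..80) from which the planted
#'   term-drug character gap is drawn uniformly; the minimum is 1 because
#'   whole-word matching needs a separator between two surfaces.
#' @param seed Integer seed; identical configurations generate identical
#'   corpora.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 30L, notes_per_patient = 20L,
                       adr_rate = 0.15, negation_rate = 0,
                       typo_rate = 0, duplicate_rate = 0.1,
                       serious_fraction = 0.2, gap_range = c(1L, 43L),
                       seed = 1L) {
  probs <- c(adr_rate = adr_rate, negation_rate = negation_rate,
             typo_rate = typo_rate, duplicate_rate = duplicate_rate,
             serious_fraction = serious_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must be in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  }
  stopifnot(n_patients >= 1, notes_per_patient >= 1,
            length(gap_range) == 2, gap_range[1] >= 1, gap_range[2] <= 80,
            gap_range[1] <= gap_range[2])
  structure(
    list(n_patients = as.integer(n_patients),
         notes_per_patient = as.integer(notes_per_patient),
         adr_rate = adr_rate, negation_rate = negation_rate,
         typo_rate = typo_rate, duplicate_rate = duplicate_rate,
         serious_fraction = serious_fraction,
         gap_range = as.integer(gap_range), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# closed synthetic vocabulary; surfaces chosen pairwise >= 3 edits apart so
# one-edit typo variants never cross-match another lexicon entry
sim_adr_term_table <- function() {
  tribble_terms <- list(
    # llt_name, pt_name, soc, synonyms, ime
    list("huiduitslag", "huiduitslag", "Skin and subcutaneous tissue disorders", "exantheem", 0),
    list("jeuk", "jeuk", "Skin and subcutaneous tissue disorders", "pruritus", 0),
    list("urticaria", "urticaria", "Skin and subcutaneous tissue disorders", "", 0),
    list("erytheem", "erytheem", "Skin and subcutaneous tissue disorders", "", 0),
    list("misselijkheid", "misselijkheid", "Gastrointestinal disorders", "nausea", 0),
    list("braken", "braken", "Gastrointestinal disorders", "", 0),
    list("diarree", "diarree", "Gastrointestinal disorders", "", 0),
    list("obstipatie", "obstipatie", "Gastrointestinal disorders", "", 0),
    list("buikpijn", "buikpijn", "Gastrointestinal disorders", "", 0),
    list("duizeligheid", "duizeligheid", "Nervous system disorders", "vertigo", 0),
    list("hoofdpijn", "hoofdpijn", "Nervous system disorders", "cefalgie", 0),
    list("tremor", "tremor", "Nervous system disorders", "", 0),
    list("convulsie", "convulsie", "Nervous system disorders", "insult", 1),
    list("sufheid", "sufheid", "Nervous system disorders", "", 0),
    list("verwardheid", "verwardheid", "Psychiatric disorders", "delier", 0),
    list("slapeloosheid", "slapeloosheid", "Psychiatric disorders", "insomnia", 0),
    list("bradycardie", "bradycardie", "Cardiac disorders", "", 0),
    list("tachycardie", "tachycardie", "Cardiac disorders", "", 0),
    list("hypotensie", "hypotensie", "Vascular disorders", "", 0),
    list("hartfalen", "hartfalen", "Cardiac disorders", "decompensatio", 1),
    list("nierfalen", "nierfalen", "Renal and urinary disorders", "nierinsufficientie", 1),
    list("hematurie", "hematurie", "Renal and urinary disorders", "", 0),
    list("urineretentie", "urineretentie", "Renal and urinary disorders", "", 0),
    list("anemie", "anemie", "Blood and lymphatic system disorders", "bloedarmoede", 0),
    list("trombocytopenie", "trombocytopenie", "Blood and lymphatic system disorders", "", 1),
    list("neutropenie", "neutropenie", "Blood and lymphatic system disorders", "", 1),
    list("agranulocytose", "agranulocytose", "Blood and lymphatic system disorders", "", 1),
    list("anafylaxie", "anafylaxie", "Immune system disorders", "", 1),
    list("leverfalen", "leverfalen", "Hepatobiliary disorders", "", 1),
    list("icterus", "icterus", "Hepatobiliary disorders", "geelzucht", 0),
    list("dyspnoe", "dyspnoe", "Respiratory, thoracic and mediastinal disorders", "kortademigheid", 0),
    list("koorts", "koorts", "General disorders and administration site conditions", "pyrexie", 0),
    list("oedeem", "oedeem", "General disorders and administration site conditions", "vochtretentie", 0),
    # rows in the four excluded SOCs: loaded tables must drop these
    list("bloeddruk verhoogd", "bloeddruk verhoogd", "Investigations", "", 0),
    list("operatie uitgevoerd", "operatie uitgevoerd", "Surgical and medical procedures", "", 0),
    list("woonsituatie gewijzigd", "woonsituatie gewijzigd", "Social circumstances", "", 0),
    list("verpakkingsfout", "verpakkingsfout", "Product issues", "", 0)
  )
  tibble(
    llt_code = sprintf("L%03d", seq_along(tribble_terms)),
    llt_name = map_chr(tribble_terms, 1),
    pt_code = sprintf("P%03d", seq_along(tribble_terms)),
    pt_name = map_chr(tribble_terms, 2),
    soc_name = map_chr(tribble_terms, 3),
    synonyms = map_chr(tribble_terms, 4),
    is_ime = purrr::map_dbl(tribble_terms, 5)
  )
}

sim_drug_table <- function() {
  rows <- list(
    # generic, brands, abbreviations, classes
    list("amoxicilline", "clamoxyl", "amox", "antibiotica"),
    list("trimetoprim", "monotrim", "", "antibiotica"),
    list("ciprofloxacine", "ciproxin", "", "antibiotica"),
    list("metoprolol", "selokeen", "", "betablokker"),
    list("bisoprolol", "", "", "betablokker"),
    list("simvastatine", "zocor", "", "statine"),
    list("atorvastatine", "lipitor", "", "statine"),
    list("ibuprofen", "brufen", "", "nsaid"),
    list("naproxen", "aleve", "", "nsaid"),
    list("omeprazol", "losec", "", "protonpompremmer"),
    list("pantoprazol", "", "", "protonpompremmer"),
    list("metformine", "", "mtf", "antidiabeticum"),
    list("gliclazide", "", "", "antidiabeticum"),
    list("furosemide", "lasix", "", "diureticum"),
    list("bumetanide", "", "", "diureticum"),
    list("enalapril", "renitec", "", "aceremmer"),
    list("lisinopril", "", "", "aceremmer"),
    list("amlodipine", "norvasc", "", "calciumantagonist"),
    list("apixaban", "eliquis", "", "anticoagulans"),
    list("rivaroxaban", "xarelto", "", "anticoagulans"),
    list("prednison", "", "", "corticosteroid"),
    list("morfine", "", "", "opiaat"),
    list("oxycodon", "oxynorm", "", "opiaat"),
    list("paracetamol", "panadol", "pcm", "analgeticum"),
    list("citalopram", "cipramil", "", "ssri"),
    list("sertraline", "zoloft", "", "ssri"),
    list("haloperidol", "haldol", "", "antipsychoticum"),
    list("digoxine", "lanoxin", "", "cardiacum"),
    list("levothyroxine", "euthyrox", "ltx", "schildklierhormoon")
  )
  tibble(
    drug_id = sprintf("D%02d", seq_along(rows)),
    generic_name = map_chr(rows, 1),
    brand_names = map_chr(rows, 2),
    abbreviations = map_chr(rows, 3),
    class_names = map_chr(rows, 4)
  )
}

sim_trigger_table <- function() {
  tibble(
    surface = c("allergie", "bijwerking", "overgevoeligheid", "intolerantie",
                "gestaakt",
                "wegens", "door", "na",
                "medicatie gerelateerd",
                "voorgeschiedenis", "familieanamnese"),
    polarity = c(rep("positive", 9), "negative", "negative"),
    strategy_tag = c(rep("keyword", 5), rep("preposition", 3), "phrase",
                     "keyword", "keyword")
  )
}

#' Generate the synthetic lexicon bundle
#'
#' Builds a schema-valid toy dictionary set: 37 ADR terms across 13 system
#' organ classes (including the four excluded ones, which are dropped at
#' load), 29 drugs with brands, abbreviations, and class names, a trigger
#' lexicon covering all four strategies, the four-word Dutch negation
#' lexicon, and an IME flag on the serious terms. Fully deterministic.
#'
#' @param config A [sim_config()] (present for interface symmetry; the
#'   lexicons are fixed).
#' @return A [lexicon_bundle()].
#' @export
generate_lexicons <- function(config = sim_config()) {
  lexicon_bundle(
    adr_terms = adr_terms(sim_adr_term_table()),
    drugs = drug_lexicon(sim_drug_table()),
    triggers = trigger_lexicon(sim_trigger_table()),
    negations = default_negations()
  )
}

# filler prose: a closed vocabulary disjoint from (and >= 2 edits away
# from) every lexicon surface, so clean corpora contain no accidental hits
sim_filler_sentences <- function() {
  c("patient komt vandaag op controle",
    "gezien op de polikliniek",
    "beleid besproken met familie",
    "controle over twee weken afgesproken",
    "lichamelijk onderzoek zonder bijzonderheden",
    "bloeddruk en pols stabiel",
    "eet en drinkt voldoende",
    "mobiliseert rustig op de afdeling",
    "ontslag naar huis gepland",
    "verder geen nieuwe klachten vandaag",
    "laboratorium uitslagen worden vervolgd",
    "afspraak gemaakt voor telefonisch consult")
}

# exact-length connector between term and drug: g characters strictly
# between the two surfaces, starting and ending in a space for g >= 3
sim_connector <- function(g) {
  if (g == 1) return(" ")
  if (g == 2) return("  ")
  paste0(" ", sim_fill_words(g - 2L), " ")
}

sim_fill_words <- function(len) {
  w <- c("u", "nu", "dan", "toen", "thuis", "eerder", "onlangs", "gisteren")
  if (len <= 8L) return(w[len])
  if (len == 9L) return(paste(w[4], w[4]))
  paste(w[8], sim_fill_words(len - 9L))
}

#' Generate a seeded synthetic note corpus with gold annotations
#'
#' Builds the note corpus described by `config`: template-built
#' Dutch-flavoured clinical notes in which each planted ADR places a
#' positive trigger word, an ADR term surface, and a drug surface separated
#' by an exact character gap drawn from `gap_range`. Corruptions follow the
#' configured rates: negated plants get a negation word directly before the
#' term, typo plants misspell the drug by one substitution or insertion,
#' duplicate plants copy the sentence into a later note of the same
#' patient. The gold standard lists what a perfect extractor running the
#' final pipeline configuration should emit: negated plants are excluded
#' and duplicates collapse onto the original note. Planted
#' (patient, term, drug) combinations are unique per patient so that
#' deduplication never merges two distinct gold events.
#'
#' @param config A [sim_config()].
#' @param bundle Lexicons from [generate_lexicons()].
#' @return An `adr_sim` list: `notes`, `gold`, `manifest` tibbles, plus the
#'   `bundle` and `config` used.
#' @export
generate_corpus <- function(config = sim_config(),
                            bundle = generate_lexicons(config)) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config, bundle))
}

generate_corpus_impl <- function(config, bundle) {
  at <- bundle$adr_terms
  dr <- bundle$drugs
  kw <- bundle$triggers |>
    filter(.data$polarity == "positive", .data$strategy_tag == "keyword")
  neg_words <- bundle$negations$word
  fillers <- sim_filler_sentences()
  categories <- c("consult", "anamnese", "beleid", "labuitslag")
  forms <- c("Consult 2.0", "Opname", "Ontslagbrief", "Dagstatus")
  roles <- c("arts", "verpleegkundige", "apotheker", "aios")
  base_time <- as.POSIXct("2018-01-01 08:00:00", tz = "UTC")

  ime_idx <- which(at$is_ime)
  plain_idx <- which(!at$is_ime)
  notes <- list()
  manifest <- list()
  note_counter <- 0L

  for (p in seq_len(config$n_patients)) {
    patient_id <- sprintf("p%03d", p)
    used_combos <- character(0)
    patient_note_ids <- character(config$notes_per_patient)
    patient_texts <- vector("list", config$notes_per_patient)
    patient_rows <- vector("list", config$notes_per_patient)

    for (k in seq_len(config$notes_per_patient)) {
      note_counter <- note_counter + 1L
      note_id <- sprintf("n%05d", note_counter)
      patient_note_ids[k] <- note_id
      n_par <- sample(2:4, 1)
      paragraphs <- vapply(seq_len(n_par), function(i) {
        paste(sample(fillers, sample(1:2, 1)), collapse = ". ")
      }, character(1))

      if (stats::runif(1) < config$adr_rate) {
        # draw a (term, drug) combination unused for this patient
        repeat {
          serious <- stats::runif(1) < config$serious_fraction
          ti <- if (serious && length(ime_idx) > 0) {
            sample(ime_idx, 1)
          } else {
            sample(plain_idx, 1)
          }
          di <- sample(nrow(dr), 1)
          combo <- paste(at$llt_code[ti], dr$drug_id[di])
          if (!combo %in% used_combos) break
        }
        used_combos <- c(used_combos, combo)
        syns <- at$synonyms[[ti]]
        term_surface <- if (length(syns) > 0 && stats::runif(1) < 0.3) {
          sample(syns, 1)
        } else {
          at$llt_name[ti]
        }
        brands <- dr$brand_names[[di]]
        drug_surface <- if (length(brands) > 0 && stats::runif(1) < 0.3) {
          sample(brands, 1)
        } else {
          dr$generic_name[di]
        }
        negated <- stats::runif(1) < config$negation_rate
        typo <- stats::runif(1) < config$typo_rate
        duplicated_flag <- stats::runif(1) < config$duplicate_rate
        gap <- sample(seq(config$gap_range[1], config$gap_range[2]), 1)
        drug_text <- if (typo) {
          sample(expand_one_edit_variants(drug_surface), 1)
        } else {
          drug_surface
        }
        trigger <- sample(kw$surface, 1)
        sentence <- paste0(
          trigger, " ",
          if (negated) paste0(sample(neg_words, 1), " ") else "",
          term_surface, sim_connector(gap), drug_text
        )
        pos <- sample(seq_len(n_par + 1L), 1)
        paragraphs <- append(paragraphs, sentence, after = pos - 1L)
        manifest[[length(manifest) + 1L]] <- tibble(
          patient_id = patient_id, note_id = note_id,
          llt_code = at$llt_code[ti], term_surface = term_surface,
          drug_id = dr$drug_id[di], drug_surface = drug_surface,
          drug_text = drug_text, trigger = trigger, gap = gap,
          negated = negated, typo = typo, duplicated = duplicated_flag,
          duplicate_note_id = NA_character_,
          serious = at$is_ime[ti]
        )
      }

      header <- if (stats::runif(1) < 0.3) {
        paste0(sample(c("anamnese", "beleid", "conclusie"), 1), ":\n")
      } else {
        ""
      }
      patient_texts[[k]] <- paste0(header,
                                   paste(paragraphs, collapse = "\n\n"))
      patient_rows[[k]] <- tibble(
        patient_id = patient_id, note_id = note_id,
        form_name = sample(forms, 1), category = sample(categories, 1),
        author_role = sample(roles, 1),
        timestamp = base_time + note_counter * 86400
      )
    }

    # copy-paste duplicates land in a strictly later note of the patient
    for (mi in seq_along(manifest)) {
      m <- manifest[[mi]]
      if (m$patient_id != patient_id || !m$duplicated ||
          !is.na(m$duplicate_note_id)) {
        next
      }
      k_orig <- match(m$note_id, patient_note_ids)
      if (is.na(k_orig) || k_orig >= config$notes_per_patient) next
      k_target <- if (k_orig + 1L == config$notes_per_patient) {
        config$notes_per_patient
      } else {
        sample(seq(k_orig + 1L, config$notes_per_patient), 1)
      }
      sentence <- paste0(
        m$trigger, " ",
        if (m$negated) paste0(sample(neg_words, 1), " ") else "",
        m$term_surface, sim_connector(m$gap), m$drug_text
      )
      patient_texts[[k_target]] <- paste0(patient_texts[[k_target]],
                                          "\n\n", sentence)
      manifest[[mi]]$duplicate_note_id <- patient_note_ids[k_target]
    }

    notes[[p]] <- bind_rows(patient_rows) |>
      mutate(text = unlist(patient_texts))
  }

  notes_tbl <- notes_table(bind_rows(notes))
  manifest_tbl <- if (length(manifest) > 0) {
    bind_rows(manifest)
  } else {
    tibble(
      patient_id = character(), note_id = character(), llt_code = character(),
      term_surface = character(), drug_id = character(),
      drug_surface = character(), drug_text = character(),
      trigger = character(), gap = integer(), negated = logical(),
      typo = logical(), duplicated = logical(),
      duplicate_note_id = character(), serious = logical()
    )
  }
  gold <- manifest_tbl |>
    filter(!.data$negated) |>
    select(dplyr::all_of(c("patient_id", "note_id", "llt_code", "drug_id",
                           "serious")))
  structure(
    list(notes = notes_tbl, gold = gold, manifest = manifest_tbl,
         bundle = bundle, config = config),
    class = "adr_sim"
  )
}

#' @export
print.adr_sim <- function(x, ...) {
  cat(sprintf(
    "<adr_sim> %d notes / %d patients, %d planted ADRs (%d negated, %d typo, %d duplicated), %d gold rows\n",
    nrow(x$notes), x$config$n_patients, nrow(x$manifest),
    sum(x$manifest$negated), sum(x$manifest$typo),
    sum(x$manifest$duplicated & !is.na(x$manifest$duplicate_note_id)),
    nrow(x$gold)
  ))
  invisible(x)
}

#' Write lexicon bundle TSV files
#'
#' Writes `adr_terms.tsv`, `drugs.tsv`, `triggers.tsv`, `negations.tsv`
#' (and the positive/negative list files when non-empty) in the schemas
#' read by [load_lexicon_dir()].
#'
#' @param bundle A [lexicon_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lexicons <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  join_pipe <- function(lst) map_chr(lst, paste, collapse = "|")
  at <- bundle$adr_terms |>
    mutate(synonyms = join_pipe(.data$synonyms),
           is_ime = as.integer(.data$is_ime))
  readr::write_tsv(at, file.path(dir, "adr_terms.tsv"), progress = FALSE)
  dr <- bundle$drugs |>
    mutate(brand_names = join_pipe(.data$brand_names),
           abbreviations = join_pipe(.data$abbreviations),
           class_names = join_pipe(.data$class_names))
  readr::write_tsv(dr, file.path(dir, "drugs.tsv"), progress = FALSE)
  readr::write_tsv(bundle$triggers, file.path(dir, "triggers.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$negations, file.path(dir, "negations.tsv"),
                   progress = FALSE)
  lists <- list(
    positive_terms = bundle$positive_term_list,
    negative_terms = bundle$negative_term_list,
    positive_drugs = bundle$positive_drug_list,
    negative_drugs = bundle$negative_drug_list
  )
  for (nm in names(lists)) {
    if (length(lists[[nm]]) > 0) {
      readr::write_tsv(tibble(surface = lists[[nm]]),
                       file.path(dir, paste0(nm, ".tsv")), progress = FALSE)
    }
  }
  invisible(dir)
}

#' Write a synthetic corpus to disk
#'
#' Writes `notes.csv`, `gold.csv`, `manifest.json`, and a `lexicons/`
#' directory of TSV files, immediately consumable by [run_pipeline()] /
#' [load_lexicon_dir()] / [read_gold()].
#'
#' @param sim An `adr_sim` from [generate_corpus()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "adr_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_notes(sim$notes, file.path(dir, "notes.csv"))
  gold_out <- sim$gold |> mutate(serious = as.integer(.data$serious))
  readr::write_csv(gold_out, file.path(dir, "gold.csv"), progress = FALSE)
  write_lexicons(sim$bundle, file.path(dir, "lexicons"))
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, na = "null", digits = NA)
  invisible(dir)
}
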