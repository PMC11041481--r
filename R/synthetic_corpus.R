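#' Configuration for the synthetic note generator
#'
#' The generator plants drug-reason relation structure into small synthetic
#' notes, one relation group per document, and records the ground truth in a
#' manifest. It emulates the structural features that matter downstream —
#' the five relation categories, duplicate answer mentions, controllable
#' drug-reason sentence distances, and the contextual trigger families — not
#' clinical realism.
#'
#' @param categories named integer vector of group counts for
#'   `one_drug_no_reason`, `one_to_one`, `one_to_n`, `n_to_one`, `m_to_n`
#'   (one document per group).
#' @param drug_lexicon,reason_lexicon disjoint term lists.
#' @param distance_probs named numeric vector: probability of each sentence
#'   gap for `one_to_one` groups (names are gaps `"0"`, `"1"`, ...); must sum
#'   to 1. Other categories are realized in a single sentence (gap 0).
#' @param duplicate_answer_rate probability that a `one_to_one` document
#'   restates (and re-annotates) its reason at a second offset.
#' @param pattern_mix named nonnegative weights over the
#'   [context_patterns()] families used to realize in-sentence relations.
#' @param distractor_rate probability of appending a neutral sentence naming
#'   an unrelated, unannotated drug (no reason triggers), to exercise
#'   false-positive behavior.
#' @param seed integer seed; the same seed yields a byte-identical corpus.
#' @return list of class `rx_generator_config`.
#' @export
generator_config <- function(
    categories = c(one_drug_no_reason = 10, one_to_one = 20, one_to_n = 5,
                   n_to_one = 3, m_to_n = 2),
    drug_lexicon = c("coumadin", "vancomycin", "lasix", "acetaminophen",
                     "senna", "oxycodone", "morphine", "amlodipine",
                     "metoprolol", "isosorbide", "albuterol", "aspirin",
                     "plavix", "pantoprazole", "mirtazapine", "docusate"),
    reason_lexicon = c("pain", "constipation", "fever", "afib", "sob",
                       "wheeze", "hypertension", "pneumonia", "stroke",
                       "edema", "nausea", "anxiety"),
    distance_probs = c("0" = 0.72, "1" = 0.18, "2" = 0.06, "3" = 0.03,
                       "4" = 0.01),
    duplicate_answer_rate = 0.15,
    pattern_mix = c(reason_started_on_drug = 25, drug_prn_reason = 18,
                    drug_given_for_reason = 14, reason_managed_with_drug = 13),
    distractor_rate = 0.25,
    seed = 42) {
  cfg <- structure(
    list(categories = categories, drug_lexicon = drug_lexicon,
         reason_lexicon = reason_lexicon, distance_probs = distance_probs,
         duplicate_answer_rate = duplicate_answer_rate,
         pattern_mix = pattern_mix, distractor_rate = distractor_rate,
         seed = seed),
    class = "rx_generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  needed <- c("one_drug_no_reason", "one_to_one", "one_to_n", "n_to_one",
              "m_to_n")
  if (!all(needed %in% names(cfg$categories))) {
    stop("categories must name all five relation categories")
  }
  if (any(cfg$categories < 0)) stop("category counts must be nonnegative")
  if (length(intersect(normalize_term(cfg$drug_lexicon),
                       normalize_term(cfg$reason_lexicon)))) {
    stop("drug and reason lexicons must be disjoint")
  }
  if (abs(sum(cfg$distance_probs) - 1) > 1e-8) {
    stop("distance_probs must sum to 1")
  }
  if (cfg$duplicate_answer_rate < 0 || cfg$duplicate_answer_rate > 1 ||
      cfg$distractor_rate < 0 || cfg$distractor_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (cfg$duplicate_answer_rate > 0 && cfg$categories[["one_to_one"]] == 0) {
    stop("duplicate_answer_rate > 0 requires one_to_one documents to host duplicates")
  }
  if (cfg$categories[["n_to_one"]] > 0 && length(cfg$drug_lexicon) < 3) {
    stop("n_to_one groups need at least 3 drugs in the lexicon")
  }
  if (sum(cfg$pattern_mix) <= 0) stop("pattern_mix must have positive mass")
  invisible(cfg)
}

#' Canonical pattern-exact generator configuration
#'
#' The regime in which the pattern-matching baseline is exact by
#' construction: every relation realized in a single sentence (gap 0) by one
#' trigger family, single-token reasons, one relation per document, no
#' duplicate restatements, no distractors, and lexicons chosen so that no
#' term is a substring of another. Includes a handful of drug-only documents
#' so abstention behavior is exercised too.
#'
#' @param n_answerable number of one-drug-one-reason documents.
#' @param n_unanswerable number of drug-only (no reason) documents.
#' @param seed integer seed.
#' @return an [generator_config()] object.
#' @export
pattern_pure_config <- function(n_answerable = 12, n_unanswerable = 4,
                                seed = 2718) {
  generator_config(
    categories = c(one_drug_no_reason = n_unanswerable,
                   one_to_one = n_answerable,
                   one_to_n = 0, n_to_one = 0, m_to_n = 0),
    drug_lexicon = c("coumadin", "vancomycin", "lasix", "acetaminophen",
                     "senna", "oxycodone", "morphine", "amlodipine"),
    reason_lexicon = c("pain", "constipation", "fever", "afib",
                       "hypertension", "pneumonia", "edema", "nausea"),
    distance_probs = c("0" = 1),
    duplicate_answer_rate = 0,
    distractor_rate = 0,
    seed = seed)
}

cap_first <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

filler_pool <- function() {
  c("Vitals stable overnight.",
    "Tolerating oral diet.",
    "Plan discussed with team.",
    "Labs unremarkable today.",
    "Ambulating without difficulty.")
}

# Neutral drug sentences: dose lines with no reason triggers.
neutral_drug_sentence <- function(drug) {
  sprintf("%s 25 mg PO QHS.", cap_first(drug))
}

# Locate a term in a sentence (case-insensitive, word-bounded); first match.
term_span <- function(sentence, term) {
  loc <- stringr::str_locate(
    sentence,
    stringr::regex(paste0("\\b", regex_escape(term), "\\b"),
                   ignore_case = TRUE))
  if (is.na(loc[1])) stop(sprintf("term '%s' not found in '%s'", term, sentence))
  c(start = loc[1] - 1L, end = loc[2])  # 0-based half-open
}

# Realize one drug-reason pair in a single sentence via a pattern family.
# Returns list(text, drug_span, reason_span) with sentence-relative offsets.
realize_pair_sentence <- function(family, drug, reason) {
  text <- switch(
    family,
    reason_started_on_drug = sprintf("%s required %s.", cap_first(reason), drug),
    drug_prn_reason = sprintf("%s 5 mg Q6H prn %s.", cap_first(drug), reason),
    drug_given_for_reason = sprintf("%s was given for %s.", cap_first(drug), reason),
    reason_managed_with_drug = sprintf("%s was managed with %s.",
                                       cap_first(reason), drug),
    stop("unknown pattern family: ", family))
  list(text = text, drug_span = term_span(text, drug),
       reason_span = term_span(text, reason))
}

# Drug-only sentence carrying an anaphoric reason slot, for gap > 0 layouts.
realize_anaphoric_drug_sentence <- function(family, drug) {
  switch(family,
         reason_started_on_drug = sprintf("This required %s.", drug),
         drug_prn_reason = sprintf("%s prn this.", cap_first(drug)),
         drug_given_for_reason = sprintf("%s was given for this.", cap_first(drug)),
         reason_managed_with_drug = sprintf("This was managed with %s.", drug))
}

#' Generate a synthetic corpus with planted relation structure
#'
#' One document per configured relation group. Answerable pairs are realized
#' by a sampled trigger family: gap 0 puts drug and reason in one sentence;
#' gap k puts the annotated reason k sentences before a drug sentence whose
#' reason slot holds an anaphor, separated by neutral filler sentences. All
#' randomness flows through the config seed, so equal seeds give
#' byte-identical corpora.
#'
#' @param config an [generator_config()] object.
#' @return list with `documents` (tibble `doc_id`, `text`), `annotations`
#'   (named list of [annotation_set()]), and `manifest` (list with per-group
#'   tibble `groups` and `totals`).
#' @export
generate_corpus <- function(config = generator_config()) {
  validate_generator_config(config)
  with_local_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  plan <- rep(names(config$categories), times = config$categories)
  fillers <- filler_pool()
  families <- names(config$pattern_mix)
  fam_prob <- config$pattern_mix / sum(config$pattern_mix)
  gaps <- as.integer(names(config$distance_probs))

  annotations <- list()
  manifest_rows <- list()

  for (d in seq_along(plan)) {
    doc_id <- sprintf("doc-%03d", d)
    category <- plan[d]
    sentences <- character()
    # per-sentence mention plans: list of (type, term, relative span)
    sent_mentions <- list()
    rel_pairs <- list()   # (drug mention index, reason mention index)
    mention_rows <- list()

    add_sentence <- function(text, mentions = list()) {
      sentences[[length(sentences) + 1L]] <<- text
      sent_mentions[[length(sentences)]] <<- mentions
    }

    draw_family <- function() {
      if (length(families) == 1) families else sample(families, 1, prob = fam_prob)
    }
    draw_gap <- function() {
      if (length(gaps) == 1) gaps else sample(gaps, 1, prob = config$distance_probs)
    }
    pattern_id <- NA_character_
    distance <- NA_integer_
    drug_terms <- character()
    reason_terms <- character()
    n_extra_spans <- 0L

    if (category == "one_drug_no_reason") {
      drug <- sample(config$drug_lexicon, 1)
      drug_terms <- drug
      add_sentence(neutral_drug_sentence(drug),
                   list(list(type = "DRUG", term = drug)))
    } else if (category == "one_to_one") {
      drug <- sample(config$drug_lexicon, 1)
      reason <- sample(config$reason_lexicon, 1)
      drug_terms <- drug; reason_terms <- reason
      fam <- draw_family()
      pattern_id <- fam
      gap <- draw_gap()
      distance <- gap
      if (gap == 0) {
        add_sentence(realize_pair_sentence(fam, drug, reason)$text,
                     list(list(type = "REASON", term = reason),
                          list(type = "DRUG", term = drug)))
      } else {
        add_sentence(sprintf("%s was noted.", cap_first(reason)),
                     list(list(type = "REASON", term = reason)))
        for (k in seq_len(gap - 1)) {
          add_sentence(sample(fillers, 1))
        }
        add_sentence(realize_anaphoric_drug_sentence(fam, drug),
                     list(list(type = "DRUG", term = drug)))
      }
      if (stats::runif(1) < config$duplicate_answer_rate) {
        fam2 <- draw_family()
        add_sentence(realize_pair_sentence(fam2, drug, reason)$text,
                     list(list(type = "REASON", term = reason),
                          list(type = "DRUG", term = drug)))
        n_extra_spans <- 1L
        # the restatement is a same-sentence pair, so the group's shortest
        # drug-reason distance collapses to 0
        distance <- 0L
      }
    } else if (category == "one_to_n") {
      drug <- sample(config$drug_lexicon, 1)
      reasons <- sample(config$reason_lexicon, 2)
      drug_terms <- drug; reason_terms <- reasons
      pattern_id <- "drug_given_for_reason"
      distance <- 0L
      add_sentence(sprintf("%s was given for %s and %s.", cap_first(drug),
                           reasons[1], reasons[2]),
                   list(list(type = "DRUG", term = drug),
                        list(type = "REASON", term = reasons[1]),
                        list(type = "REASON", term = reasons[2])))
    } else if (category == "n_to_one") {
      drugs <- sample(config$drug_lexicon, 3)
      reason <- sample(config$reason_lexicon, 1)
      drug_terms <- drugs; reason_terms <- reason
      pattern_id <- "reason_started_on_drug"
      distance <- 0L
      add_sentence(sprintf("%s: started %s, %s, and %s.", cap_first(reason),
                           drugs[1], drugs[2], drugs[3]),
                   c(list(list(type = "REASON", term = reason)),
                     lapply(drugs, function(dr) list(type = "DRUG", term = dr))))
    } else if (category == "m_to_n") {
      drugs <- sample(config$drug_lexicon, 2)
      reasons <- sample(config$reason_lexicon, 2)
      drug_terms <- drugs; reason_terms <- reasons
      pattern_id <- "reason_started_on_drug"
      distance <- 0L
      add_sentence(sprintf("%s and %s: maintained on %s and %s.",
                           cap_first(reasons[1]), reasons[2],
                           drugs[1], drugs[2]),
                   list(list(type = "REASON", term = reasons[1]),
                        list(type = "REASON", term = reasons[2]),
                        list(type = "DRUG", term = drugs[1]),
                        list(type = "DRUG", term = drugs[2])))
    }

    if (stats::runif(1) < config$distractor_rate) {
      spare <- setdiff(config$drug_lexicon, drug_terms)
      if (length(spare)) {
        add_sentence(neutral_drug_sentence(sample(spare, 1)))
      }
    }

    # Assemble text and absolute mention offsets
    text <- paste(unlist(sentences), collapse = " ")
    offsets <- cumsum(c(0L, nchar(unlist(sentences)) + 1L))
    mention_tbl <- list()
    for (s in seq_along(sentences)) {
      for (mn in sent_mentions[[s]] %||% list()) {
        span <- term_span(sentences[[s]], mn$term)
        mention_tbl[[length(mention_tbl) + 1L]] <- list(
          type = mn$type, term = mn$term,
          start = offsets[s] + span[["start"]],
          end = offsets[s] + span[["end"]])
      }
    }
    mentions <- tibble::tibble(
      mention_id = paste0("T", seq_along(mention_tbl)),
      concept_type = vapply(mention_tbl, function(m) m$type, character(1)),
      fragments = lapply(mention_tbl, function(m) {
        data.frame(start = as.integer(m$start), end = as.integer(m$end))
      }),
      surface_text = vapply(mention_tbl, function(m) {
        slice_text(text, m$start, m$end)
      }, character(1)))

    # relations: every annotated drug mention relates to every annotated
    # reason mention that shares its group (single group per document)
    drug_idx <- which(mentions$concept_type == "DRUG" &
                        normalize_term(mentions$surface_text) %in%
                        normalize_term(drug_terms))
    reason_idx <- which(mentions$concept_type == "REASON")
    rel <- list()
    if (category != "one_drug_no_reason") {
      for (di in drug_idx) {
        for (ri in reason_idx) {
          rel[[length(rel) + 1L]] <- tibble::tibble(
            relation_id = paste0("R", length(rel) + 1L),
            drug_id = mentions$mention_id[di],
            reason_id = mentions$mention_id[ri])
        }
      }
    }
    relations <- if (length(rel)) do.call(rbind, rel) else empty_relations()

    annotations[[doc_id]] <- annotation_set(doc_id, text, mentions, relations)
    manifest_rows[[length(manifest_rows) + 1L]] <- tibble::tibble(
      doc_id = doc_id, category = toupper(category),
      drug_terms = list(normalize_term(drug_terms)),
      reason_strings = list(sort(unique(normalize_term(reason_terms)))),
      n_relations = nrow(relations),
      n_answer_spans = length(reason_idx),
      unique_answers = length(unique(normalize_term(reason_terms))),
      distance = distance, pattern_id = pattern_id)
  }

  groups <- do.call(rbind, manifest_rows)
  answerable <- groups[groups$category != "ONE_DRUG_NO_REASON", , drop = FALSE]
  totals <- list(
    categories = config$categories,
    n_docs = nrow(groups),
    unique_answers = table(answerable$unique_answers),
    distances = table(answerable$distance)
  )
  list(documents = corpus_documents(annotations), annotations = annotations,
       manifest = list(groups = groups, totals = totals))
}

#' Write a generated corpus to disk
#'
#' Writes `<id>.txt`/`<id>.ann` pairs plus `manifest.json`.
#'
#' @param corpus result of [generate_corpus()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_synthetic_corpus <- function(corpus, dir) {
  write_corpus_dir(corpus$annotations, dir)
  groups <- corpus$manifest$groups
  jsonlite::write_json(
    list(groups = groups,
         categories = as.list(corpus$manifest$totals$categories)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
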