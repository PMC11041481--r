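#' Build configuration for QA entry generation
#'
#' @param multidrug_mode how drugs sharing an identical reason set are
#'   emitted: `"both"` (default; split per-drug entries *and* one combined
#'   multidrug entry), `"split_only"`, or `"combined_only"`.
#' @param templates question template table from
#'   [read_question_templates()]; the canonical templates are used when `NULL`.
#' @return list of class `rx_qa_config`.
#' @export
qa_config <- function(multidrug_mode = c("both", "split_only", "combined_only"),
                      templates = NULL) {
  multidrug_mode <- match.arg(multidrug_mode)
  structure(list(multidrug_mode = multidrug_mode,
                 templates = templates %||% default_templates()),
            class = "rx_qa_config")
}

#' Question templates
#'
#' Templates are pairs of question patterns with a `{drugs}` slot: a singular
#' form (one drug) and a plural form (two or more drugs, rendered as a
#' comma-separated list with a final ", and"). Paraphrase sets are read from a
#' two-column tab-separated file, one template per line, canonical first; the
#' default set holds only the two canonical forms.
#'
#' @param path tab-separated file with columns `singular<TAB>plural`.
#' @return tibble with columns `singular`, `plural`.
#' @export
read_question_templates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  if (any(!nzchar(parts[, 2]))) stop("template line without plural form")
  tibble::tibble(singular = parts[, 1], plural = parts[, 2])
}

default_templates <- function() {
  path <- system.file("extdata", "question_templates.tsv", package = "rxwhyqa")
  if (nzchar(path)) return(read_question_templates(path))
  tibble::tibble(
    singular = "Why was {drugs} prescribed to the patient?",
    plural = "Why were {drugs} prescribed to the patient?"
  )
}

#' Render why-questions for a set of drug terms
#'
#' @param drug_terms nonempty character vector of drug names, in question
#'   order.
#' @param templates template table (canonical template first).
#' @return character vector, one question per template.
#' @export
render_question <- function(drug_terms, templates = default_templates()) {
  if (length(drug_terms) == 0) stop("drug_terms must be nonempty")
  form <- if (length(drug_terms) == 1) templates$singular else templates$plural
  stringr::str_replace_all(form, stringr::fixed("{drugs}"),
                           collapse_term_list(drug_terms))
}

#' Group drug-reason relations within one document
#'
#' Every distinct lowercased drug surface string yields one single-drug group
#' collecting all reason mentions related to any mention of that drug; in
#' addition, each maximal set of two or more drug terms whose sets of distinct
#' normalized reason strings are identical and nonempty yields one multidrug
#' group. Categories follow the drug/reason cardinalities: `ONE_DRUG_NO_REASON`,
#' `ONE_TO_ONE`, `ONE_TO_N` for single-drug groups and `N_TO_ONE` (one shared
#' reason string) or `M_TO_N` for multidrug groups.
#'
#' @param ann an [annotation_set()] object.
#' @return tibble with columns `doc_id`, `drug_terms` (list), `drug_mention_ids`
#'   (list), `reason_mention_ids` (list), `reason_strings` (list of distinct
#'   normalized reason strings), `category`, `multidrug`.
#' @export
group_relations <- function(ann) {
  m <- ann$mentions
  empty <- tibble::tibble(doc_id = character(), drug_terms = list(),
                          drug_mention_ids = list(), reason_mention_ids = list(),
                          reason_strings = list(), category = character(),
                          multidrug = logical())
  drugs <- m[m$concept_type == "DRUG", , drop = FALSE]
  if (nrow(drugs) == 0) return(empty)

  first_start <- vapply(m$fragments, function(f) as.integer(f$start[1]),
                        integer(1))
  names(first_start) <- m$mention_id
  terms <- normalize_term(drugs$surface_text)

  rows <- list()
  for (term in unique(terms[order(first_start[drugs$mention_id])])) {
    dm_ids <- drugs$mention_id[terms == term]
    rel <- ann$relations[ann$relations$drug_id %in% dm_ids, , drop = FALSE]
    rm_ids <- unique(rel$reason_id)
    rm_ids <- rm_ids[order(first_start[rm_ids])]
    r_strings <- sort(unique(normalize_term(
      m$surface_text[match(rm_ids, m$mention_id)])))
    category <- if (length(rm_ids) == 0) "ONE_DRUG_NO_REASON"
      else if (length(r_strings) == 1) "ONE_TO_ONE" else "ONE_TO_N"
    rows[[length(rows) + 1L]] <- tibble::tibble(
      doc_id = ann$doc_id, drug_terms = list(term),
      drug_mention_ids = list(dm_ids), reason_mention_ids = list(rm_ids),
      reason_strings = list(r_strings), category = category, multidrug = FALSE)
  }
  singles <- do.call(rbind, rows)

  answerable <- singles[singles$category != "ONE_DRUG_NO_REASON", , drop = FALSE]
  multi <- list()
  if (nrow(answerable) > 1) {
    keys <- vapply(answerable$reason_strings, paste, character(1),
                   collapse = "\x1f")
    for (k in unique(keys)) {
      idx <- which(keys == k)
      if (length(idx) < 2) next
      dt <- unlist(answerable$drug_terms[idx])
      dm <- unique(unlist(answerable$drug_mention_ids[idx]))
      rm_ids <- unique(unlist(answerable$reason_mention_ids[idx]))
      rm_ids <- rm_ids[order(first_start[rm_ids])]
      r_strings <- answerable$reason_strings[[idx[1]]]
      multi[[length(multi) + 1L]] <- tibble::tibble(
        doc_id = ann$doc_id, drug_terms = list(dt),
        drug_mention_ids = list(dm), reason_mention_ids = list(rm_ids),
        reason_strings = list(r_strings),
        category = if (length(r_strings) == 1) "N_TO_ONE" else "M_TO_N",
        multidrug = TRUE)
    }
  }
  out <- rbind(singles, if (length(multi)) do.call(rbind, multi))
  out
}

# Longest fragment of a mention (ties: first); SQuAD answers must be
# contiguous, so discontinuous reasons are flattened to it.
longest_fragment <- function(frags) {
  len <- frags$end - frags$start
  frags[which.max(len), , drop = FALSE]
}

#' Convert one document's relation groups into SQuAD-style QA entries
#'
#' A `ONE_DRUG_NO_REASON` group becomes an unanswerable entry; every other
#' group becomes an answerable entry with one answer span per linked reason
#' mention (duplicate answer strings at distinct offsets are retained;
#' discontinuous reason mentions contribute their longest contiguous
#' fragment). One entry is emitted per question template, the canonical
#' template first. Entry identifiers are deterministic:
#' `"<doc_id>::<drug terms joined by '+'>::t<template index>"`.
#'
#' @param ann an [annotation_set()] object.
#' @param config an [qa_config()] object.
#' @return tibble with columns `qa_id`, `doc_id`, `question`, `drug_names`
#'   (list), `is_impossible`, `answers` (list of tibbles with `text`,
#'   `answer_start`), `category`, `template`.
#' @export
build_qa_entries <- function(ann, config = qa_config()) {
  groups <- group_relations(ann)
  groups <- filter_groups_by_mode(groups, config$multidrug_mode)
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    terms <- groups$drug_terms[[g]]
    questions <- render_question(terms, config$templates)
    rm_ids <- groups$reason_mention_ids[[g]]
    if (length(rm_ids) == 0) {
      answers <- tibble::tibble(text = character(), answer_start = integer())
    } else {
      frag <- lapply(rm_ids, function(id) {
        longest_fragment(ann$mentions$fragments[[match(id, ann$mentions$mention_id)]])
      })
      starts <- vapply(frag, function(f) as.integer(f$start), integer(1))
      ends <- vapply(frag, function(f) as.integer(f$end), integer(1))
      ord <- order(starts)
      answers <- tibble::tibble(
        text = mapply(slice_text, starts[ord], ends[ord],
                      MoreArgs = list(text = ann$text)),
        answer_start = starts[ord])
    }
    for (t in seq_along(questions)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        qa_id = sprintf("%s::%s::t%d", ann$doc_id,
                        paste(terms, collapse = "+"), t),
        doc_id = ann$doc_id, question = questions[t],
        drug_names = list(terms), is_impossible = length(rm_ids) == 0,
        answers = list(answers), category = groups$category[g],
        template = t)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(qa_id = character(), doc_id = character(),
                          question = character(), drug_names = list(),
                          is_impossible = logical(), answers = list(),
                          category = character(), template = integer()))
  }
  do.call(rbind, rows)
}

filter_groups_by_mode <- function(groups, mode) {
  if (nrow(groups) == 0 || mode == "both") return(groups)
  if (mode == "split_only") return(groups[!groups$multidrug, , drop = FALSE])
  # combined_only: keep multidrug groups, unanswerable singles, and answerable
  # singles whose drug does not belong to any multidrug group
  covered <- unique(unlist(groups$drug_terms[groups$multidrug]))
  keep <- groups$multidrug |
    groups$category == "ONE_DRUG_NO_REASON" |
    !vapply(groups$drug_terms, function(t) t[1] %in% covered, logical(1))
  groups[keep, , drop = FALSE]
}

#' Build QA entries for a whole corpus
#'
#' @param annotations named list of [annotation_set()] objects.
#' @param config an [qa_config()] object.
#' @return row-bound tibble of per-document [build_qa_entries()] results.
#' @export
build_qa_dataset <- function(annotations, config = qa_config()) {
  do.call(rbind, lapply(annotations, build_qa_entries, config = config))
}

#' Write QA entries as a SQuAD-2.0-style JSON file
#'
#' Emits the `version`/`data`/`title`/`paragraphs`/`context`/`qas` structure
#' with per-question fields `id`, `question`, `_mname` (the drug name(s) the
#' question asks about, as a JSON array), `is_impossible` and
#' `answers[{text, answer_start}]`, with keys in fixed order for byte
#' stability. Every `answer_start` is verified against its context before
#' writing; a mismatch aborts naming the offending entry.
#'
#' @param entries tibble from [build_qa_entries()] / [read_squad()].
#' @param documents tibble with columns `doc_id`, `text`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
write_squad <- function(entries, documents, path = NULL) {
  data <- list()
  for (doc in unique(entries$doc_id)) {
    j <- match(doc, documents$doc_id)
    if (is.na(j)) stop(sprintf("entries reference unknown document '%s'", doc))
    text <- documents$text[j]
    sub <- entries[entries$doc_id == doc, , drop = FALSE]
    qas <- lapply(seq_len(nrow(sub)), function(i) {
      ans <- sub$answers[[i]]
      for (k in seq_len(nrow(ans))) {
        got <- substr(text, ans$answer_start[k] + 1L,
                      ans$answer_start[k] + nchar(ans$text[k]))
        if (!identical(got, ans$text[k])) {
          stop(sprintf("answer offset mismatch in %s: expected '%s', found '%s'",
                       sub$qa_id[i], ans$text[k], got))
        }
      }
      list(
        id = sub$qa_id[i],
        question = sub$question[i],
        `_mname` = as.list(sub$drug_names[[i]]),
        is_impossible = sub$is_impossible[i],
        answers = lapply(seq_len(nrow(ans)), function(k) {
          list(text = ans$text[k], answer_start = ans$answer_start[k])
        })
      )
    })
    data[[length(data) + 1L]] <- list(
      title = doc,
      paragraphs = list(list(context = text, qas = qas)))
  }
  json <- jsonlite::toJSON(list(version = "v2.0", data = data),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) writeLines(json, path, useBytes = TRUE)
  invisible(as.character(json))
}

#' Read a SQuAD-2.0-style JSON file
#'
#' @param path file written by [write_squad()] (or any file following the
#'   same schema; a missing `_mname` field yields an empty drug list).
#' @return list with `entries` (tibble as from [build_qa_entries()], without
#'   `category`) and `documents` (tibble `doc_id`, `text`).
#' @export
read_squad <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  erows <- list()
  drows <- list()
  for (d in raw$data) {
    for (p in d$paragraphs) {
      doc_id <- d$title %||% sprintf("doc%04d", length(drows) + 1L)
      drows[[length(drows) + 1L]] <-
        tibble::tibble(doc_id = doc_id, text = p$context)
      for (q in p$qas) {
        ans <- if (length(q$answers)) {
          tibble::tibble(
            text = vapply(q$answers, function(a) a$text, character(1)),
            answer_start = vapply(q$answers, function(a)
              as.integer(a$answer_start), integer(1)))
        } else {
          tibble::tibble(text = character(), answer_start = integer())
        }
        erows[[length(erows) + 1L]] <- tibble::tibble(
          qa_id = q$id, doc_id = doc_id, question = q$question,
          drug_names = list(as.character(unlist(q$`_mname`))),
          is_impossible = isTRUE(q$is_impossible), answers = list(ans))
      }
    }
  }
  list(entries = do.call(rbind, erows), documents = do.call(rbind, drows))
}

#' Partition documents into train/dev/test splits
#'
#' Document-level partition: split sizes are the largest-remainder
#' apportionment of the (normalized) ratios, with fractional-remainder ties
#' broken toward the earlier split; the assignment of documents to splits is a
#' seeded shuffle, so the same seed always yields the same partition.
#'
#' @param doc_ids character vector of document identifiers.
#' @param ratios nonnegative split ratios (train, dev, test); default `5:2:3`.
#' @param seed integer seed for the shuffle.
#' @return list with elements `train`, `dev`, `test`.
#' @export
split_documents <- function(doc_ids, ratios = c(5, 2, 3), seed = 1) {
  stopifnot(length(ratios) == 3, all(ratios >= 0), sum(ratios) > 0)
  if (length(doc_ids) < sum(ratios > 0)) {
    stop("fewer documents than nonzero ratio cells")
  }
  p <- ratios / sum(ratios)
  n <- length(doc_ids)
  quota <- n * p
  sizes <- floor(quota)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- quota - sizes
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  shuffled <- with_local_seed(seed, sample(doc_ids))
  cuts <- cumsum(sizes)
  list(train = shuffled[seq_len(sizes[1])],
       dev = if (sizes[2] > 0) shuffled[(cuts[1] + 1):cuts[2]] else character(),
       test = if (sizes[3] > 0) shuffled[(cuts[2] + 1):cuts[3]] else character())
}
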