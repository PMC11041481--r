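#' Integer percentage breakdown of a count vector
#'
#' Percentages of the total, rounded half away from zero to `digits` decimal
#' places (integers by default). The reported convention everywhere in the
#' corpus summaries.
#'
#' @param counts nonnegative numeric vector.
#' @param digits decimal places (default 0).
#' @return numeric vector of percentages.
#' @export
percent_breakdown <- function(counts, digits = 0) {
  round_half_away(100 * counts / sum(counts), digits)
}

#' Pooled event-rate estimate across review runs
#'
#' `100 * sum(events) / sum(trials)`, rounded half away from zero to one
#' decimal by default — the convention used for off-label prevalence
#' estimates pooled over repeated manual-review samples.
#'
#' @param events per-run event counts.
#' @param trials per-run sample sizes.
#' @param digits decimal places (default 1).
#' @return a single percentage.
#' @export
rate_estimate <- function(events, trials, digits = 1) {
  round_half_away(100 * sum(events) / sum(trials), digits)
}

#' Distribution of unique answers per answerable question
#'
#' Counts the distinct lowercased answer strings of each answerable entry and
#' buckets the questions as 1, 2, 3 or ">=4" unique answers, with integer
#' percentages of the answerable total.
#'
#' @param entries tibble from [build_qa_entries()].
#' @return tibble with columns `unique_answers` (factor-ordered character:
#'   `"1"`, `"2"`, `"3"`, `">=4"`), `n`, `percent`; only observed buckets.
#' @export
answer_count_distribution <- function(entries) {
  ans <- entries[!entries$is_impossible, , drop = FALSE]
  if (nrow(ans) == 0) {
    return(tibble::tibble(unique_answers = character(), n = integer(),
                          percent = numeric()))
  }
  k <- vapply(ans$answers, function(a) length(unique(normalize_term(a$text))),
              integer(1))
  bucket <- ifelse(k >= 4, ">=4", as.character(k))
  levels <- c("1", "2", "3", ">=4")
  tab <- table(factor(bucket, levels = levels))
  keep <- tab > 0
  tibble::tibble(unique_answers = levels[keep],
                 n = as.integer(tab[keep]),
                 percent = percent_breakdown(as.integer(tab))[keep])
}

#' Drug and drug-reason pair frequencies over QA entries
#'
#' Frequency is the number of QA entries mentioning the lowercased term (or
#' pair), i.e. entry-denominated, not mention-denominated. Drug rankings are
#' reported separately for answerable and unanswerable entries.
#'
#' @param entries tibble from [build_qa_entries()].
#' @return list with ranked tibbles `answerable_drugs`, `unanswerable_drugs`
#'   (columns `term`, `n`) and `pairs` (columns `drug`, `reason`, `n`).
#' @export
term_frequencies <- function(entries) {
  rank_terms <- function(terms) {
    if (length(terms) == 0) {
      return(tibble::tibble(term = character(), n = integer()))
    }
    tab <- sort(table(terms), decreasing = TRUE)
    tibble::tibble(term = names(tab), n = as.integer(tab))
  }
  drug_lists <- lapply(entries$drug_names, normalize_term)
  answerable <- !entries$is_impossible
  pairs <- list()
  for (i in which(answerable)) {
    reasons <- unique(normalize_term(entries$answers[[i]]$text))
    for (d in drug_lists[[i]]) {
      for (r in reasons) {
        pairs[[length(pairs) + 1L]] <- c(d, r)
      }
    }
  }
  pair_tbl <- if (length(pairs)) {
    keys <- vapply(pairs, paste, character(1), collapse = "\x1f")
    tab <- sort(table(keys), decreasing = TRUE)
    parts <- stringr::str_split_fixed(names(tab), "\x1f", 2)
    tibble::tibble(drug = parts[, 1], reason = parts[, 2], n = as.integer(tab))
  } else {
    tibble::tibble(drug = character(), reason = character(), n = integer())
  }
  list(
    answerable_drugs = rank_terms(unlist(drug_lists[answerable])),
    unanswerable_drugs = rank_terms(unlist(drug_lists[!answerable])),
    pairs = pair_tbl
  )
}

#' Sentence distance between a question's drug and its reasons
#'
#' The number of sentences between the nearest drug mention and the nearest
#' reason mention of a relation group: the minimum over all (drug mention,
#' reason mention) pairs of the absolute difference of their sentence indices
#' (0 when some pair shares a sentence). A mention's sentence is the one
#' containing its first fragment's start offset.
#'
#' @param ann an [annotation_set()] object.
#' @param group a single row of [group_relations()] output.
#' @param splitter sentence splitter (default [split_sentences()]).
#' @return nonnegative integer distance.
#' @export
sentence_distance <- function(ann, group, splitter = split_sentences) {
  rm_ids <- group$reason_mention_ids[[1]]
  if (length(rm_ids) == 0) stop("sentence_distance: group is unanswerable")
  dm_ids <- group$drug_mention_ids[[1]]
  spans <- splitter(ann$text)
  idx_of <- function(mid) {
    f <- ann$mentions$fragments[[match(mid, ann$mentions$mention_id)]]
    sentence_index_at(spans, as.integer(f$start[1]))
  }
  di <- vapply(dm_ids, idx_of, integer(1))
  ri <- vapply(rm_ids, idx_of, integer(1))
  min(abs(outer(di, ri, `-`)))
}

#' Sentence-distance records for every answerable group in a corpus
#'
#' @param annotations named list of [annotation_set()] objects.
#' @param splitter sentence splitter.
#' @return tibble with columns `doc_id`, `drug_terms` (list), `category`,
#'   `multidrug`, `distance`.
#' @export
corpus_sentence_distances <- function(annotations, splitter = split_sentences) {
  rows <- list()
  for (ann in annotations) {
    groups <- group_relations(ann)
    for (g in seq_len(nrow(groups))) {
      if (groups$category[g] == "ONE_DRUG_NO_REASON") next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        doc_id = ann$doc_id, drug_terms = groups$drug_terms[g],
        category = groups$category[g], multidrug = groups$multidrug[g],
        distance = sentence_distance(ann, groups[g, , drop = FALSE], splitter))
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(doc_id = character(), drug_terms = list(),
                   category = character(), multidrug = logical(),
                   distance = integer())
}

#' Screen drug-reason pairs against an indication lookup table
#'
#' A pair is on-label iff the (lowercased drug, lowercased reason) pair
#' appears verbatim in the knowledge base; everything else is "unknown"
#' (candidate off-label, for human review). This is a deliberately simple
#' exact-match screen: a pluggable two-column lookup stands in for a full
#' medication-indication knowledge base.
#'
#' @param pairs tibble with columns `drug`, `reason`.
#' @param kb tibble with columns `drug`, `indication` (two-column TSV read
#'   with [read_indication_kb()]).
#' @return list with `pairs` (input plus logical `on_label`), `n_on_label`,
#'   `n_unknown`, and `unknown_pct` (one-decimal percentage).
#' @export
off_label_screen <- function(pairs, kb) {
  if (nrow(kb) == 0) warning("empty knowledge base: all pairs unknown")
  kb_keys <- paste(normalize_term(kb$drug), normalize_term(kb$indication),
                   sep = "\x1f")
  keys <- paste(normalize_term(pairs$drug), normalize_term(pairs$reason),
                sep = "\x1f")
  on_label <- keys %in% kb_keys
  pairs$on_label <- on_label
  list(pairs = pairs,
       n_on_label = sum(on_label),
       n_unknown = sum(!on_label),
       unknown_pct = round_half_away(100 * mean(!on_label), 1))
}

#' Read a two-column drug/indication lookup table
#'
#' @param path tab-separated file with columns `drug`, `indication` (no
#'   header required; a `drug<TAB>indication` header line is skipped).
#' @return tibble with columns `drug`, `indication`.
#' @export
read_indication_kb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  tbl <- tibble::tibble(drug = parts[, 1], indication = parts[, 2])
  tbl[normalize_term(tbl$drug) != "drug", , drop = FALSE]
}

#' Summary report over a built QA corpus
#'
#' Convenience bundle of the corpus analytics: entry counts by category,
#' unique-answer distribution, term/pair frequencies, and the
#' sentence-distance histogram (with integer percentages and the cumulative
#' same-or-adjacent share).
#'
#' @param entries tibble from [build_qa_dataset()].
#' @param annotations named list of [annotation_set()] objects.
#' @return list of tibbles/lists; see Details.
#' @export
corpus_stats_report <- function(entries, annotations) {
  dist <- corpus_sentence_distances(annotations)
  dist_tab <- if (nrow(dist)) {
    tab <- table(dist$distance)
    tibble::tibble(distance = as.integer(names(tab)), n = as.integer(tab),
                   percent = percent_breakdown(as.integer(tab)))
  } else {
    tibble::tibble(distance = integer(), n = integer(), percent = numeric())
  }
  list(
    n_entries = nrow(entries),
    n_answerable = sum(!entries$is_impossible),
    n_unanswerable = sum(entries$is_impossible),
    by_category = {
      tab <- table(entries$category)
      tibble::tibble(category = names(tab), n = as.integer(tab))
    },
    unique_answers = answer_count_distribution(entries),
    frequencies = term_frequencies(entries),
    sentence_distances = dist_tab
  )
}
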