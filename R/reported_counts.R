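#' Reported summary counts of the released RxWhyQA corpus
#'
#' The RxWhyQA corpus itself is distributed under a data-use agreement and is
#' not shipped here, but its published summary tables are: entry counts per
#' relation category, the unique-answer histogram of the answerable
#' questions, the drug-reason sentence-distance histogram, and the per-run
#' off-label review tallies. They are machine-readable inputs for the
#' summarization helpers ([percent_breakdown()], [rate_estimate()]), so the
#' corpus-level totals and percentages can be recomputed rather than quoted.
#'
#' @return list of tibbles: `entry_counts` (`category`, `n`),
#'   `unique_answer_counts` (`unique_answers`, `n`),
#'   `sentence_distance_counts` (`distance`, `n`),
#'   `off_label_reviews` (`run`, `off_label`, `reviewed`).
#' @export
reported_corpus_counts <- function() {
  dir <- system.file("extdata", "reported", package = "rxwhyqa")
  read_tsv2 <- function(name) {
    utils::read.delim(file.path(dir, name), sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
  list(
    entry_counts = tibble::as_tibble(read_tsv2("entry_counts.tsv")),
    unique_answer_counts = tibble::as_tibble(read_tsv2("unique_answer_counts.tsv")),
    sentence_distance_counts =
      tibble::as_tibble(read_tsv2("sentence_distance_counts.tsv")),
    off_label_reviews = tibble::as_tibble(read_tsv2("off_label_reviews.tsv"))
  )
}

#' Recompute the headline corpus summary from the reported counts
#'
#' Derives, from the raw reported counts alone: the total number of QA
#' entries, the number of multi-answer questions, the single-/multi-answer
#' percentage split, the same-sentence and same-or-adjacent-sentence
#' percentages of the drug-reason distance histogram, and the pooled
#' off-label rate.
#'
#' @param counts list from [reported_corpus_counts()].
#' @return named list of numbers.
#' @export
reported_corpus_summary <- function(counts = reported_corpus_counts()) {
  ua <- counts$unique_answer_counts
  single <- ua$n[ua$unique_answers == "1"]
  multi <- sum(ua$n[ua$unique_answers != "1"])
  split_pct <- percent_breakdown(c(single, multi))
  d <- counts$sentence_distance_counts
  dist_pct <- percent_breakdown(d$n)
  cum_pct <- round_half_away(100 * cumsum(d$n) / sum(d$n))
  list(
    total_entries = sum(counts$entry_counts$n),
    answerable_questions = sum(ua$n),
    multi_answer_questions = multi,
    single_answer_pct = split_pct[1],
    multi_answer_pct = split_pct[2],
    same_sentence_pct = dist_pct[d$distance == 0],
    same_or_adjacent_pct = cum_pct[d$distance == 1],
    off_label_pct = rate_estimate(counts$off_label_reviews$off_label,
                                  counts$off_label_reviews$reviewed)
  )
}
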