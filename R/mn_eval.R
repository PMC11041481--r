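#' Normalize an answer string to tokens
#'
#' The SQuAD-style evaluation convention: lowercase, strip punctuation
#' characters, drop the articles a/an/the, split on whitespace.
#'
#' @param text character scalar.
#' @return character vector of tokens (possibly empty).
#' @export
normalize_tokens <- function(text) {
  x <- tolower(text)
  x <- stringr::str_remove_all(x, "[[:punct:]]")
  toks <- stringr::str_split_1(stringr::str_squish(x), " ")
  toks <- toks[nzchar(toks)]
  toks[!toks %in% c("a", "an", "the")]
}

normalized_answer_key <- function(text) {
  paste(normalize_tokens(text), collapse = " ")
}

# Multiset intersection size of two token vectors.
token_overlap <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0L)
  shared <- intersect(a, b)
  sum(vapply(shared, function(t) min(sum(a == t), sum(b == t)), integer(1)))
}

# Coerce answers to a canonical tibble: dedup by normalized string (keeping
# the smallest offset) and sort by offset then key, so input order never
# influences scoring. dedupe = FALSE keeps duplicate strings (sensitivity
# analyses only).
canonical_answers <- function(x, tokenizer = normalize_tokens,
                              dedupe = TRUE) {
  if (is.character(x)) {
    x <- tibble::tibble(text = x, answer_start = rep(NA_integer_, length(x)))
  }
  if (nrow(x) == 0) {
    return(tibble::tibble(text = character(), answer_start = integer(),
                          key = character()))
  }
  x$key <- vapply(x$text, function(t) paste(tokenizer(t), collapse = " "),
                  character(1))
  x <- x[order(x$answer_start, x$key, method = "radix", na.last = TRUE), ,
         drop = FALSE]
  if (dedupe) x <- x[!duplicated(x$key), , drop = FALSE]
  x
}

#' Score one question's gold answers against its model answers
#'
#' Weighted token-overlap counts for an M-gold-to-N-model comparison.
#' Anchoring on each gold answer, the model answer with the most overlapping
#' tokens (multiset intersection of normalized tokens; ties to the model
#' answer at the smaller offset) sets the weighted true-positive and
#' false-negative mass; the weighted false positive is set vice versa by
#' anchoring on each model answer. Both sides are deduplicated by normalized
#' string before scoring. Abstention conventions: both sides empty counts one
#' sentinel true-positive token (a correctly unanswered question); an answer
#' offered against empty gold counts one false-negative token plus all its
#' tokens as false positives; a missed nonempty gold counts all gold tokens
#' as false negatives.
#'
#' @param gold_answers,model_answers tibbles with `text`, `answer_start`
#'   (character vectors also accepted; empty = abstention/unanswerable).
#' @param tokenizer tokenization function (default [normalize_tokens()]).
#' @param dedupe deduplicate by normalized string before scoring (default
#'   `TRUE`; disable only for sensitivity analyses).
#' @return named numeric vector `c(wTP, wFN, wFP)`.
#' @export
score_question <- function(gold_answers, model_answers,
                           tokenizer = normalize_tokens, dedupe = TRUE) {
  g <- canonical_answers(gold_answers, tokenizer, dedupe)
  m <- canonical_answers(model_answers, tokenizer, dedupe)
  gt <- lapply(g$text, tokenizer)
  mt <- lapply(m$text, tokenizer)
  wTP <- 0; wFN <- 0; wFP <- 0
  if (nrow(g) == 0 && nrow(m) == 0) {
    return(c(wTP = 1, wFN = 0, wFP = 0))
  }
  if (nrow(g) == 0) {
    return(c(wTP = 0, wFN = 1, wFP = sum(lengths(mt))))
  }
  if (nrow(m) == 0) {
    return(c(wTP = 0, wFN = sum(lengths(gt)), wFP = 0))
  }
  for (i in seq_along(gt)) {
    ov <- vapply(mt, token_overlap, integer(1), a = gt[[i]])
    best <- unname(ov[which.max(ov)])  # m sorted by offset: first max wins ties
    wTP <- wTP + best
    wFN <- wFN + length(gt[[i]]) - best
  }
  for (j in seq_along(mt)) {
    ov <- vapply(gt, token_overlap, integer(1), a = mt[[j]])
    wFP <- wFP + length(mt[[j]]) - max(ov)
  }
  c(wTP = wTP, wFN = wFN, wFP = wFP)
}

#' Exhaustive re-derivation of [score_question()] (independent oracle)
#'
#' Recomputes the weighted counts by brute force on small answer sets:
#' overlaps are counted by explicit one-by-one token matching, and each
#' anchor's argmax is verified by full enumeration against every candidate.
#' Intended for property tests; capped at 6 answers per side.
#'
#' @inheritParams score_question
#' @return named numeric vector `c(wTP, wFN, wFP)`.
#' @export
brute_force_oracle <- function(gold_answers, model_answers) {
  g <- canonical_answers(gold_answers)
  m <- canonical_answers(model_answers)
  if (nrow(g) > 6 || nrow(m) > 6) stop("oracle capped at 6 answers per side")
  count_matches <- function(a, b) {
    # remove matched tokens of b one at a time
    pool <- b
    n <- 0L
    for (tok in a) {
      hit <- match(tok, pool)
      if (!is.na(hit)) {
        pool <- pool[-hit]
        n <- n + 1L
      }
    }
    n
  }
  gt <- lapply(g$text, normalize_tokens)
  mt <- lapply(m$text, normalize_tokens)
  if (nrow(g) == 0 && nrow(m) == 0) return(c(wTP = 1, wFN = 0, wFP = 0))
  if (nrow(g) == 0) return(c(wTP = 0, wFN = 1, wFP = sum(lengths(mt))))
  if (nrow(m) == 0) return(c(wTP = 0, wFN = sum(lengths(gt)), wFP = 0))
  wTP <- 0; wFN <- 0; wFP <- 0
  for (i in seq_along(gt)) {
    ovs <- integer(length(mt))
    for (j in seq_along(mt)) ovs[j] <- count_matches(gt[[i]], mt[[j]])
    best_j <- 1L
    for (j in seq_along(mt)) if (ovs[j] > ovs[best_j]) best_j <- j
    # verify the argmax by enumeration
    stopifnot(all(ovs[best_j] >= ovs))
    wTP <- wTP + ovs[best_j]
    wFN <- wFN + length(gt[[i]]) - ovs[best_j]
  }
  for (j in seq_along(mt)) {
    ovs <- integer(length(gt))
    for (i in seq_along(gt)) ovs[i] <- count_matches(mt[[j]], gt[[i]])
    wFP <- wFP + length(mt[[j]]) - max(c(ovs, 0L))
  }
  c(wTP = wTP, wFN = wFN, wFP = wFP)
}

prf <- function(wTP, wFN, wFP) {
  p <- if (wTP + wFP > 0) wTP / (wTP + wFP) else 0
  r <- if (wTP + wFN > 0) wTP / (wTP + wFN) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Aggregate per-question counts into a sliced evaluation report
#'
#' Micro-pooled precision/recall/F1 over the full question set and over the
#' standard slices: unanswerable questions, single- vs multi-answer
#' questions, and single- vs multi-drug questions (the latter four partition
#' the answerable set two ways). Empty slices are absent from the table, not
#' reported as zero. Macro averaging (mean of per-question F1) is available
#' behind a flag.
#'
#' @param question_counts tibble with columns `qa_id`, `wTP`, `wFN`, `wFP`,
#'   `is_impossible`, `n_unique_answers`, `n_drugs`.
#' @param macro also report macro-averaged F1 per slice.
#' @return list with `full` (named list `precision`, `recall`, `f1`, counts)
#'   and `slices` (tibble).
#' @export
aggregate_eval <- function(question_counts, macro = FALSE) {
  qc <- question_counts
  slice_def <- list(
    full = rep(TRUE, nrow(qc)),
    unanswerable = qc$is_impossible,
    single_answer = !qc$is_impossible & qc$n_unique_answers == 1,
    multi_answer = !qc$is_impossible & qc$n_unique_answers > 1,
    single_drug = !qc$is_impossible & qc$n_drugs == 1,
    multi_drug = !qc$is_impossible & qc$n_drugs > 1
  )
  rows <- list()
  for (s in names(slice_def)) {
    sel <- slice_def[[s]]
    if (!any(sel)) next
    sums <- c(wTP = sum(qc$wTP[sel]), wFN = sum(qc$wFN[sel]),
              wFP = sum(qc$wFP[sel]))
    met <- prf(sums[["wTP"]], sums[["wFN"]], sums[["wFP"]])
    row <- tibble::tibble(slice = s, n_questions = sum(sel),
                          wTP = sums[["wTP"]], wFN = sums[["wFN"]],
                          wFP = sums[["wFP"]],
                          precision = met[["precision"]],
                          recall = met[["recall"]], f1 = met[["f1"]])
    if (macro) {
      per_q <- vapply(which(sel), function(i) {
        prf(qc$wTP[i], qc$wFN[i], qc$wFP[i])[["f1"]]
      }, numeric(1))
      row$macro_f1 <- mean(per_q)
    }
    rows[[length(rows) + 1L]] <- row
  }
  slices <- do.call(rbind, rows)
  full <- as.list(slices[slices$slice == "full",
                         c("precision", "recall", "f1", "wTP", "wFN", "wFP")])
  list(full = full, slices = slices)
}

#' Evaluate a predictions file against gold entries
#'
#' Scores every gold entry with [score_question()] against the model's
#' answer list (an entry absent from `predictions` counts as abstention, with
#' a warning) and aggregates with [aggregate_eval()]. Slice labels come from
#' the gold side: `is_impossible`, the number of distinct normalized gold
#' answers, and the number of drugs the question asks about.
#'
#' @param entries gold QA entry tibble.
#' @param predictions named list `qa_id -> tibble(text, answer_start)` (an
#'   empty tibble or `character()` encodes abstention), e.g. the
#'   `predictions` element of [extract_multi_answers()].
#' @param macro also report macro-averaged F1.
#' @return as [aggregate_eval()], plus `questions` (the per-question counts).
#' @export
evaluate_predictions <- function(entries, predictions, macro = FALSE) {
  missing <- setdiff(entries$qa_id, names(predictions))
  if (length(missing)) {
    warning(sprintf("%d entries without predictions treated as abstentions",
                    length(missing)))
  }
  rows <- lapply(seq_len(nrow(entries)), function(i) {
    gold <- entries$answers[[i]]
    pred <- predictions[[entries$qa_id[i]]] %||%
      tibble::tibble(text = character(), answer_start = integer())
    counts <- score_question(gold, pred)
    tibble::tibble(
      qa_id = entries$qa_id[i],
      wTP = counts[["wTP"]], wFN = counts[["wFN"]], wFP = counts[["wFP"]],
      is_impossible = entries$is_impossible[i],
      n_unique_answers = length(unique(vapply(gold$text, normalized_answer_key,
                                              character(1)))),
      n_drugs = length(entries$drug_names[[i]]))
  })
  qc <- do.call(rbind, rows)
  out <- aggregate_eval(qc, macro = macro)
  out$questions <- qc
  out
}
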