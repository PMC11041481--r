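#' Construct a model answer
#'
#' The unit returned by any answerer conforming to the single-answer
#' extractive-QA contract: a literal span of the (possibly masked) context
#' plus a confidence score (higher is better).
#'
#' @param text answer surface string.
#' @param answer_start 0-based character offset of `text` in the context the
#'   answerer was given.
#' @param score real-valued confidence.
#' @return list of class `rx_model_answer`.
#' @export
model_answer <- function(text, answer_start, score = 1) {
  structure(list(text = unname(text), answer_start = as.integer(answer_start),
                 score = as.numeric(unname(score))),
            class = "rx_model_answer")
}

#' The answerer contract
#'
#' An answerer is any function
#' `f(question, drug_names, context, no_answer_threshold = 0, qa_id = NULL)`
#' that deterministically returns either `NULL` (refrain / no answer) or a
#' [model_answer()] whose `text` equals the context slice at
#' `[answer_start, answer_start + nchar(text))`, and that refrains whenever
#' its best score falls below `no_answer_threshold`. The drug anchor comes
#' from the entry's `_mname` payload (`drug_names`), not from re-parsing the
#' question. [pattern_baseline()] and [scripted_mock()] both conform; a
#' transformer-backed adapter can be plugged in behind the same signature.
#'
#' @param answer a candidate return value.
#' @param context the context it was produced from.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_model_answer <- function(answer, context) {
  if (is.null(answer)) return(invisible(TRUE))
  stopifnot(inherits(answer, "rx_model_answer"))
  got <- substr(context, answer$answer_start + 1L,
                answer$answer_start + nchar(answer$text))
  if (!identical(got, answer$text)) {
    stop(sprintf("model answer '%s' does not match context slice '%s'",
                 answer$text, got))
  }
  invisible(TRUE)
}

# token table of a text window: tibble(text, start, end) with 1-based
# inclusive positions relative to the window
window_tokens <- function(window) {
  loc <- stringr::str_locate_all(window, "\\S+")[[1]]
  tibble::tibble(
    text = stringr::str_sub(window, loc[, 1], loc[, 2]),
    start = as.integer(loc[, 1]), end = as.integer(loc[, 2]))
}

# A content token carries at least one non-mask alphanumeric character and is
# not a stopword.
is_content_token <- function(tok, stopwords, mask_char = "_") {
  stripped <- stringr::str_remove_all(
    tolower(tok), paste0("[[:punct:]", mask_char, "]"))
  nzchar(stripped) & !(stripped %in% stopwords)
}

# Trim leading/trailing punctuation from a window-relative span; returns
# c(start, end) or NULL if nothing remains.
trim_punct_span <- function(window, start, end) {
  while (start <= end &&
         stringr::str_detect(substr(window, start, start), "[[:punct:][:space:]]")) {
    start <- start + 1L
  }
  while (end >= start &&
         stringr::str_detect(substr(window, end, end), "[[:punct:][:space:]]")) {
    end <- end - 1L
  }
  if (start > end) return(NULL)
  c(start, end)
}

# Capture the reason slot after `from` (forward) or before `to` (backward):
# skip non-content tokens, then take the contiguous run of content tokens
# (up to max_tokens), trimmed of surrounding punctuation.
capture_span <- function(tokens, window, stopwords, from = NULL, to = NULL,
                         max_tokens = 6L) {
  if (!is.null(from)) {
    cand <- tokens[tokens$start > from, , drop = FALSE]
  } else {
    cand <- tokens[tokens$end < to, , drop = FALSE]
    cand <- cand[rev(seq_len(nrow(cand))), , drop = FALSE]
  }
  if (nrow(cand) == 0) return(NULL)
  content <- is_content_token(cand$text, stopwords)
  first <- which(content)[1]
  if (is.na(first)) return(NULL)
  run_end <- first
  while (run_end < nrow(cand) && content[run_end + 1L] &&
         run_end - first + 1L < max_tokens) {
    run_end <- run_end + 1L
  }
  run <- cand[first:run_end, , drop = FALSE]
  trim_punct_span(window, min(run$start), max(run$end))
}

#' Rule-based pattern answerer
#'
#' A no-training baseline implementing the answerer contract with the
#' contextual trigger families of [context_patterns()]: it locates each
#' anchor drug in the context, applies the compiled patterns within the
#' sentence window of each occurrence, and captures the shortest contiguous
#' content-token span filling the reason slot (at most 6 tokens, trimmed of
#' stopwords and punctuation, stopped at sentence boundaries). The score of a
#' capture is its pattern's priority weight; the highest-scoring capture
#' wins, ties broken by earliest offset. It refrains when nothing is
#' captured, when the best capture is below the threshold, or when a capture
#' consists only of mask characters.
#'
#' @param question question string (unused by this baseline; the anchor comes
#'   from `drug_names`).
#' @param drug_names nonempty character vector of anchor drug names.
#' @param context document text (possibly masked).
#' @param no_answer_threshold minimum score to answer.
#' @param params list: `patterns` ([context_patterns()] table), `splitter`,
#'   `stopwords`, `max_tokens`.
#' @return a [model_answer()] or `NULL` (refrain).
#' @export
pattern_baseline_answer <- function(question, drug_names, context,
                                    no_answer_threshold = 0,
                                    params = list()) {
  stopifnot(length(drug_names) >= 1)
  patterns <- params$patterns %||% context_patterns()
  splitter <- params$splitter %||% split_sentences
  stopwords <- params$stopwords %||% baseline_stopwords()
  max_tokens <- params$max_tokens %||% 6L

  spans <- splitter(context)
  candidates <- list()
  for (drug in drug_names) {
    occ <- stringr::str_locate_all(
      context, stringr::regex(paste0("\\b", regex_escape(drug), "\\b"),
                              ignore_case = TRUE))[[1]]
    if (nrow(occ) == 0) next
    sent_idx <- unique(vapply(occ[, 1], function(p) {
      sentence_index_at(spans, as.integer(p) - 1L)
    }, integer(1)))
    sent_idx <- sent_idx[!is.na(sent_idx)]
    for (si in sent_idx) {
      row <- spans[spans$index == si, , drop = FALSE]
      window <- slice_text(context, row$start, row$end)
      tokens <- window_tokens(window)
      for (p in seq_len(nrow(patterns))) {
        cap <- baseline_capture(patterns[p, , drop = FALSE], drug, window,
                                tokens, stopwords, max_tokens)
        if (is.null(cap)) next
        abs_start <- row$start + cap[1] - 1L  # 0-based context offset
        candidates[[length(candidates) + 1L]] <- tibble::tibble(
          text = substr(window, cap[1], cap[2]),
          answer_start = as.integer(abs_start),
          score = patterns$weight[p])
      }
    }
  }
  if (length(candidates) == 0) return(NULL)
  cand <- do.call(rbind, candidates)
  cand <- cand[!is_mask_only(cand$text), , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(-cand$score, cand$answer_start), , drop = FALSE]
  if (cand$score[1] < no_answer_threshold) return(NULL)
  model_answer(cand$text[1], cand$answer_start[1], cand$score[1])
}

# Apply one pattern family around a drug in a sentence window; returns a
# window-relative capture span or NULL.
baseline_capture <- function(pattern, drug, window, tokens, stopwords,
                             max_tokens) {
  gap <- "(?:\\S+\\s+){0,12}?"
  drug_re <- paste0("\\b", regex_escape(drug), "\\b")
  if (pattern$direction == "DRUG_FIRST") {
    re <- paste0("(?i)", drug_re, "[\\s:,\\-]*", gap, pattern$trigger)
    m <- regexpr(re, window, perl = TRUE)
    if (m == -1) return(NULL)
    capture_span(tokens, window, stopwords,
                 from = as.integer(m) + attr(m, "match.length") - 1L,
                 max_tokens = max_tokens)
  } else {
    re <- paste0("(?i)", pattern$trigger, drug_re)
    m <- regexpr(re, window, perl = TRUE)
    if (m == -1) return(NULL)
    capture_span(tokens, window, stopwords, to = as.integer(m),
                 max_tokens = max_tokens)
  }
}

#' Wrap the pattern baseline as an answerer function
#'
#' @param params see [pattern_baseline_answer()].
#' @return a function conforming to the answerer contract.
#' @export
pattern_baseline <- function(params = list()) {
  function(question, drug_names, context, no_answer_threshold = 0,
           qa_id = NULL) {
    pattern_baseline_answer(question, drug_names, context,
                            no_answer_threshold, params)
  }
}

#' Scripted test double for the answerer contract
#'
#' Replays a fixed script: for each question id, a list of per-round
#' responses, each either `NA` (refrain) or an answer string to be located
#' (case-insensitively, first occurrence) in the context supplied at that
#' round — so positions are verified against the masked text the driver
#' actually passes. Any call outside the script is an error: tests must be
#' exhaustive.
#'
#' @param script named list: `qa_id -> list(response, response, ...)`;
#'   responses are `NA` (refrain), a string, or `list(text =, score =)`.
#' @return a function conforming to the answerer contract.
#' @export
scripted_mock <- function(script) {
  calls <- new.env(parent = emptyenv())
  function(question, drug_names, context, no_answer_threshold = 0,
           qa_id = NULL) {
    if (is.null(qa_id) || !qa_id %in% names(script)) {
      stop(sprintf("scripted_mock: unscripted question id '%s'",
                   qa_id %||% "<null>"))
    }
    n_prev <- get0(qa_id, envir = calls, ifnotfound = 0L)
    round <- n_prev + 1L
    assign(qa_id, round, envir = calls)
    steps <- script[[qa_id]]
    if (round > length(steps)) {
      stop(sprintf("scripted_mock: no scripted response for '%s' round %d",
                   qa_id, round))
    }
    step <- steps[[round]]
    if (length(step) == 1 && is.na(step[[1]])) return(NULL)
    text <- if (is.list(step)) step$text else step
    score <- if (is.list(step)) step$score %||% 1 else 1
    loc <- stringr::str_locate(context,
                               stringr::regex(regex_escape(text),
                                              ignore_case = TRUE))
    if (is.na(loc[1])) {
      stop(sprintf("scripted_mock: scripted answer '%s' absent from context for '%s'",
                   text, qa_id))
    }
    model_answer(stringr::str_sub(context, loc[1], loc[2]), loc[1] - 1L, score)
  }
}

#' Calibrate the no-answer threshold on a development set
#'
#' Runs the answerer once per development question (no masking) at each
#' candidate threshold and returns the grid value maximizing the pooled
#' weighted-overlap F1 ([evaluate_predictions()]); ties break toward the
#' larger (more conservative) threshold.
#'
#' @param answerer a contract-conforming answerer.
#' @param dev_entries QA entries with gold answers (must contain both
#'   answerable and unanswerable questions for the trade-off to be visible).
#' @param documents tibble `doc_id`, `text`.
#' @param grid numeric vector of candidate thresholds.
#' @return list with `threshold`, and the tibble `sweep` of F1 per grid value.
#' @export
calibrate_no_answer_threshold <- function(answerer, dev_entries, documents,
                                          grid) {
  if (length(grid) == 0) stop("empty threshold grid")
  f1s <- vapply(grid, function(th) {
    preds <- lapply(seq_len(nrow(dev_entries)), function(i) {
      ctx <- documents$text[match(dev_entries$doc_id[i], documents$doc_id)]
      ans <- answerer(dev_entries$question[i], dev_entries$drug_names[[i]],
                      ctx, th, dev_entries$qa_id[i])
      if (is.null(ans)) {
        tibble::tibble(text = character(), answer_start = integer())
      } else {
        tibble::tibble(text = ans$text, answer_start = ans$answer_start)
      }
    })
    names(preds) <- dev_entries$qa_id
    evaluate_predictions(dev_entries, preds)$full$f1
  }, numeric(1))
  best <- max(f1s)
  threshold <- max(grid[f1s == best])
  list(threshold = threshold,
       sweep = tibble::tibble(threshold = grid, f1 = f1s))
}
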