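#' Masking loop configuration
#'
#' @param max_rounds safety cap on masking rounds (the loop normally stops
#'   when a full round yields no novel answer anywhere); must be >= 1.
#' @param mask_char single masking character (default `"_"`).
#' @param no_answer_threshold threshold passed through to the answerer.
#' @param keep_mask_only_answers if `TRUE`, answers consisting only of mask
#'   characters are recorded rather than dropped (they always terminate the
#'   question's loop either way); off by default.
#' @return list of class `rx_masking_config`.
#' @export
masking_config <- function(max_rounds = 10L, mask_char = "_",
                           no_answer_threshold = 0,
                           keep_mask_only_answers = FALSE) {
  stopifnot(max_rounds >= 1, nchar(mask_char) == 1)
  structure(list(max_rounds = as.integer(max_rounds), mask_char = mask_char,
                 no_answer_threshold = no_answer_threshold,
                 keep_mask_only_answers = keep_mask_only_answers),
            class = "rx_masking_config")
}

#' Mask every occurrence of an answer string in a context
#'
#' Replaces each case-insensitive, non-overlapping (left-to-right) occurrence
#' of `answer_text` with mask characters of identical length, so the output
#' always has the same length as the input. An answer consisting only of mask
#' characters is a no-op (returned unchanged).
#'
#' @param context context string.
#' @param answer_text nonempty answer string.
#' @param mask_char masking character.
#' @return masked context, same length as `context`.
#' @export
mask_answer <- function(context, answer_text, mask_char = "_") {
  if (!nzchar(answer_text)) stop("answer_text must be nonempty")
  if (is_mask_only(answer_text, mask_char)) {
    message("mask_answer: answer is mask-only; context unchanged")
    return(context)
  }
  gsub(paste0("(?i)", regex_escape(answer_text)),
       strrep(mask_char, nchar(answer_text)),
       context, perl = TRUE)
}

#' Drive a single-answer model to produce multiple answers by incremental
#' masking
#'
#' Each question owns a private working copy of its document text. Round
#' after round, the answerer's top answer is recorded if it is novel (its
#' normalized string not yet recorded for that question and not composed
#' solely of mask characters), then masked throughout that question's working
#' context; a question is frozen once the answerer refrains, repeats itself,
#' or returns a mask-only span. The loop stops when a full round yields no
#' novel answer anywhere, or at `max_rounds`. Masking preserves length, so
#' all recorded offsets are valid in the original text.
#'
#' @param answerer a contract-conforming answerer (see [pattern_baseline()]).
#' @param entries QA entry tibble (gold answers are not consulted).
#' @param documents tibble `doc_id`, `text`.
#' @param config an [masking_config()] object.
#' @return list of class `rx_masking_result`: `predictions` (named list
#'   `qa_id -> tibble(text, answer_start)`, zero rows meaning abstention),
#'   `rounds` (per-round tibble with `round`, `n_active`, `n_novel`,
#'   `newly_masked_chars`), `questions` (per-question tibble with `qa_id`,
#'   `n_answers`, `rounds`, `stop_reason`), `capped` (logical).
#' @export
extract_multi_answers <- function(answerer, entries, documents,
                                  config = masking_config()) {
  n <- nrow(entries)
  ctx0 <- documents$text[match(entries$doc_id, documents$doc_id)]
  if (anyNA(ctx0)) {
    stop("entries reference documents absent from `documents`")
  }
  work <- ctx0
  active <- rep(TRUE, n)
  stop_reason <- rep(NA_character_, n)
  rounds_used <- rep(0L, n)
  answers <- replicate(n, tibble::tibble(text = character(),
                                         answer_start = integer()),
                       simplify = FALSE)
  seen <- replicate(n, character(), simplify = FALSE)

  round_log <- list()
  round <- 0L
  repeat {
    if (!any(active) || round >= config$max_rounds) break
    n_novel <- 0L
    newly_masked <- 0L
    n_active <- sum(active)
    for (i in which(active)) {
      ans <- answerer(entries$question[i], entries$drug_names[[i]], work[i],
                      config$no_answer_threshold, entries$qa_id[i])
      rounds_used[i] <- round + 1L
      if (is.null(ans)) {
        active[i] <- FALSE
        stop_reason[i] <- "refrain"
        next
      }
      got <- substr(work[i], ans$answer_start + 1L,
                    ans$answer_start + nchar(ans$text))
      if (!identical(got, ans$text)) {
        stop(sprintf(
          "answerer contract violation for '%s' in round %d: offset %d holds '%s', not '%s'",
          entries$qa_id[i], round, ans$answer_start, got, ans$text))
      }
      if (is_mask_only(ans$text, config$mask_char)) {
        if (config$keep_mask_only_answers) {
          answers[[i]] <- rbind(answers[[i]],
                                tibble::tibble(text = ans$text,
                                               answer_start = ans$answer_start))
        }
        active[i] <- FALSE
        stop_reason[i] <- "mask_only"
        next
      }
      norm <- paste(normalize_term(ans$text))
      if (norm %in% seen[[i]]) {
        active[i] <- FALSE
        stop_reason[i] <- "repeat"
        next
      }
      seen[[i]] <- c(seen[[i]], norm)
      answers[[i]] <- rbind(answers[[i]],
                            tibble::tibble(text = ans$text,
                                           answer_start = ans$answer_start))
      n_novel <- n_novel + 1L
      masked <- mask_answer(work[i], ans$text, config$mask_char)
      newly_masked <- newly_masked +
        (stringr::str_count(masked, stringr::fixed(config$mask_char)) -
           stringr::str_count(work[i], stringr::fixed(config$mask_char)))
      work[i] <- masked
    }
    round_log[[length(round_log) + 1L]] <- tibble::tibble(
      round = round, n_active = n_active, n_novel = n_novel,
      newly_masked_chars = as.integer(newly_masked))
    round <- round + 1L
    if (n_novel == 0L) break
  }
  capped <- any(active)
  stop_reason[active] <- "max_rounds"

  predictions <- answers
  names(predictions) <- entries$qa_id
  structure(
    list(predictions = predictions,
         rounds = do.call(rbind, round_log) %||%
           tibble::tibble(round = integer(), n_active = integer(),
                          n_novel = integer(), newly_masked_chars = integer()),
         questions = tibble::tibble(
           qa_id = entries$qa_id,
           n_answers = vapply(answers, nrow, integer(1)),
           rounds = rounds_used, stop_reason = stop_reason),
         capped = capped),
    class = "rx_masking_result")
}

#' Termination certificate for a masking run
#'
#' Machine-checkable termination argument: every round that recorded a novel
#' answer masked at least one previously unmasked character, so the number of
#' productive rounds is bounded by the context length (and by the round cap).
#' Errors if the recorded rounds violate that invariant.
#'
#' @param result an `rx_masking_result` from [extract_multi_answers()].
#' @return list with `rounds` (the per-round log), `productive_rounds`,
#'   `capped`, `valid` (`TRUE`).
#' @export
termination_certificate <- function(result) {
  stopifnot(inherits(result, "rx_masking_result"))
  log <- result$rounds
  productive <- log$n_novel > 0
  if (any(productive & log$newly_masked_chars <= 0)) {
    stop("termination violation: a productive round masked no new characters")
  }
  list(rounds = log, productive_rounds = sum(productive),
       capped = result$capped, valid = TRUE)
}
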