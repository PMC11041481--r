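#' Contextual trigger patterns between drug and reason mentions
#'
#' The four trigger-pattern families frequently observed around drug-reason
#' pairs in clinical notes, compiled as case-insensitive regular expressions.
#' Shorthand in the human-readable `pattern` column: `...` is a bounded word
#' gap, parentheses scope, `[a|b]` is an alternation, and `?` marks an
#' optional element. Each row carries a synthetic exemplar sentence built from
#' the pattern's own elements; the compiled pattern must match it (a shipped
#' self-check, exercised by [pattern_self_coverage()]).
#'
#' @param gap_limit maximum number of intervening words an ellipsis may span
#'   (default 12).
#' @return tibble with columns `pattern_id`, `direction`
#'   (`"REASON_FIRST"`/`"DRUG_FIRST"`), `weight` (priority; higher wins),
#'   `pattern` (human-readable form), `template` (regex with `{DRUG}`,
#'   `{REASON}` slots), `trigger` (regex of the anchor trigger used by the
#'   answering baseline), `exemplar`, `exemplar_drug`, `exemplar_reason`.
#' @export
context_patterns <- function(gap_limit = 12) {
  gap <- sprintf("(?:\\S+\\s+){0,%d}?", gap_limit)
  sep <- "[\\s:,\\-]*"
  tibble::tibble(
    pattern_id = c("reason_started_on_drug", "drug_prn_reason",
                   "drug_given_for_reason", "reason_managed_with_drug"),
    direction = c("REASON_FIRST", "DRUG_FIRST", "DRUG_FIRST", "REASON_FIRST"),
    weight = c(25, 18, 14, 13),
    pattern = c(
      "Reason ... (being)? [received|started|restarted|required|maintained|continued?] (on)? Drug",
      "Drug ... [prn|PRN|(as needed for)?] Reason",
      "Drug ... (was)? [attempted|given|dosing|taking] for (any)? [possible|likely|presumed]? Reason",
      "Reason ... (was)? [managed|treated|improved|recommended|downtrended|resolved|reversed|needed] with Drug"
    ),
    template = c(
      paste0("{REASON}\\b", sep, gap,
             "(?:being\\s+)?(?:received|started|restarted|required|maintained|continued?)",
             "\\s+(?:on\\s+)?", gap, "{DRUG}\\b"),
      paste0("{DRUG}\\b", sep, gap,
             "(?:(?:prn|as\\s+needed\\s+for)\\s+)?{REASON}\\b"),
      paste0("{DRUG}\\b", sep, gap,
             "(?:was\\s+)?(?:attempted|given|dosing|taking)\\s+for\\s+",
             "(?:any\\s+)?(?:(?:possible|likely|presumed)\\s+)?{REASON}\\b"),
      paste0("{REASON}\\b", sep, gap,
             "(?:was\\s+)?(?:managed|treated|improved|recommended|downtrended|",
             "resolved|reversed|needed)\\s+with\\s+", gap, "{DRUG}\\b")
    ),
    trigger = c(
      "(?:being\\s+)?(?:received|started|restarted|required|maintained|continued?)\\s+(?:on\\s+)?",
      "(?:prn|as\\s+needed\\s+for|for)\\s+",
      "(?:was\\s+)?(?:attempted|given|dosing|taking)\\s+for\\s+(?:any\\s+)?(?:(?:possible|likely|presumed)\\s+)?",
      "(?:was\\s+)?(?:managed|treated|improved|recommended|downtrended|resolved|reversed|needed)\\s+with\\s+"
    ),
    exemplar = c(
      "Afib: patient being restarted on coumadin.",
      "Morphine 2 mg IV Q4H prn pain.",
      "Vancomycin was given for presumed pneumonia.",
      "Constipation was managed with senna."
    ),
    exemplar_drug = c("coumadin", "Morphine", "Vancomycin", "senna"),
    exemplar_reason = c("Afib", "pain", "pneumonia", "Constipation")
  )
}

# Fill the {DRUG}/{REASON} slots of a pattern template with literal surfaces.
compile_pattern <- function(template, drug_surface, reason_surface) {
  re <- stringr::str_replace_all(template, stringr::fixed("{DRUG}"),
                                 regex_escape(drug_surface))
  re <- stringr::str_replace_all(re, stringr::fixed("{REASON}"),
                                 regex_escape(reason_surface))
  paste0("(?i)", re)
}

#' Match a drug-reason pair against the contextual patterns
#'
#' Reads the sentence window spanning both mentions (from the start of the
#' earlier mention's sentence to the end of the later one's) and reports every
#' pattern family whose ordered elements align with the token sequence, in
#' priority (weight) order.
#'
#' @param text document text.
#' @param drug_span,reason_span length-2 integer vectors `c(start, end)`,
#'   0-based half-open character offsets of the two mentions.
#' @param patterns pattern table from [context_patterns()].
#' @param splitter sentence splitter, by default [split_sentences()].
#' @return character vector of matching `pattern_id`s (possibly empty).
#' @export
match_context_patterns <- function(text, drug_span, reason_span,
                                   patterns = context_patterns(),
                                   splitter = split_sentences) {
  spans <- splitter(text)
  si_d <- sentence_index_at(spans, drug_span[1])
  si_r <- sentence_index_at(spans, reason_span[1])
  if (is.na(si_d) || is.na(si_r)) return(character())
  lo <- min(si_d, si_r); hi <- max(si_d, si_r)
  win_start <- spans$start[spans$index == lo]
  win_end <- spans$end[spans$index == hi]
  window <- slice_text(text, win_start, win_end)
  drug_surface <- slice_text(text, drug_span[1], drug_span[2])
  reason_surface <- slice_text(text, reason_span[1], reason_span[2])

  ord <- order(-patterns$weight)
  hits <- character()
  for (i in ord) {
    re <- compile_pattern(patterns$template[i], drug_surface, reason_surface)
    if (stringr::str_detect(window, re)) {
      hits <- c(hits, patterns$pattern_id[i])
    }
  }
  hits
}

#' Self-check the pattern table against its shipped exemplars
#'
#' Runs each compiled pattern family over its own exemplar sentence and
#' reports whether it matches.
#'
#' @param patterns pattern table from [context_patterns()].
#' @return tibble with columns `pattern_id`, `matched` (logical).
#' @export
pattern_self_coverage <- function(patterns = context_patterns()) {
  matched <- logical(nrow(patterns))
  for (i in seq_len(nrow(patterns))) {
    sent <- patterns$exemplar[i]
    d <- stringr::str_locate(stringr::str_to_lower(sent),
                             stringr::fixed(tolower(patterns$exemplar_drug[i])))
    r <- stringr::str_locate(stringr::str_to_lower(sent),
                             stringr::fixed(tolower(patterns$exemplar_reason[i])))
    ids <- match_context_patterns(
      sent, c(d[1] - 1L, d[2]), c(r[1] - 1L, r[2]), patterns)
    matched[i] <- patterns$pattern_id[i] %in% ids
  }
  tibble::tibble(pattern_id = patterns$pattern_id, matched = matched)
}
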