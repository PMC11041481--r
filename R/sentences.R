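#' Rule-based sentence splitter
#'
#' Breaks a note into sentence spans on (a) newlines and (b) runs of
#' `.`, `?`, `!` followed by whitespace and an uppercase letter or digit.
#' Spans are contiguous 0-based half-open character ranges over the original
#' text (whitespace-only spans are dropped), so any character offset maps to
#' exactly one sentence. Any function with the same signature and return shape
#' can be passed wherever a `splitter` argument is accepted, e.g. to swap in a
#' model-based segmenter.
#'
#' @param text document text (newline-normalized).
#' @return tibble with columns `index` (0-based sentence index), `start`,
#'   `end` (0-based half-open), `sentence` (the raw span text).
#' @export
split_sentences <- function(text) {
  n <- nchar(text)
  if (n == 0) {
    return(tibble::tibble(index = integer(), start = integer(),
                          end = integer(), sentence = character()))
  }
  locs <- stringr::str_locate_all(text, "[.?!]+(?=[ \\t]+[A-Z0-9])|\\n")[[1]]
  bounds <- sort(unique(c(0L, as.integer(locs[, 2]), n)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  spans <- tibble::tibble(start = starts, end = ends)
  spans$sentence <- mapply(slice_text, spans$start, spans$end,
                           MoreArgs = list(text = text))
  keep <- nzchar(stringr::str_trim(spans$sentence))
  spans <- spans[keep, , drop = FALSE]
  spans$index <- seq_len(nrow(spans)) - 1L
  spans[, c("index", "start", "end", "sentence")]
}

# Sentence index (0-based) containing a 0-based character offset; NA if the
# offset falls in dropped whitespace or out of range.
sentence_index_at <- function(spans, offset) {
  hit <- which(spans$start <= offset & offset < spans$end)
  if (length(hit) == 0) return(NA_integer_)
  spans$index[hit[1]]
}
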