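#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Integer (or fixed-decimal) rounding where ties go away from zero, the
#' convention used for all reported percentages (base R's `round()` rounds
#' half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Escape a literal string for use inside a PCRE pattern.
regex_escape <- function(x) {
  stringr::str_replace_all(x, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\\\1")
}

# Lowercase + collapse internal whitespace + trim; the term identity used for
# drug/reason normalization throughout the package.
normalize_term <- function(x) {
  stringr::str_squish(stringr::str_to_lower(x))
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Normalize line endings to "\n" before any character offsets are interpreted.
normalize_newlines <- function(x) {
  stringr::str_replace_all(x, "\r\n|\r", "\n")
}

# "a", "a and b", "a, b, and c"
collapse_term_list <- function(terms) {
  n <- length(terms)
  if (n == 0) stop("empty term list")
  if (n == 1) return(terms)
  if (n == 2) return(paste(terms[1], "and", terms[2]))
  paste0(paste(terms[-n], collapse = ", "), ", and ", terms[n])
}

# Slice a document by a 0-based half-open character range.
slice_text <- function(text, start, end) {
  substr(text, start + 1L, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small fixed stopword list (articles, be-verbs, prepositions, conjunctions,
# anaphors) used to trim captured reason spans in the pattern baseline.
baseline_stopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "rxwhyqa")
  if (nzchar(path)) {
    readLines(path, warn = FALSE)
  } else {
    c("a", "an", "the", "is", "are", "was", "were", "be", "been", "being",
      "am", "of", "for", "to", "with", "on", "in", "at", "by", "from", "as",
      "or", "and", "per", "this", "that", "it", "patient", "pt", "he", "she",
      "his", "her", "they")
  }
}

# A token made only of mask characters / punctuation-free content check.
is_mask_only <- function(x, mask_char = "_") {
  stripped <- stringr::str_remove_all(x, paste0("[", mask_char, "[:space:]]"))
  !nzchar(stripped)
}
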