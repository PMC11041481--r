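# Fixture builders: canonical example documents for each relation category,
# constructed programmatically so character offsets are always exact.

# Locate the n-th occurrence of `surface` in `text`; returns c(start, end),
# 0-based half-open.
locate_nth <- function(text, surface, n = 1) {
  loc <- stringr::str_locate_all(text, stringr::fixed(surface))[[1]]
  stopifnot(nrow(loc) >= n)
  c(loc[n, 1] - 1L, loc[n, 2])
}

# Build standoff annotation text from mention specs
# mentions: list of list(type=, surface=, occ=), relations: list of
# c(drug_mention_index, reason_mention_index)
make_brat <- function(text, mentions, relations = list()) {
  t_lines <- vapply(seq_along(mentions), function(i) {
    m <- mentions[[i]]
    span <- locate_nth(text, m$surface, m$occ %||% 1)
    sprintf("T%d\t%s %d %d\t%s", i, m$type, span[1], span[2], m$surface)
  }, character(1))
  r_lines <- vapply(seq_along(relations), function(k) {
    r <- relations[[k]]
    sprintf("R%d\tReason-Drug Arg1:T%d Arg2:T%d", k, r[1], r[2])
  }, character(1))
  paste(c(t_lines, r_lines), collapse = "\n")
}

make_ann <- function(text, mentions, relations = list(), doc_id = "doc") {
  read_brat_standoff(text, make_brat(text, mentions, relations), doc_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- canonical category fixtures -------------------------------------------

fixture_morphine <- function() {
  make_ann("The patient received morphine for pain as needed",
           list(list(type = "Drug", surface = "morphine"),
                list(type = "Reason", surface = "pain")),
           list(c(1, 2)), doc_id = "morphine-doc")
}

fixture_mirtazapine <- function() {
  make_ann("Mirtazapine 15 mg PO QHS",
           list(list(type = "Drug", surface = "Mirtazapine")),
           doc_id = "mirtazapine-doc")
}

fixture_amlodipine <- function() {
  text <- paste("Hypertension: severely elevated blood pressure.",
                "Started amlodipine, metoprolol, and isosorbide.")
  make_ann(text,
           list(list(type = "Reason", surface = "severely elevated blood pressure"),
                list(type = "Drug", surface = "amlodipine"),
                list(type = "Drug", surface = "metoprolol"),
                list(type = "Drug", surface = "isosorbide")),
           list(c(2, 1), c(3, 1), c(4, 1)), doc_id = "amlodipine-doc")
}

fixture_albuterol <- function() {
  text <- "Albuterol sulfate 90 mcg Puff Inhalation Q4H for sob or wheeze."
  make_ann(text,
           list(list(type = "Drug", surface = "Albuterol sulfate"),
                list(type = "Reason", surface = "sob"),
                list(type = "Reason", surface = "wheeze")),
           list(c(1, 2), c(1, 3)), doc_id = "albuterol-doc")
}

fixture_asa_plavix <- function() {
  text <- paste("Left frontoparietal stroke - maintained on ASA and plavix.",
                "Hx of CVA: restarted ASA/Plavix per the GI team's recommendation.")
  make_ann(text,
           list(list(type = "Reason", surface = "stroke"),
                list(type = "Drug", surface = "ASA", occ = 1),
                list(type = "Drug", surface = "plavix", occ = 1),
                list(type = "Reason", surface = "CVA"),
                list(type = "Drug", surface = "ASA", occ = 2),
                list(type = "Drug", surface = "Plavix", occ = 1)),
           list(c(2, 1), c(3, 1), c(5, 4), c(6, 4)), doc_id = "asa-plavix-doc")
}

# tibble(text, answer_start) shortcut
answers_tbl <- function(text = character(), answer_start = integer()) {
  tibble::tibble(text = text, answer_start = as.integer(answer_start))
}
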