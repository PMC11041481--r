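#' Annotation container for one clinical note
#'
#' An `rx_annotations` object bundles one document (identifier plus full text)
#' with its drug/reason concept mentions and the drug-to-reason relations
#' between them. Offsets are 0-based, half-open, counted in unicode characters
#' after newline normalization to `"\n"`.
#'
#' @param doc_id nonempty document identifier.
#' @param text full note text.
#' @param mentions tibble with columns `mention_id`, `concept_type`
#'   (`"DRUG"`/`"REASON"`), `fragments` (list of data frames with 0-based
#'   half-open `start`/`end`), `surface_text`.
#' @param relations tibble with columns `relation_id`, `drug_id`, `reason_id`.
#' @param ignored named list of counts of skipped non-drug/reason content.
#' @return an object of class `rx_annotations`.
#' @export
annotation_set <- function(doc_id, text,
                           mentions = empty_mentions(),
                           relations = empty_relations(),
                           ignored = list(mentions = 0L, relations = 0L)) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  structure(
    list(doc_id = doc_id, text = normalize_newlines(text),
         mentions = mentions, relations = relations, ignored = ignored),
    class = "rx_annotations"
  )
}

empty_mentions <- function() {
  tibble::tibble(mention_id = character(), concept_type = character(),
                 fragments = list(), surface_text = character())
}

empty_relations <- function() {
  tibble::tibble(relation_id = character(), drug_id = character(),
                 reason_id = character())
}

#' @export
print.rx_annotations <- function(x, ...) {
  cat(sprintf("<rx_annotations> doc '%s': %d chars, %d mentions, %d relations\n",
              x$doc_id, nchar(x$text), nrow(x$mentions), nrow(x$relations)))
  invisible(x)
}

#' Parse BRAT standoff annotations for one document
#'
#' Reads the standoff dialect used to distribute drug/reason relation
#' annotations: tab-separated `T` lines for concept mentions
#' (`T1<TAB>Drug 9 17<TAB>morphine`, with `;`-separated ranges for
#' discontinuous spans) and `R` lines for binary relations
#' (`R1<TAB>Reason-Drug Arg1:T1 Arg2:T2`). Only `Drug` and `Reason` mentions
#' and the relations linking a drug to a reason (either argument order) are
#' kept; all other annotation types are ignored, with counts recorded in the
#' returned object's `ignored` field.
#'
#' @param doc_text raw note text.
#' @param ann_text raw standoff annotation text (may be empty).
#' @param doc_id document identifier to attach.
#' @return an [annotation_set()] object.
#' @export
read_brat_standoff <- function(doc_text, ann_text, doc_id = "doc") {
  text <- normalize_newlines(doc_text)
  lines <- stringr::str_split_1(ann_text %||% "", "\n")
  lines <- lines[nzchar(stringr::str_trim(lines))]

  all_mentions <- list()   # every T line (any type), for reference resolution
  rel_rows <- list()
  n_ignored_m <- 0L
  n_ignored_r <- 0L
  n_ignored_other <- 0L

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    tag <- substr(line, 1, 1)
    if (tag == "T") {
      fields <- stringr::str_split_1(line, "\t")
      if (length(fields) < 2) {
        stop(sprintf("malformed mention line %d: %s", i, line))
      }
      head_parts <- stringr::str_match(
        fields[2], "^(\\S+) (\\d+ \\d+(?:;\\d+ \\d+)*)$")
      if (is.na(head_parts[1, 1])) {
        stop(sprintf("malformed mention line %d: %s", i, line))
      }
      type <- head_parts[1, 2]
      ranges <- stringr::str_split_1(head_parts[1, 3], ";")
      frag <- do.call(rbind, lapply(ranges, function(r) {
        as.integer(stringr::str_split_1(r, " "))
      }))
      frags <- data.frame(start = frag[, 1], end = frag[, 2])
      frags <- frags[order(frags$start), , drop = FALSE]
      if (any(frags$end > nchar(text)) || any(frags$start >= frags$end)) {
        stop(sprintf("mention %s on line %d: offsets outside document (len %d)",
                     fields[1], i, nchar(text)))
      }
      surface <- paste(mapply(slice_text, frags$start, frags$end,
                              MoreArgs = list(text = text)),
                       collapse = " ")
      all_mentions[[fields[1]]] <- list(type = type, fragments = frags,
                                        surface = surface)
    } else if (tag == "R") {
      fields <- stringr::str_split_1(line, "\t")
      m <- stringr::str_match(
        fields[2], "^(\\S+) Arg1:(T\\S+) Arg2:(T\\S+)\\s*$")
      if (length(fields) < 2 || is.na(m[1, 1])) {
        stop(sprintf("malformed relation line %d: %s", i, line))
      }
      rel_rows[[length(rel_rows) + 1L]] <-
        list(id = fields[1], arg1 = m[1, 3], arg2 = m[1, 4])
    } else {
      # attribute/event/note lines (A/E/#/...) are outside the drug-reason scope
      n_ignored_other <- n_ignored_other + 1L
    }
  }

  keep <- vapply(all_mentions, function(m) m$type %in% c("Drug", "Reason"),
                 logical(1))
  n_ignored_m <- sum(!keep)
  kept <- all_mentions[keep]

  mentions <- tibble::tibble(
    mention_id = names(kept),
    concept_type = unname(vapply(kept, function(m) toupper(m$type), character(1))),
    fragments = unname(lapply(kept, function(m) m$fragments)),
    surface_text = unname(vapply(kept, function(m) m$surface, character(1)))
  )

  rel_out <- list()
  for (r in rel_rows) {
    for (arg in c(r$arg1, r$arg2)) {
      if (is.null(all_mentions[[arg]])) {
        stop(sprintf("relation %s references missing mention %s", r$id, arg))
      }
    }
    t1 <- all_mentions[[r$arg1]]$type
    t2 <- all_mentions[[r$arg2]]$type
    if (setequal(c(t1, t2), c("Drug", "Reason"))) {
      drug <- if (t1 == "Drug") r$arg1 else r$arg2
      reason <- if (t1 == "Reason") r$arg1 else r$arg2
      rel_out[[length(rel_out) + 1L]] <-
        tibble::tibble(relation_id = r$id, drug_id = drug, reason_id = reason)
    } else {
      n_ignored_r <- n_ignored_r + 1L
    }
  }
  relations <- if (length(rel_out)) do.call(rbind, rel_out) else empty_relations()

  annotation_set(doc_id, text, mentions, relations,
                 ignored = list(mentions = n_ignored_m, relations = n_ignored_r,
                                other = n_ignored_other))
}

#' Serialize an annotation set back to BRAT standoff
#'
#' Deterministic inverse of [read_brat_standoff()]: identifiers are renumbered
#' `T1..Tn` / `R1..Rm` in input order, so `read(write(x))` reproduces `x` up to
#' identifier renaming and two calls on the same input are byte-identical.
#'
#' @param ann an [annotation_set()] object.
#' @return list with elements `doc_text` and `ann_text`.
#' @export
write_brat_standoff <- function(ann) {
  stopifnot(inherits(ann, "rx_annotations"))
  id_map <- stats::setNames(paste0("T", seq_len(nrow(ann$mentions))),
                            ann$mentions$mention_id)
  t_lines <- character(nrow(ann$mentions))
  for (i in seq_len(nrow(ann$mentions))) {
    frags <- ann$mentions$fragments[[i]]
    ranges <- paste(sprintf("%d %d", frags$start, frags$end), collapse = ";")
    type <- if (ann$mentions$concept_type[i] == "DRUG") "Drug" else "Reason"
    t_lines[i] <- sprintf("%s\t%s %s\t%s", id_map[[ann$mentions$mention_id[i]]],
                          type, ranges, ann$mentions$surface_text[i])
  }
  r_lines <- character(nrow(ann$relations))
  for (i in seq_len(nrow(ann$relations))) {
    r_lines[i] <- sprintf("R%d\tReason-Drug Arg1:%s Arg2:%s", i,
                          id_map[[ann$relations$drug_id[i]]],
                          id_map[[ann$relations$reason_id[i]]])
  }
  list(doc_text = ann$text,
       ann_text = paste(c(t_lines, r_lines), collapse = "\n"))
}

#' Validate the structural invariants of an annotation set
#'
#' Checks fragment ordering and bounds, surface-text fidelity against the
#' document slice, identifier uniqueness, and relation endpoint types. A
#' surface text differing from the slice only in whitespace is reported with
#' severity `"warning"` (real standoff files often collapse whitespace);
#' everything else is severity `"error"`. Violations are data, not conditions.
#'
#' @param ann an [annotation_set()] object.
#' @return tibble with columns `id`, `rule`, `severity`, `message`; zero rows
#'   when every invariant holds.
#' @export
validate_annotation_set <- function(ann) {
  v <- list()
  add <- function(id, rule, severity, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(
      id = id, rule = rule, severity = severity, message = message)
  }
  n <- nchar(ann$text)
  if (!nzchar(ann$doc_id)) add("", "doc_id_nonempty", "error", "empty doc_id")
  if ((nrow(ann$mentions) > 0 || nrow(ann$relations) > 0) && n == 0) {
    add(ann$doc_id, "text_nonempty", "error", "annotated document has no text")
  }
  if (anyDuplicated(ann$mentions$mention_id)) {
    add(ann$mentions$mention_id[duplicated(ann$mentions$mention_id)][1],
        "mention_id_unique", "error", "duplicate mention_id")
  }
  if (anyDuplicated(ann$relations$relation_id)) {
    add(ann$relations$relation_id[duplicated(ann$relations$relation_id)][1],
        "relation_id_unique", "error", "duplicate relation_id")
  }
  for (i in seq_len(nrow(ann$mentions))) {
    id <- ann$mentions$mention_id[i]
    frags <- ann$mentions$fragments[[i]]
    if (any(frags$start >= frags$end) || any(frags$end > n) ||
        any(frags$start < 0)) {
      add(id, "fragment_bounds", "error", "fragment outside [0, len(text))")
      next
    }
    if (is.unsorted(frags$start) ||
        (nrow(frags) > 1 && any(frags$end[-nrow(frags)] > frags$start[-1]))) {
      add(id, "fragments_sorted_disjoint", "error",
          "fragments overlap or are unsorted")
    }
    slice <- paste(mapply(slice_text, frags$start, frags$end,
                          MoreArgs = list(text = ann$text)), collapse = " ")
    if (!identical(slice, ann$mentions$surface_text[i])) {
      ws_equal <- identical(stringr::str_squish(slice),
                            stringr::str_squish(ann$mentions$surface_text[i]))
      add(id, "surface_matches_slice",
          if (ws_equal) "warning" else "error",
          sprintf("surface '%s' != slice '%s'",
                  ann$mentions$surface_text[i], slice))
    }
    if (!ann$mentions$concept_type[i] %in% c("DRUG", "REASON")) {
      add(id, "concept_type", "error", "concept_type not DRUG/REASON")
    }
  }
  for (i in seq_len(nrow(ann$relations))) {
    rid <- ann$relations$relation_id[i]
    for (role in c("drug", "reason")) {
      mid <- ann$relations[[paste0(role, "_id")]][i]
      j <- match(mid, ann$mentions$mention_id)
      if (is.na(j)) {
        add(rid, "relation_endpoint_exists", "error",
            sprintf("%s endpoint %s not found", role, mid))
      } else if (ann$mentions$concept_type[j] != toupper(role)) {
        add(rid, "relation_endpoint_type", "error",
            sprintf("%s endpoint %s has type %s", role, mid,
                    ann$mentions$concept_type[j]))
      }
    }
  }
  if (length(v)) do.call(rbind, v) else
    tibble::tibble(id = character(), rule = character(),
                   severity = character(), message = character())
}

#' Read a directory of paired note/annotation files
#'
#' Expects `<id>.txt` / `<id>.ann` pairs (the `.ann` file may be absent, in
#' which case the document carries no annotations).
#'
#' @param notes_dir directory of `.txt` files.
#' @param ann_dir directory of `.ann` files; defaults to `notes_dir`.
#' @return named list of [annotation_set()] objects, keyed by doc id.
#' @export
read_corpus_dir <- function(notes_dir, ann_dir = notes_dir) {
  txts <- sort(list.files(notes_dir, pattern = "\\.txt$", full.names = TRUE))
  out <- list()
  for (f in txts) {
    id <- sub("\\.txt$", "", basename(f))
    ann_file <- file.path(ann_dir, paste0(id, ".ann"))
    ann_text <- if (file.exists(ann_file)) {
      paste(readLines(ann_file, warn = FALSE), collapse = "\n")
    } else ""
    out[[id]] <- read_brat_standoff(
      paste(readLines(f, warn = FALSE), collapse = "\n"), ann_text, doc_id = id)
  }
  out
}

#' Write a corpus of annotation sets as `<id>.txt` / `<id>.ann` pairs
#'
#' @param annotations named list of [annotation_set()] objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_corpus_dir <- function(annotations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ann in annotations) {
    pair <- write_brat_standoff(ann)
    writeLines(pair$doc_text, file.path(dir, paste0(ann$doc_id, ".txt")),
               sep = "")
    writeLines(pair$ann_text, file.path(dir, paste0(ann$doc_id, ".ann")),
               sep = "")
  }
  invisible(dir)
}

#' Document table of an annotation corpus
#'
#' @param annotations named list of [annotation_set()] objects.
#' @return tibble with columns `doc_id`, `text`.
#' @export
corpus_documents <- function(annotations) {
  tibble::tibble(
    doc_id = unname(vapply(annotations, function(a) a$doc_id, character(1))),
    text = unname(vapply(annotations, function(a) a$text, character(1)))
  )
}
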