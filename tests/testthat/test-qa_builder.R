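test_that("relation grouping assigns the five categories", {
  g <- group_relations(fixture_morphine())
  expect_equal(g$category, "ONE_TO_ONE")

  g <- group_relations(fixture_mirtazapine())
  expect_equal(g$category, "ONE_DRUG_NO_REASON")

  g <- group_relations(fixture_albuterol())
  expect_equal(g$category, "ONE_TO_N")
  expect_length(g$reason_strings[[1]], 2)

  # three drugs sharing one reason: 3 single groups + 1 combined group
  g <- group_relations(fixture_amlodipine())
  expect_equal(sum(g$category == "ONE_TO_ONE"), 3)
  expect_equal(sum(g$category == "N_TO_ONE"), 1)
  expect_equal(g$drug_terms[[which(g$category == "N_TO_ONE")]],
               c("amlodipine", "metoprolol", "isosorbide"))

  # two drugs sharing two reasons
  g <- group_relations(fixture_asa_plavix())
  expect_equal(sum(g$category == "ONE_TO_N"), 2)
  expect_equal(sum(g$category == "M_TO_N"), 1)
  expect_equal(sort(g$reason_strings[[which(g$category == "M_TO_N")]]),
               c("cva", "stroke"))
})

test_that("question rendering follows the singular/plural list templates", {
  expect_equal(render_question("morphine"),
               "Why was morphine prescribed to the patient?")
  expect_equal(render_question(c("amlodipine", "metoprolol", "isosorbide")),
               "Why were amlodipine, metoprolol, and isosorbide prescribed to the patient?")
  expect_equal(render_question(c("asa", "plavix")),
               "Why were asa and plavix prescribed to the patient?")
  expect_error(render_question(character()), "nonempty")

  paraphrases <- tibble::tibble(
    singular = c("Why was {drugs} prescribed to the patient?",
                 "What was the reason for prescribing {drugs}?"),
    plural = c("Why were {drugs} prescribed to the patient?",
               "What was the reason for prescribing {drugs}?"))
  q <- render_question("senna", paraphrases)
  expect_length(q, 2)
  expect_equal(q[1], "Why was senna prescribed to the patient?")
})

test_that("entries carry offset-verified answers; duplicates retained", {
  e <- build_qa_entries(fixture_morphine())
  expect_equal(nrow(e), 1)
  expect_false(e$is_impossible)
  expect_equal(e$answers[[1]]$text, "pain")
  expect_equal(e$answers[[1]]$answer_start, 34)

  e <- build_qa_entries(fixture_mirtazapine())
  expect_true(e$is_impossible)
  expect_equal(nrow(e$answers[[1]]), 0)

  # the same reason string annotated at three offsets stays three answers
  text <- "Pain reported. Gave oxycodone for pain. Later pain again."
  ann <- make_ann(text,
                  list(list(type = "Drug", surface = "oxycodone"),
                       list(type = "Reason", surface = "Pain", occ = 1),
                       list(type = "Reason", surface = "pain", occ = 1),
                       list(type = "Reason", surface = "pain", occ = 2)),
                  list(c(1, 2), c(1, 3), c(1, 4)), doc_id = "dup")
  e <- build_qa_entries(ann)
  expect_equal(nrow(e), 1)
  expect_equal(nrow(e$answers[[1]]), 3)
  expect_equal(length(unique(normalize_tokens(paste(e$answers[[1]]$text,
                                                    collapse = " ")))), 1)
  expect_equal(e$category, "ONE_TO_ONE")
})

test_that("multidrug_mode controls split vs combined emission", {
  ann <- fixture_amlodipine()
  both <- build_qa_entries(ann, qa_config("both"))
  split <- build_qa_entries(ann, qa_config("split_only"))
  combined <- build_qa_entries(ann, qa_config("combined_only"))
  expect_equal(nrow(both), 4)
  expect_equal(nrow(split), 3)
  expect_equal(nrow(combined), 1)
  expect_equal(combined$category, "N_TO_ONE")
  expect_equal(
    combined$question,
    "Why were amlodipine, metoprolol, and isosorbide prescribed to the patient?")
  expect_equal(nrow(combined$answers[[1]]), 1)
})

test_that("entry conservation: groups times templates, qa_ids deterministic", {
  ann <- fixture_asa_plavix()
  templates <- tibble::tibble(
    singular = c("Why was {drugs} prescribed to the patient?",
                 "What was {drugs} given for?"),
    plural = c("Why were {drugs} prescribed to the patient?",
               "What were {drugs} given for?"))
  e <- build_qa_entries(ann, qa_config("both", templates = templates))
  n_groups <- nrow(group_relations(ann))
  expect_equal(nrow(e), n_groups * 2)
  expect_false(anyDuplicated(e$qa_id) > 0)
  expect_true(all(grepl("::t[12]$", e$qa_id)))
  e2 <- build_qa_entries(ann, qa_config("both", templates = templates))
  expect_identical(e, e2)
})

test_that("SQuAD files round-trip losslessly and verify offsets", {
  corpus <- generate_corpus(generator_config(
    categories = c(one_drug_no_reason = 3, one_to_one = 8, one_to_n = 3,
                   n_to_one = 2, m_to_n = 2), seed = 17))
  entries <- build_qa_dataset(corpus$annotations, qa_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_squad(entries, corpus$documents, path)
  back <- read_squad(path)
  expect_equal(nrow(back$entries), nrow(entries))
  expect_identical(back$entries$qa_id, entries$qa_id)
  expect_identical(back$entries$question, entries$question)
  expect_identical(back$entries$is_impossible, entries$is_impossible)
  expect_identical(back$entries$drug_names, unname(entries$drug_names))
  for (i in seq_len(nrow(entries))) {
    expect_equal(back$entries$answers[[i]]$text, entries$answers[[i]]$text)
    expect_equal(back$entries$answers[[i]]$answer_start,
                 entries$answers[[i]]$answer_start)
  }
  # byte-determinism of the writer
  expect_identical(write_squad(entries, corpus$documents),
                   write_squad(entries, corpus$documents))

  bad <- entries
  bad$answers[[which(!bad$is_impossible)[1]]]$answer_start <- 0L
  expect_error(write_squad(bad, corpus$documents), "offset mismatch")
})

test_that("document splits follow largest-remainder apportionment deterministically", {
  ids <- sprintf("d%03d", 1:303)
  sp <- split_documents(ids, c(5, 2, 3), seed = 9)
  # oracle, derived by hand: quotas 151.5/60.6/90.9 -> floors 151/60/90,
  # two leftover seats go to the largest remainders .9 (test) and .6 (dev)
  expect_equal(lengths(sp), c(train = 151, dev = 61, test = 91))
  expect_setequal(unlist(sp), ids)
  expect_equal(anyDuplicated(unlist(sp)), 0)
  expect_identical(sp, split_documents(ids, c(5, 2, 3), seed = 9))
  expect_false(identical(sp, split_documents(ids, c(5, 2, 3), seed = 10)))

  all_train <- split_documents(ids[1:10], c(1, 0, 0), seed = 1)
  expect_length(all_train$train, 10)
  expect_length(all_train$dev, 0)

  expect_error(split_documents(c("a", "b"), c(5, 2, 3), seed = 1),
               "fewer documents")
})
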