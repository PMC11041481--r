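test_that("masking replaces every case-insensitive occurrence at identical length", {
  expect_equal(mask_answer("admitted for leg edema. leg edema improved",
                           "leg edema"),
               "admitted for _________. _________ improved")
  expect_equal(mask_answer("Pain, pain, PAIN", "pain"), "____, ____, ____")
  ctx <- "nothing to mask here"
  expect_equal(mask_answer(ctx, "absent"), ctx)
  expect_message(out <- mask_answer(ctx, "____"), "mask-only")
  expect_equal(out, ctx)
  expect_error(mask_answer(ctx, ""), "nonempty")
  # length preservation over random inputs
  set.seed(13)
  for (k in 1:20) {
    ctx <- paste(sample(c("pain", "leg", "edema", "x.y", "a(b)"), 12,
                        replace = TRUE), collapse = " ")
    ans <- sample(c("pain", "leg edema", "x.y", "a(b)"), 1)
    expect_equal(nchar(mask_answer(ctx, ans)), nchar(ctx))
  }
})

test_that("an always-refraining answerer yields abstentions after one round", {
  entries <- build_qa_entries(fixture_morphine())
  docs <- tibble::tibble(doc_id = "morphine-doc",
                         text = fixture_morphine()$text)
  refuser <- function(question, drug_names, context, no_answer_threshold = 0,
                      qa_id = NULL) NULL
  res <- extract_multi_answers(refuser, entries, docs)
  expect_equal(nrow(res$predictions[[1]]), 0)
  expect_equal(res$questions$stop_reason, "refrain")
  expect_equal(nrow(res$rounds), 1)
  expect_false(res$capped)
})

test_that("the novelty rule records each normalized answer once and stops on repeats", {
  ctx <- "Leg edema worse. leg  edema stable. Fever too."
  docs <- tibble::tibble(doc_id = "d", text = ctx)
  entries <- tibble::tibble(
    qa_id = "q1", doc_id = "d", question = "q", drug_names = list("x"),
    is_impossible = FALSE, answers = list(answers_tbl("Leg edema", 0)),
    category = "ONE_TO_N", template = 1L)
  # third response normalizes to the already-recorded "leg edema"
  mock <- scripted_mock(list(q1 = list("leg edema", "fever", "leg  edema")))
  res <- extract_multi_answers(mock, entries, docs)
  pred <- res$predictions$q1
  expect_equal(nrow(pred), 2)
  expect_equal(tolower(pred$text[1]), "leg edema")
  expect_equal(tolower(pred$text[2]), "fever")
  expect_equal(res$questions$stop_reason, "repeat")
  # recorded offsets are valid in the ORIGINAL text
  for (k in seq_len(nrow(pred))) {
    expect_equal(tolower(substr(ctx, pred$answer_start[k] + 1,
                                pred$answer_start[k] + nchar(pred$text[k]))),
                 tolower(pred$text[k]))
  }
  cert <- termination_certificate(res)
  expect_true(cert$valid)
  expect_equal(cert$productive_rounds, 2)
})

test_that("mask-only answers freeze the question without being recorded", {
  ctx <- "Edema bad. Edema worse."
  docs <- tibble::tibble(doc_id = "d", text = ctx)
  entries <- tibble::tibble(
    qa_id = "q1", doc_id = "d", question = "q", drug_names = list("x"),
    is_impossible = FALSE, answers = list(answers_tbl("Edema", 0)),
    category = "ONE_TO_ONE", template = 1L)
  mock <- scripted_mock(list(q1 = list("edema", "____")))
  res <- extract_multi_answers(mock, entries, docs)
  expect_equal(res$predictions$q1$text, "Edema")
  expect_equal(res$questions$stop_reason, "mask_only")
  expect_false(any(vapply(res$predictions$q1$text,
                          function(t) grepl("^_+$", t), logical(1))))
})

test_that("masking state is monotone, per-question, and bounded by max_rounds", {
  corpus <- generate_corpus(generator_config(
    categories = c(one_drug_no_reason = 2, one_to_one = 6, one_to_n = 3,
                   n_to_one = 0, m_to_n = 0),
    distance_probs = c("0" = 1), duplicate_answer_rate = 0, seed = 19))
  entries <- build_qa_dataset(corpus$annotations, qa_config())
  res <- extract_multi_answers(pattern_baseline(), entries, corpus$documents)
  cert <- termination_certificate(res)
  expect_true(cert$valid)
  log <- res$rounds
  expect_true(all(log$newly_masked_chars[log$n_novel > 0] > 0))
  expect_true(all(diff(log$n_active) <= 0))
  # no answer string recorded twice per question; none mask-only
  for (p in res$predictions) {
    keys <- tolower(p$text)
    expect_equal(anyDuplicated(keys), 0)
    expect_false(any(grepl("^[_\\s]+$", p$text)))
  }

  capped <- extract_multi_answers(
    scripted_mock(list(q1 = list("Edema", "bad", "worse"))),
    tibble::tibble(qa_id = "q1", doc_id = "d", question = "q",
                   drug_names = list("x"), is_impossible = FALSE,
                   answers = list(answers_tbl("Edema", 0)),
                   category = "ONE_TO_N", template = 1L),
    tibble::tibble(doc_id = "d", text = "Edema bad worse."),
    masking_config(max_rounds = 2))
  expect_true(capped$capped)
  expect_true(termination_certificate(capped)$capped)
})

test_that("a single-answer answerer reduces to classic extraction", {
  corpus <- generate_corpus(pattern_pure_config(seed = 9))
  entries <- build_qa_dataset(corpus$annotations, qa_config())
  once <- local({
    answered <- new.env(parent = emptyenv())
    function(question, drug_names, context, no_answer_threshold = 0,
             qa_id = NULL) {
      if (!is.null(get0(qa_id, envir = answered))) return(NULL)
      assign(qa_id, TRUE, envir = answered)
      pattern_baseline_answer(question, drug_names, context,
                              no_answer_threshold)
    }
  })
  res <- extract_multi_answers(once, entries, corpus$documents)
  expect_true(all(vapply(res$predictions, nrow, integer(1)) <= 1))
})

test_that("contract violations are reported with question id and round", {
  liar <- function(question, drug_names, context, no_answer_threshold = 0,
                   qa_id = NULL) model_answer("xyz", 0)
  entries <- build_qa_entries(fixture_morphine())
  docs <- tibble::tibble(doc_id = "morphine-doc",
                         text = fixture_morphine()$text)
  expect_error(extract_multi_answers(liar, entries, docs),
               "contract violation.*morphine-doc")
})
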