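test_that("token normalization lowercases, strips punctuation, drops articles", {
  expect_equal(normalize_tokens("The leg edema."), c("leg", "edema"))
  expect_equal(normalize_tokens(""), character())
  expect_equal(normalize_tokens("Afib (chronic)"), c("afib", "chronic"))
  expect_equal(normalize_tokens("a an the"), character())
})

test_that("weighted overlap counts follow the gold/model anchoring rule", {
  counts <- score_question(answers_tbl("leg edema", 0), answers_tbl("edema", 4))
  expect_equal(counts, c(wTP = 1, wFN = 1, wFP = 0))
  p <- counts[["wTP"]] / (counts[["wTP"]] + counts[["wFP"]])
  r <- counts[["wTP"]] / (counts[["wTP"]] + counts[["wFN"]])
  expect_equal(2 * p * r / (p + r), 2 / 3)

  # correct abstention earns one sentinel token
  expect_equal(score_question(answers_tbl(), answers_tbl()),
               c(wTP = 1, wFN = 0, wFP = 0))
  # exact multiset match
  expect_equal(score_question(answers_tbl(c("pain", "fever"), c(0, 10)),
                              answers_tbl(c("pain", "fever"), c(0, 10))),
               c(wTP = 2, wFN = 0, wFP = 0))
  # answering an unanswerable question
  expect_equal(score_question(answers_tbl(), answers_tbl("leg edema", 0)),
               c(wTP = 0, wFN = 1, wFP = 2))
  # missing a nonempty gold
  expect_equal(score_question(answers_tbl(c("pain", "leg edema"), c(0, 9)),
                              answers_tbl()),
               c(wTP = 0, wFN = 3, wFP = 0))
})

test_that("pooled aggregation reproduces hand-computed micro metrics", {
  qc <- tibble::tibble(
    qa_id = c("a", "b"), wTP = c(1, 1), wFN = c(1, 0), wFP = c(0, 1),
    is_impossible = c(FALSE, FALSE), n_unique_answers = c(1, 2),
    n_drugs = c(1, 2))
  rep <- aggregate_eval(qc)
  expect_equal(rep$full$precision, 2 / 3)
  expect_equal(rep$full$recall, 2 / 3)
  expect_equal(rep$full$f1, 2 / 3)
  # slice partition: single + multi answer cover the answerable set
  s <- rep$slices
  expect_equal(s$n_questions[s$slice == "single_answer"] +
                 s$n_questions[s$slice == "multi_answer"],
               s$n_questions[s$slice == "full"])
  expect_false("unanswerable" %in% s$slice)  # empty slice absent, not zero
})

test_that("scoring is invariant to answer order and penalizes junk answers", {
  gold <- answers_tbl(c("leg edema", "renal failure"), c(5, 40))
  model <- answers_tbl(c("edema", "failure", "renal"), c(9, 46, 40))
  base <- score_question(gold, model)
  perm <- score_question(gold[c(2, 1), ], model[c(3, 1, 2), ])
  expect_equal(base, perm)

  junk <- rbind(model, answers_tbl("zzz qqq", 90))
  with_junk <- score_question(gold, junk)
  expect_equal(with_junk[["wTP"]], base[["wTP"]])
  expect_gt(with_junk[["wFP"]], base[["wFP"]])

  # duplicate model strings collapse under dedupe, accumulate without it
  dup <- rbind(model, answers_tbl(c("zzz edema", "zzz edema"), c(70, 80)))
  a <- score_question(gold, dup)
  b <- score_question(gold, dup, dedupe = FALSE)
  expect_equal(a[["wFP"]], base[["wFP"]] + 1)
  expect_equal(b[["wFP"]], base[["wFP"]] + 2)
})

test_that("per-question gold token mass is conserved as wTP + wFN", {
  set.seed(41)
  vocab <- c("pain", "leg", "edema", "fever", "afib", "the", "chronic",
             "renal", "failure")
  for (k in 1:200) {
    gold_n <- sample(0:3, 1)
    model_n <- sample(0:3, 1)
    mk <- function(n) {
      if (n == 0) return(answers_tbl())
      answers_tbl(
        vapply(seq_len(n), function(i) {
          paste(sample(vocab, sample(1:3, 1), replace = TRUE), collapse = " ")
        }, character(1)),
        sample(0:500, n))
    }
    g <- mk(gold_n); m <- mk(model_n)
    counts <- score_question(g, m)
    if (gold_n == 0) {
      # sentinel conventions: empty gold carries one token of mass
      expect_equal(counts[["wTP"]] + counts[["wFN"]], 1)
    } else {
      # dedup by normalized key first, as score_question does
      keys <- unique(vapply(g$text, function(t)
        paste(normalize_tokens(t), collapse = " "), character(1)))
      mass <- sum(lengths(lapply(keys, function(k)
        strsplit(k, " ")[[1]][nzchar(strsplit(k, " ")[[1]])])))
      expect_equal(counts[["wTP"]] + counts[["wFN"]], mass)
    }
    # metrics bounded in [0, 1]
    p <- if (counts[["wTP"]] + counts[["wFP"]] > 0)
      counts[["wTP"]] / (counts[["wTP"]] + counts[["wFP"]]) else 0
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("the exhaustive oracle agrees with the implementation", {
  cases <- list(
    list(answers_tbl("leg edema", 0), answers_tbl("edema", 4)),
    list(answers_tbl(), answers_tbl()),
    list(answers_tbl(c("pain", "fever"), c(0, 9)),
         answers_tbl(c("fever", "pain"), c(9, 0))),
    list(answers_tbl(), answers_tbl("pain", 3)),
    list(answers_tbl("pain", 3), answers_tbl()),
    list(answers_tbl("leg edema", 7), answers_tbl("leg edema", 7)))
  for (cs in cases) {
    expect_equal(score_question(cs[[1]], cs[[2]]),
                 brute_force_oracle(cs[[1]], cs[[2]]))
  }
  expect_error(brute_force_oracle(answers_tbl(letters[1:7], 1:7),
                                  answers_tbl()), "capped")
})

test_that("evaluating predictions attaches gold-side slice labels", {
  corpus <- generate_corpus(generator_config(
    categories = c(one_drug_no_reason = 2, one_to_one = 4, one_to_n = 2,
                   n_to_one = 1, m_to_n = 1), seed = 53))
  entries <- build_qa_dataset(corpus$annotations, qa_config("combined_only"))
  res <- extract_multi_answers(pattern_baseline(), entries, corpus$documents)
  rep <- evaluate_predictions(entries, res$predictions)
  s <- rep$slices
  full_n <- s$n_questions[s$slice == "full"]
  unans <- s$n_questions[s$slice == "unanswerable"]
  expect_equal(s$n_questions[s$slice == "single_answer"] +
                 s$n_questions[s$slice == "multi_answer"], full_n - unans)
  expect_equal(s$n_questions[s$slice == "single_drug"] +
                 s$n_questions[s$slice == "multi_drug"], full_n - unans)
  expect_true(all(s$f1 >= 0 & s$f1 <= 1))
  # a missing prediction is an abstention, with a warning
  expect_warning(evaluate_predictions(entries, res$predictions[-1]),
                 "abstention")
})
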