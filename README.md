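# rxwhyqa

Clinical notes routinely document *why* a medication was prescribed, and
extracting that justification is a natural extractive question-answering
(EQA) task: given "Why was morphine prescribed to the patient?" and the note
text, return the literal span ("pain") that answers it. Realistic clinical
EQA is messier than the classic one-answer-per-document setting — a single
question can have several correct spans scattered through a note
(multi-answer), one question can ask about several drugs at once
(multi-focus, "Why were amlodipine, metoprolol, and isosorbide
prescribed…?"), and many questions have no documented answer at all.

`rxwhyqa` is an R toolkit for building, analyzing, answering, and scoring
such corpora. It is aimed at clinical-NLP researchers who have (or want to
emulate) drug–reason relation annotations in the BRAT standoff style, and
provides:

- **annotation I/O** — parse/write `<id>.txt`/`<id>.ann` standoff pairs
  (`T` mention lines with discontinuous spans, `R` relation lines), with
  structural validation (`read_brat_standoff()`, `validate_annotation_set()`);
- **QA construction** — group drug–reason relations into the five canonical
  categories (1 drug/no reason, 1-to-1, 1-to-N, N-to-1, M-to-N) and emit
  SQuAD-2.0-style entries with unanswerable, multi-answer and multidrug
  questions (`build_qa_entries()`, `write_squad()`, `split_documents()`);
- **corpus analytics** — unique-answer distributions, drug and drug–reason
  pair frequencies, drug↔reason sentence distances, contextual trigger
  patterns ("Drug … prn Reason"), and an exact-match on/off-label screen
  (`corpus_stats_report()`, `match_context_patterns()`, `off_label_screen()`);
- **a synthetic generator** — seeded notes with planted relation structure
  and a ground-truth manifest, standing in for DUA-restricted clinical text
  (`generate_corpus()`);
- **an incremental masking driver** — the loop that makes any *single*-answer
  EQA model produce *multiple* answers: record the top answer, mask every
  occurrence with same-length `_` runs, re-ask, stop when nothing new
  appears (`extract_multi_answers()`, `termination_certificate()`);
- **M-to-N evaluation** — weighted token-overlap precision/recall/F1 with
  per-slice reports (`score_question()`, `evaluate_predictions()`).

## The scoring model

For one question with gold answers $G$ and model answers $M$ (each a set of
spans, deduplicated by normalized string), let $\mathrm{tok}(\cdot)$ be the
normalized token multiset (lowercase, punctuation stripped, articles
dropped). Anchoring on each gold answer $g$, the model answer
$m^\* = \arg\max_{m \in M} |\mathrm{tok}(g) \cap \mathrm{tok}(m)|$ sets

$$\mathrm{wTP} \mathrel{+}= |\mathrm{tok}(g) \cap \mathrm{tok}(m^\*)|,\qquad
  \mathrm{wFN} \mathrel{+}= |\mathrm{tok}(g)| - |\mathrm{tok}(g) \cap \mathrm{tok}(m^\*)|,$$

and vice versa, anchoring on each model answer $m$,
$\mathrm{wFP} \mathrel{+}= |\mathrm{tok}(m)| - |\mathrm{tok}(m) \cap \mathrm{tok}(g^\*)|$.
Counts are pooled over the question set (micro), then
$P = \mathrm{wTP}/(\mathrm{wTP}+\mathrm{wFP})$,
$R = \mathrm{wTP}/(\mathrm{wTP}+\mathrm{wFN})$, $F_1 = 2PR/(P+R)$. A
correctly-unanswered question contributes one sentinel true-positive token.
An independent brute-force oracle (`brute_force_oracle()`) re-derives the
same counts by exhaustive enumeration and backs the property tests.

## Worked example

```r
library(rxwhyqa)

txt <- "The patient received morphine for pain as needed"
ann <- "T1\tDrug 21 29\tmorphine\nT2\tReason 34 38\tpain\nR1\tReason-Drug Arg1:T1 Arg2:T2"
a <- read_brat_standoff(txt, ann, "note-1")
e <- build_qa_entries(a)
e$question
#> [1] "Why was morphine prescribed to the patient?"
e$answers[[1]]
#> # A tibble: 1 x 2
#>   text  answer_start
#>   <chr>        <int>
#> 1 pain            34

ans <- pattern_baseline_answer(e$question, e$drug_names[[1]],
                               "received morphine for pain as needed")
ans$text; ans$answer_start
#> [1] "pain"
#> [1] 22
```

The question was generated from the annotated drug, the gold answer span
carries its character offset into the note, and the rule-based baseline
recovered the same span from the raw text via the "Drug … for … Reason"
trigger family.

A full pipeline on a synthetic corpus, via the CLI (`exec/rxwhyqa`,
installed into the package's `exec/` directory):

```sh
rxwhyqa synth  --out corpus/ --seed 5
rxwhyqa build  --notes corpus/ --out squad.json
rxwhyqa answer --squad squad.json --out preds.json
rxwhyqa eval   --squad squad.json --pred preds.json --out report.json
#> F1 = 0.8205 (precision 0.9057, recall 0.7500); report in report.json
```

The default generator plants long-distance and list-style relations the
pattern baseline cannot always resolve, hence F1 < 1; on the pattern-exact
regime (`pattern_pure_config()`) the pipeline scores exactly 1.0.

## Scope

The toolkit deliberately does not ship or require the DUA-restricted source
corpus, does not fine-tune transformer models (an adapter can implement the
answerer contract), and replaces the full medication–indication knowledge
base with a pluggable two-column lookup. See the methods vignette
(`vignettes/rxwhyqa-methods.Rmd`) for the design rationale and limitations.
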