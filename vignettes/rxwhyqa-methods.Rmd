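---
title: "Methods: building and scoring multi-answer drug-reason QA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and scoring multi-answer drug-reason QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxwhyqa)
```

## The problem

Drug-reason relation annotations link a medication mention to the documented
indication for prescribing it, both as character-offset spans in a clinical
note. `rxwhyqa` recasts such annotations as extractive question answering:
each drug (or group of drugs) becomes a why-question, each linked reason
span becomes a gold answer, and drugs without any linked reason become
unanswerable questions. The result is a SQuAD-2.0-compatible corpus that
deliberately keeps three realistic complications most EQA corpora remove:
multiple answers per question, multiple drugs per question, and questions
with no answer.

## From relations to questions

Within one document, drug identity is the lowercased surface string; no
brand/generic or spelling merging is attempted, because anything stronger
requires a drug lexicon and the corpus conventions do not assume one. Every
distinct drug term yields one single-drug group holding all reason mentions
linked to any of its mentions. Groups are categorized by cardinality:
`ONE_DRUG_NO_REASON`, `ONE_TO_ONE`, `ONE_TO_N` (two or more distinct
normalized reason strings), plus combined multidrug groups — maximal sets of
two or more drug terms whose distinct reason-string sets are identical and
nonempty (`N_TO_ONE` with one shared reason, `M_TO_N` otherwise).

Two conversion conventions coexist in the field for N-drugs-one-reason
structures: breaking them into N separate 1-to-1 entries, and preserving a
single combined multidrug question. Both are legitimate — large 1-to-1
counts and hundreds of multidrug questions coexist in the released corpus —
so the builder exposes `multidrug_mode` with default `"both"` (emit the
split entries *and* the combined entry), plus `"split_only"` and
`"combined_only"` for either pure convention. `"combined_only"` suppresses
split entries only for drugs that belong to some multidrug group.

Other fixed choices:

* **Answers.** One answer span per linked reason *mention* — duplicate
  answer strings at distinct offsets are retained, because the repeated
  occurrences are real evidence an EQA system may exploit. Discontinuous
  reason mentions are flattened to their longest contiguous fragment, since
  SQuAD answers must be contiguous spans; the dropped fragments remain in
  the annotation layer.
* **Questions.** Templates are singular/plural pairs with a `{drugs}` slot;
  the canonical pair is "Why was/were {drugs} prescribed to the patient?"
  with multi-drug lists rendered "a, b, and c". Paraphrase sets are a plain
  editable TSV; one entry is emitted per template, canonical first, so entry
  counts are always (groups emitted) x (templates).
* **Identifiers.** `qa_id = "<doc_id>::<drug terms joined by '+'>::t<k>"` —
  deterministic and human-debuggable; identical inputs give byte-identical
  output files.
* **Offsets.** 0-based, half-open, unicode characters, after normalizing
  line endings to `"\n"` — mixed line endings silently shift offsets
  otherwise. The on-disk annotation dialect is BRAT standoff, the
  distribution convention for this kind of relation corpus.

Document-level train/dev/test splitting uses largest-remainder
apportionment of the (normalized) ratios with a seeded shuffle. For 303
documents at 5:2:3 the quotas are 151.5/60.6/90.9, so the two leftover
seats go to the largest fractional remainders, giving 151/61/91.

## Corpus analytics

* **Unique answers per question** are counted on distinct lowercased answer
  strings and bucketed 1/2/3/>=4; percentages are rounded half away from
  zero (the reporting convention used throughout; base R rounds half to
  even, which would mis-reproduce published percentage tables).
* **Frequencies** are entry-denominated (number of QA entries mentioning
  the term or pair), not mention-denominated.
* **Sentence distance** between a question's drug and its reasons is the
  minimum over all drug-mention x reason-mention pairs of the absolute
  sentence-index difference; 0 means some pair shares a sentence. The
  default splitter is rule-based (break on newline, and on `.?!` followed
  by whitespace and an uppercase/numeric character) and pluggable, since no
  segmenter is canonical for clinical text.
* **Trigger patterns.** Four trigger families commonly observed around
  drug-reason pairs (e.g. `Drug … [prn|PRN|(as needed for)?] Reason`,
  `Reason … (was)? [managed|treated|…] with Drug`) are compiled to
  case-insensitive regular expressions with bounded ellipses (default gap
  limit 12 words — generous for within-sentence cues while excluding
  cross-paragraph accidents) and priority weights given by their observed
  frequencies. Because no exemplar sentences are published alongside the
  pattern shorthand, each compiled family ships with a *synthetic* exemplar
  constructed from its own elements, and a self-coverage check asserts all
  four match.
* **Off-label screening** is an exact lowercased (drug, reason) lookup in a
  pluggable two-column table; everything not found is "unknown" — a
  candidate for human review, not a verdict. The shipped
  `indications_kb.tsv` is a toy lookup for tests and examples, not a
  clinical resource. Rates are reported to one decimal.

## The synthetic generator

Real clinical corpora of this kind are DUA-restricted, so the package
treats its generator as first-class: seeded synthetic notes with planted
structure and a ground-truth manifest that downstream stages must recover
exactly. One relation group is planted per document. Defaults follow the
structure reported for the corpus this toolkit emulates: the
sentence-distance histogram concentrates at 0 (72%) and 1 (18%) with a thin
tail; lexicons are seeded from its frequent terms (coumadin, vancomycin,
lasix, acetaminophen, senna, oxycodone; pain, constipation, fever, afib,
sob, wheeze, …); a 15% duplicate-answer rate plants repeated answer
mentions; a 25% distractor rate appends neutral dose-line sentences naming
unrelated drugs, to exercise false-positive behavior.

Gap-0 relations are realized by one sampled trigger family in a single
sentence. Gap-k relations put the annotated reason k sentences before a
drug sentence whose reason slot holds an anaphor ("X was given for this."),
separated by neutral fillers — the pattern baseline cannot resolve these,
which is intended: long-distance pairs *should* be hard for a
surface-pattern system. All randomness flows through one seed; equal seeds
give byte-identical corpora.

`pattern_pure_config()` is the calibrated exact regime: gap 0 everywhere,
single-token reasons, one relation per document, no duplicates or
distractors, substring-free lexicons, plus a few drug-only documents for
abstention. On it, the pattern baseline answers every answerable question
and refrains on every unanswerable one by construction, so the full
pipeline must score F1 = 1.0 — any deviation is a defect, not noise.

What the generator does *not* emulate: section structure, abbreviations and
misspellings, negation, overlapping mentions, multi-token reason
paraphrases, PHI. Passing manifest-recovery tests therefore demonstrates
correctness of the machinery on controlled structure, not performance on
real notes.

## Answerers and the masking loop

Any single-answer EQA model enters through one contract:
`f(question, drug_names, context, no_answer_threshold, qa_id)` returning
`NULL` (refrain) or one offset-faithful span with a score. The drug anchor
comes from the entry's `_mname` payload rather than re-parsing the question
— the field exists precisely to avoid that fragility. The package ships a
rule-based pattern baseline (no training), a scripted mock that makes loop
tests exact and fails loudly on unscripted calls, and a calibration routine
that picks the no-answer threshold maximizing dev-set F1, breaking ties
toward the more conservative (larger) value. Transformer fine-tuning is out
of scope; an adapter implementing the contract can be dropped in.

The baseline captures the reason slot as the contiguous run of content
tokens adjacent to the matched trigger (forward for drug-first families,
backward for reason-first), at most 6 tokens, trimmed of stopwords and
punctuation and stopped at sentence boundaries. The stopword list is a
small fixed set (articles, be-verbs, prepositions, conjunctions, anaphors,
"patient") shipped as data. Captures consisting only of mask characters are
discarded. Scores are the pattern priority weights; ties break to the
earliest offset.

The masking loop forces multiple answers out of a single-answer model:
record the top answer; replace every case-insensitive occurrence in that
question's working context with `_` runs of identical length; re-ask;
repeat until a full round yields nothing new (or a safety cap of 10
rounds, present because an adversarial answerer could otherwise cycle —
well above the deepest answer multiplicity the generator plants). Three
deliberate interpretations:

* **Masking is per-question.** One document serves many questions;
  masking answers of one question in a shared copy would corrupt other
  questions' evidence.
* **Novelty is string identity** on lowercased, whitespace-collapsed
  answers — the minimal reading of "no new answers"; anything stronger
  (synonymy) would need resources the loop does not have.
* **Mask-only answers** (a model "clinging" to the `______` span) are
  excluded from recorded answers but freeze that question's loop,
  preventing infinite cycling; a flag can retain them for replication
  studies.

Because masking preserves length, every recorded offset is valid in the
original text, and each productive round masks at least one previously
unmasked character — the machine-checkable termination argument that
`termination_certificate()` verifies on every run.

## Evaluation

Scoring M gold against N model answers uses anchored weighted token
overlap (see the README for the formulas). Choices that were genuinely
open:

* **Tokenization** follows the SQuAD evaluation convention (lowercase,
  strip punctuation, drop articles), since the corpus format is
  SQuAD-2.0-compatible; it is configurable.
* **Ties** in the argmax go to the model answer at the smaller original
  offset, making scores invariant to answer-list order.
* **Deduplication** by normalized string precedes scoring: duplicate
  offsets of the same string carry no extra token content. A flag disables
  it for sensitivity analysis.
* **Abstention** is scored with a one-token sentinel (both sides empty:
  +1 wTP; spurious answer against empty gold: +1 wFN plus all model tokens
  as wFP), so unanswerable questions contribute to pooled counts and the
  unanswerable slice is well defined.
* **Pooling is micro** (counts summed over questions, then P/R/F1), the
  reading consistent with tallying weighted matches over a whole test set;
  macro averaging is available behind a flag.

Reports cover the full set and the standard slices — unanswerable,
single-/multi-answer, single-/multi-drug — with empty slices absent rather
than zero. `brute_force_oracle()` re-derives every count by exhaustive
enumeration with independent token matching and is held equal to the
implementation on randomized instances in the test suite.

## Numerical conventions and problem sizes

Percentages round half away from zero (integers for distributions, one
decimal for pooled review rates). Test and acceptance runs use small
problem sizes chosen to exercise every category while keeping the suite
quick: the mixed-category manifest-recovery corpus plants 10/20/5/3/2
groups across 40 documents, the pattern-exact corpus uses 12 answerable
plus 4 unanswerable documents, splitting demonstrations use 303 documents,
and oracle equivalence draws 1000 randomized answer-set instances.

## Known limitations

* The pattern baseline is surface-level: it cannot resolve long-distance
  or heavily paraphrased reasons, and its reason captures are at most 6
  tokens.
* Drug identity by lowercased string means "ASA" and "aspirin" are
  different drugs to the builder.
* The off-label screen's "unknown" bucket conflates true off-label use with
  knowledge-base gaps; it ranks candidates for review, nothing more.
* The corpus summary tables shipped under `inst/extdata/reported/` describe
  the released corpus this package emulates; they are inputs for
  arithmetic, and none of the package's own results depend on them.
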