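---
title: "Extract-then-phenotype: concept-based PPH phenotyping from discharge summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extract-then-phenotype: concept-based PPH phenotyping from discharge summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pphnlp)
```

## The problem

Postpartum hemorrhage (PPH) — excessive bleeding after childbirth — is the
leading cause of severe maternal morbidity. Large studies usually identify
PPH from claims data (ICD diagnosis codes), but coding is incomplete: many
deliveries whose documented blood loss clearly meets the clinical definition
carry no PPH code at all. The clinically decisive information — the
estimated blood loss (EBL), the delivery mode, the interventions performed —
lives in the free text of the discharge summary.

`pphnlp` implements an *extract-then-phenotype* design. Rather than training
a classifier end to end, the pipeline first extracts 24 granular, auditable
clinical concepts from each note (23 binary concepts such as *uterine
atony*, *Bakri balloon*, *fresh frozen plasma*, plus the numeric *estimated
blood loss*), and then applies transparent rule engines on top of the
extracted concepts:

* **Phenotype**: a delivery is PPH when the summed extracted EBL exceeds
  500 mL (vaginal) or 1000 mL (cesarean), strictly — the definition in
  clinical use before 2018. The post-2018 consensus definition (> 1000 mL
  regardless of mode) is available as `rule_preset("acog2017")`; because the
  phenotype is computed from stored concepts, re-thresholding requires no
  re-extraction.
* **Subtype**: the four T's of PPH etiology — Tone, Tissue, Trauma,
  Thrombin — each defined as a disjunction over extracted concepts, with an
  ICD-9 code-family baseline for comparison.

Every decision is traceable to the concept calls (and through them to the
chunk-level responses) that produced it; that interpretability is the point
of the two-step design.

## Extraction model

Each concept carries an ordered list of *prompt templates* written for an
instruction-tuned text-to-text model ("Answer the following yes/no question.
Does the following discharge summary mention X during the current delivery?
note: `<note>`") and a set of case-insensitive regular expressions. Backends
are pluggable behind one contract — a function from (rendered prompt, call
context) to a short generated text:

* `pattern_backend()` — answers from the concept's regular expressions;
  deterministic, runs anywhere, and doubles as the regex baseline that
  concept-level evaluations compare against.
* `mock_backend()` — replays planted truth with an optional per-call flip
  probability; the test double for noise experiments.
* `generative_backend()` — an adapter for an external large-language-model
  serving endpoint. The caller supplies the `generate_fn` wrapping their
  server; the adapter forwards greedy decoding, `max_new_tokens = 5`, and
  `temperature = 1.0` from the extraction config. No model ships with the
  package and nothing in the test suite requires one.

Notes routinely exceed a model context window, so extraction is
chunk-and-aggregate: the note is tokenized (whitespace-plus-punctuation by
default; the tokenizer is a pluggable contract so a model's own subword
tokenizer can be substituted), split into windows of `window_tokens = 512`
with `overlap_tokens = 128` (step 384), and each (chunk × prompt) pair is
queried. A binary concept is positive if *any* chunk under *any* of its
chained prompts parses positive; the measurement concept takes the *union*
of extracted segments, dropping the `"unanswerable"` fallback token. We read
the windowing parameter "stride" as the *overlap* between consecutive
windows, the dominant convention in the sliding-window ecosystems these
models come from; readers who prefer the step-size reading can set
`extraction_config(window_tokens = 512, overlap_tokens = 384)`.

Two parsing conventions are deliberately conservative: a yes/no response
that parses to neither yes nor no counts as *negative* (never inflating
positives), and a backend failure on any chunk is a hard error rather than
missing data — phenotyping on silently partial extractions would be unsafe.

The overlap also carries a correctness guarantee exercised by the tests: a
concept phrase shorter than the overlap can never be split across chunk
boundaries in a way that hides it from every chunk.

## EBL normalization

Clinicians write blood loss as "800 cc", "EBL: 1.5 L", bare numbers, or
corrupted concatenations like `500ccf/b`. The EBL module:

1. parses every maximal numeric token in each extracted segment, sniffing an
   adjoining unit (ml/cc/l and long forms, possibly concatenated — a bare
   "l" is only accepted when not followed by another letter, so "lbs" never
   reads as liters);
2. normalizes to mL: liters × 1000; a *unit-less* value below 10 is read as
   liters (no plausible delivery loss is under 10 mL and none is over 10 L,
   so the boundary is safe for decimals like "1.5" as well as literal single
   digits); 10 and above is assumed mL. Note this rule is intentionally
   non-monotone across the 10 boundary for unit-less values — 9.9 reads as
   9900 mL while 10 reads as 10 mL — because the two sides are different
   interpretations, not one scale;
3. collapses equal normalized values before summing: repeated equal values
   in a note (or across the notes of one delivery) are taken to restate the
   same loss, not to describe separate events. Numeric ranges ("400-600")
   keep both endpoints, a conservative choice since the two values carry
   distinct information.

## Delivery grouping and mode

The mapping from notes to deliveries is not observable in the data model, so
`group_notes()` chains a patient's notes whose dates are within
`max_gap_days = 7` of each other; deliveries are months apart, so any small
gap separates encounters cleanly. Callers with a trusted delivery identifier
can bypass grouping entirely (`assess_deliveries(groups = ...)`). Delivery
mode is cesarean iff the `cesarean_delivery` concept is positive on any note
of the group, vaginal otherwise; EBL de-duplication applies across the whole
group because a second (addendum) note typically restates the same loss.

## Subtyping rules

A delivery may carry several subtypes (multi-label):

| Subtype | NLP triggers | ICD-9 baseline |
|---|---|---|
| Tone | uterine atony; methylergonovine; carboprost; misoprostol as uterotonic | 666.1x |
| Tissue | accreta spectrum; retained products; D&C; manual extraction | 666.0x |
| Trauma | uterine rupture; O'Leary sutures; surgical-cause PPH; laceration *(guarded)* | 665.x, or 664.x if no 666.x |
| Thrombin | coagulation disorders (DIC); platelets; cryoprecipitate; FFP in ratio > 1:1:1 with red cells | 666.3x |

The *laceration guard* reflects the clinical reality that lacerations are
routine in delivery: laceration alone signifies traumatic hemorrhage only
when no other subtype trigger (including the other trauma triggers) is
present. The guard is evaluated after every other trigger.

The thrombin rule references an FFP:RBC unit ratio, but extraction yields a
binary FFP concept. Default behavior is faithful to the printed definition
while honest about the missing counts: FFP qualifies only when
`transfusion_counts` are supplied with `ffp_units > rbc_units`; without
counts, FFP alone does not trigger thrombin (DIC, platelets and
cryoprecipitate still do) and the skipped check is recorded on the result. A
permissive mode (`ffp_alone_qualifies = TRUE`) is one switch away.

ICD wildcard matching is literal: in `666.1x` each trailing `x` matches one
digit, and a code may extend past the pattern only through a trailing
wildcard — `666.1x` matches `666.14` and `666.145` but not `666.1`.

## The synthetic generator, and what passing tests do and do not show

The clinical notes this kind of pipeline targets contain protected health
information and cannot ship with software. The package therefore includes a
first-class generator of synthetic obstetric discharge summaries,
`generate_corpus()`, which is the test substrate for every other module.
Its defaults are fixed study conditions, chosen once:

* per-concept prevalences follow the relative frequencies of the concepts in
  a PPH-enriched annotated note cohort (e.g. laceration 0.36, direct PPH
  mention 0.31, O'Leary sutures 0.01);
* cesarean rate 0.32 (a typical U.S. figure); PPH rate 0.10; 30% of non-PPH
  deliveries document no EBL;
* 15% of deliveries emit a second addendum note 0–3 days later restating the
  same EBL — matching a notes-to-deliveries ratio of about 1.15 and
  exercising the cross-note de-duplication path;
* EBL surface formats are drawn from a weighted mix of "`v` mL", "`v`cc",
  "`v/1000` L", bare numbers, bare single-digit liters, and concatenated
  corruptions ("`v`ccs/p");
* optional noise: word-level misspellings (rate 0.05), clinical abbreviation
  substitutions ("dilation and curettage" → "d&c", rate 0.10), and polysemy
  distractors (rate 0.10) such as "artificial rupture of membranes" (which
  must never fire the uterine-rupture concept) and "misoprostol for cervical
  ripening" (which must never fire the uterotonic-misoprostol concept).

In *clean mode* (noise rates 0) every planted phrase is drawn from surface
forms the registry patterns provably match, and no phrase or scaffold
sentence matches any other concept's patterns. That property — checked by a
dedicated test — is what licenses the generator as an oracle: on a clean
corpus the pattern backend must recover every planted concept and every
planted EBL value exactly, and end-to-end agreement with planted truth is
asserted per delivery, not on average.

What passing these tests shows: the chunking, aggregation, normalization,
grouping, phenotype and subtype logic are correct, and the whole chain is
deterministic and reproducible. What it does not show: performance on real
clinical prose. The generator targets structural fidelity (formats,
variants, traps), not linguistic fluency; real notes contain negation,
templated boilerplate, copy-forward text and institutional idiosyncrasies
that no synthetic corpus represents. Concept-level performance claims on
real data require chart-review validation with the evaluation module.

## Numerical and statistical choices

* **Strict thresholds.** The phenotype comparison is strictly greater-than:
  exactly 500 mL vaginal or exactly 1000 mL cesarean is not PPH. Boundary
  tests pin 500/501 and 1000/1001.
* **Undefined metrics are flagged, never zeroed.** With no predicted
  positives, PPV is `NA` and named in `undefined`; silently coercing to 0
  would corrupt averages.
* **McNemar variant.** `mcnemar(mode = "auto")` uses the exact two-sided
  binomial test when the discordant count is below 25 and the
  continuity-corrected chi-square otherwise — standard practice when the
  variant is unspecified; both are callable explicitly, and the tests check
  the exact mode against direct binomial tail sums and the chi-square mode
  against `stats::mcnemar.test()`.
* **EBL note-level accuracy** is exact set equality of normalized values
  (both sets possibly empty). Total-EBL equality is a reasonable alternative
  reading; set equality is stricter and is the one implemented.
* **Degenerate inputs.** An empty note yields no chunks (not one empty
  chunk); an empty corpus cleans to an empty corpus; zero PPH-positive
  deliveries yield an empty prevalence table with a warning; zero discordant
  pairs give McNemar p = 1.
* **Tie-breaks.** De-duplication keeps the earliest note (ties broken by
  note id); grouping sorts by date then note id, so results are independent
  of input order.

## Problem sizes in the test suite

The default suite validates the subtype engine exhaustively (all 2^15
combinations of the 15 unconditional subtype flags, plus the 2^12 grid over
the tone/tissue/trauma flags and all 2^10 subsets of a 10-code ICD
universe), the EBL parser on 30+ format fixtures and 1000 random mention
lists against a set-then-sum oracle, chunking on three window shapes over
random lengths up to 2000 tokens, and the full pipeline on clean synthetic
corpora of 500 notes (plus 2000 notes for prevalence recovery and 1000-note
mock-noise experiments). These sizes give exhaustive coverage where the
state space is finite and tight binomial bounds elsewhere.

## Known limitations

* The registry's regular expressions are authored pattern sets covering
  canonical names, common abbreviations and frequent variants; they are a
  baseline and a test instrument, not a validated clinical NLP system.
* No negation handling: "no evidence of uterine atony" would match the
  atony pattern. The prompt-based route is the intended remedy on real
  data; on the synthetic corpus the issue does not arise by construction.
* Secondary/delayed PPH is out of scope — the pipeline analyzes delivery
  discharge summaries only.
* The ICD inclusion/exclusion lists for delivery identification and the PPH
  code sets used in the EBL-by-ICD cross-tabulation are institution- and
  study-specific; the package ships documented placeholders and expects
  curated lists via configuration.
* ICD-10 is carried as a vocabulary tag but the subtype baseline operates on
  ICD-9 code families; mapping ICD-10 to ICD-9 is the caller's
  responsibility.

## A worked example

```{r example, eval = FALSE}
library(pphnlp)

# 200 synthetic notes, clean mode, fixed seed
syn <- generate_corpus(synth_config(n_notes = 200, misspell_rate = 0,
                                    abbrev_rate = 0, distractor_rate = 0,
                                    seed = 42))
reg <- builtin_registry()
calls <- extract_corpus(syn$notes, reg, pattern_backend(reg))

# deliveries, phenotype, subtypes
ass <- assess_deliveries(syn$notes, calls)
mean(ass$pph)
subtype_prevalence(subtype_deliveries(ass[ass$pph, ], "nlp"))

# concept-level validation against the gold labels
concept_report(calls, syn$gold, reg)
```
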