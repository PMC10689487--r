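# pphnlp

Concept-based phenotyping of **postpartum hemorrhage (PPH)** from obstetric
discharge summaries, for clinical-NLP and EHR-phenotyping researchers.

Claims codes miss a large share of PPH cases, while the decisive facts — the
estimated blood loss (EBL), the delivery mode, the interventions performed —
sit in free text. `pphnlp` implements an *extract-then-phenotype* pipeline:

1. **Extract** 24 granular PPH-related concepts per note (23 binary —
   e.g. *uterine atony*, *Bakri balloon*, *fresh frozen plasma* — plus the
   numeric *estimated blood loss*) by chunked zero-shot prompting. Notes are
   split into 512-token windows with a 128-token overlap; a binary concept
   is positive if **any** chunk under **any** of its chained prompts answers
   yes, and EBL extraction takes the **union** of segments across chunks.
   Backends are pluggable: a deterministic regular-expression backend, a
   mock backend for noise experiments, and an adapter for an external
   instruction-tuned LLM endpoint (greedy decoding, `max_new_tokens = 5`,
   temperature 1.0).
2. **Normalize EBL**: parse numeric mentions in heterogeneous formats
   ("800 cc", "EBL 1.5 L", bare numbers, corrupted concatenations like
   `500ccf/b`), convert to mL (unit-less values below 10 read as liters),
   and de-duplicate equal values before summing.
3. **Phenotype**: a delivery is PPH when total extracted EBL is
   **> 500 mL (vaginal)** or **> 1000 mL (cesarean)** — strict comparisons;
   the post-2018 definition (> 1000 mL regardless of mode) is one preset
   away (`rule_preset("acog2017")`).
4. **Subtype** PPH deliveries into the four T's (multi-label):
   **Tone** (atony, uterotonics), **Tissue** (accreta spectrum, retained
   products, D&C, manual extraction), **Trauma** (uterine rupture, O'Leary
   sutures, surgical causes, laceration *only when no other subtype
   applies*), **Thrombin** (DIC, platelets, cryoprecipitate, FFP:RBC ratio
   above 1:1:1) — with an ICD-9 code-family baseline (`666.1x`, `666.0x`,
   `665.x`/`664.x`-guarded, `666.3x`).
5. **Evaluate**: sensitivity/specificity/PPV/binary-F1/accuracy per concept,
   pooled value-set metrics for EBL, McNemar paired tests (exact or
   continuity-corrected chi-square), and an EBL-by-ICD cross-tabulation.

Because real obstetric notes cannot be shared, the package ships a
first-class **synthetic note generator** with planted truth, gold labels,
corruption operators (misspellings, clinical abbreviations) and polysemy
distractors ("artificial rupture of membranes") — the offline test substrate
for the whole pipeline. See `vignette source in vignettes/pph-phenotyping.Rmd`
for the methods account.

## Worked example

```r
library(pphnlp)

# 200 synthetic notes, clean mode (no corruption), fixed seed
syn   <- generate_corpus(synth_config(n_notes = 200, misspell_rate = 0,
                                      abbrev_rate = 0, distractor_rate = 0,
                                      seed = 42))
reg   <- builtin_registry()
calls <- extract_corpus(syn$notes, reg, pattern_backend(reg))

ass <- assess_deliveries(syn$notes, calls)
nrow(ass); sum(ass$pph)
#> [1] 180
#> [1] 18        # 10% of deliveries meet the blood-loss definition

subtype_prevalence(subtype_deliveries(ass[ass$pph, ], "nlp"))
#>   subtype  count fraction
#> 1 tone         5    0.278
#> 2 tissue       3    0.167
#> 3 trauma       5    0.278
#> 4 thrombin     5    0.278

concept_report(calls, syn$gold, reg)[1:5, c("concept_id", "n", "sensitivity", "ppv")]
#>   concept_id            n     sensitivity   ppv
#> 1 abruption             9               1     1
#> 2 accreta_spectrum      5               1     1
#> 3 bakri_balloon         5               1     1
#> 4 carboprost           10               1     1
#> 5 cesarean_delivery    67               1     1
```

The 180 deliveries come from 200 notes (some deliveries emit a second
addendum note; EBL restated across notes de-duplicates rather than
double-counting). On a clean corpus the pattern backend recovers every
planted concept, so sensitivity and PPV are 1 for every concept — that exact
recovery is what qualifies the generator as an oracle for the end-to-end
tests. EBL normalization is direct to inspect:

```r
summarize_ebl(parse_ebl_mentions(c("EBL 1.5 L", "1500 cc", "300 ml")))
#> <ebl> values: {300, 1500} mL, total 1800 mL   # 1.5 L == 1500 cc collapses
```

A thin command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/pph.R", package = "pphnlp"))') \
  synth --n-notes 200 --seed 7 --clean --out-dir corpus/
Rscript $(Rscript -e 'cat(system.file("cli/pph.R", package = "pphnlp"))') \
  run --notes corpus/notes.jsonl --gold corpus/gold.jsonl --out-dir run/
```

`run/` then holds `calls.jsonl`, `deliveries.jsonl`, `subtypes.jsonl`,
`report.csv`, and a `manifest.json` whose digests are byte-identical across
reruns of the same configuration.

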