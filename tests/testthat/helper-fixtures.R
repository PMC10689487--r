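# Shared fixtures built in code.

make_note <- function(id = "n1", patient = "p1", date = "2010-03-01",
                      text = "She had a normal spontaneous vaginal delivery.",
                      status = "final", department = "obstetrics") {
  note_record(id, patient, date, hospital = "h1", status = status,
              department = department, text = text)
}

# A corpus of short single-chunk notes with known per-note concept truth,
# for mock-backend experiments.
make_mock_truth <- function(n, concept_ids, positive_rate = 1, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(note_id = sprintf("m%04d", seq_len(n)),
                      concept_id = concept_ids, stringsAsFactors = FALSE)
  rows$label <- runif(nrow(rows)) < positive_rate
  rows
}

clean_synth <- function(n_notes, seed, ...) {
  generate_corpus(synth_config(n_notes = n_notes, misspell_rate = 0,
                               abbrev_rate = 0, distractor_rate = 0,
                               seed = seed, ...))
}

# Independent truth-table oracle for the four-T subtype rule, coded directly
# from the composite definitions (kept deliberately separate from the
# package implementation).
oracle_subtype <- function(flags, ffp_qualifies = FALSE) {
  g <- function(id) isTRUE(flags[[id]])
  tone <- g("uterine_atony") || g("methylergonovine") || g("carboprost") ||
    g("misoprostol_uterotonic")
  tissue <- g("accreta_spectrum") || g("retained_products") ||
    g("dilation_curettage") || g("manual_extraction_placenta")
  thrombin <- g("coagulation_disorders") || g("platelets") ||
    g("cryoprecipitate") || (g("fresh_frozen_plasma") && ffp_qualifies)
  trauma_other <- g("uterine_rupture") || g("oleary_sutures") || g("pph_surgical")
  trauma <- trauma_other ||
    (g("laceration") && !tone && !tissue && !thrombin && !trauma_other)
  list(tone = tone, tissue = tissue, trauma = trauma, thrombin = thrombin)
}

# Brute-force ICD subtype oracle applying the code-family table literally.
oracle_icd_subtype <- function(codes) {
  fam <- function(prefix) any(startsWith(codes, prefix) &
                                nchar(codes) > nchar(prefix) &
                                grepl("^[0-9]+$", substring(codes, nchar(prefix) + 1)))
  any666 <- fam("666.")
  list(tone = fam("666.1"), tissue = fam("666.0"),
       trauma = fam("665.") || (fam("664.") && !any666),
       thrombin = fam("666.3"))
}
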