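#' @title Delivery-note identification
#' @description Not every discharge summary describes a delivery encounter.
#'   Three approaches identify delivery notes: a recall-oriented term filter,
#'   a linkage of pregnancy-related ICD/DRG codes within a day window of the
#'   note date, and a prompted filter that asks a backend chunk by chunk.
#' @name delivery_filter
NULL

#' Delivery filter configuration
#'
#' The default term list is the recall-oriented set of delivery cues; the
#' trailing space in `"labor "` is significant (it keeps "laborious" and
#' "laboratory" from matching). The inclusion/exclusion code sets for the ICD
#' window filter are institution-specific and ship only as a documented
#' placeholder (common ICD-9 delivery-outcome prefixes); callers should
#' supply their own curated list.
#'
#' @param terms Character vector of case-insensitive substrings.
#' @param window_days Day window for ICD linkage; conventionally one of
#'   0, 2, 7, 14 (other non-negative values are accepted with a warning).
#' @param inclusion_codes Character vector of dotted code prefixes that mark
#'   a pregnancy-related admission.
#' @param exclusion_codes Character vector of code prefixes that disqualify.
#' @return A list of class `pph_filter_config`.
#' @export
delivery_filter_config <- function(
    terms = c("labor ", "delivery", "l&d", "cesarean section", "c-section",
              "estimated edc", "pregnancy"),
    window_days = 7L,
    inclusion_codes = c("650", "V27", "644", "669.7"),
    exclusion_codes = character(0)) {
  stopifnot(length(terms) > 0L, window_days >= 0)
  if (!window_days %in% c(0L, 2L, 7L, 14L)) {
    warning("window_days ", window_days, " is outside the conventional set {0, 2, 7, 14}")
  }
  structure(list(terms = terms, window_days = as.integer(window_days),
                 inclusion_codes = inclusion_codes,
                 exclusion_codes = exclusion_codes),
            class = "pph_filter_config")
}

#' Term filter for delivery notes
#'
#' TRUE iff any configured term occurs as a case-insensitive substring of the
#' note text. Matching is literal (fixed strings, not regex), so the trailing
#' space in `"labor "` is honoured.
#'
#' @param note A [note_record()].
#' @param config A [delivery_filter_config()].
#' @return Logical scalar.
#' @export
term_filter <- function(note, config = delivery_filter_config()) {
  text <- tolower(note$text)
  any(vapply(tolower(config$terms), function(t) grepl(t, text, fixed = TRUE),
             logical(1)))
}

#' ICD-window filter for delivery notes
#'
#' TRUE iff the note's patient has at least one inclusion-code record and no
#' exclusion-code record dated within `window_days` of the note date
#' (inclusive on the boundary). Code prefixes match on the dotted string.
#'
#' @param note A [note_record()].
#' @param codes List of [icd_record()]s (any patients; filtered internally).
#' @param config A [delivery_filter_config()].
#' @return Logical scalar.
#' @export
icd_window_filter <- function(note, codes, config = delivery_filter_config()) {
  if (is.na(note$note_date)) stop("note ", note$note_id, " has no date")
  in_window <- function(rec) {
    if (is.na(rec$code_date)) stop("ICD record for patient ", rec$patient_id, " has no date")
    rec$patient_id == note$patient_id &&
      abs(as.numeric(rec$code_date - note$note_date)) <= config$window_days
  }
  matches_any <- function(code, prefixes) {
    any(vapply(prefixes, function(p) startsWith(code, p), logical(1)))
  }
  has_inclusion <- FALSE
  for (rec in codes) {
    if (!in_window(rec)) next
    if (matches_any(rec$code, config$exclusion_codes)) return(FALSE)
    if (matches_any(rec$code, config$inclusion_codes)) has_inclusion <- TRUE
  }
  has_inclusion
}

# Pseudo-concept handed to backends by the prompted delivery filter; the
# patterns make the pattern backend usable as a delivery classifier too.
delivery_concept <- function() {
  delivery_prompt <- prompt_template(
    paste0("Answer the following yes/no question. Does this discharge summary ",
           "note mention a woman's delivery? note: <note>"), "yes_no")
  concept_spec("delivery_note", "Delivery encounter", "binary",
               list(delivery_prompt),
               c("delivery", "delivered", "labor\\b", "cesarean", "c-section"),
               "Whether the note describes a delivery encounter.")
}

#' Prompted filter for delivery notes
#'
#' Chunks the note at the configured window (no overlap by default for this
#' screening pass), asks the backend the delivery question per chunk, and
#' returns TRUE iff any chunk parses positive.
#'
#' @param note A [note_record()].
#' @param backend A backend.
#' @param config An [extraction_config()]; default 512-token windows with no
#'   overlap.
#' @return Logical scalar.
#' @export
prompted_filter <- function(note, backend,
                            config = extraction_config(overlap_tokens = 0L)) {
  call <- run_binary_concept(note, delivery_concept(), backend, config)
  call$label
}

#' Compare delivery-identification approaches against note-level gold labels
#'
#' Applies each requested approach to every note and scores it against the
#' gold labels with the standard binary metrics plus macro F1 (mean of the
#' positive-class and negative-class F1).
#'
#' @param notes List of [note_record()]s.
#' @param gold Named logical vector: `gold[note_id]` is TRUE for delivery
#'   notes. Must cover all notes.
#' @param methods Named list of predicate functions `function(note) ->
#'   logical`; default the term filter alone.
#' @return A tibble with one row per approach: sensitivity, specificity,
#'   ppv, binary_f1, macro_f1, accuracy.
#' @export
compare_filters <- function(notes, gold,
                            methods = list(terms = function(n) term_filter(n))) {
  ids <- vapply(notes, `[[`, character(1), "note_id")
  if (!all(ids %in% names(gold))) {
    stop("gold labels missing for: ",
         paste(utils::head(setdiff(ids, names(gold))), collapse = ", "))
  }
  truth <- as.logical(gold[ids])
  rows <- lapply(names(methods), function(name) {
    pred <- vapply(notes, methods[[name]], logical(1))
    cc <- confusion_counts(pred, truth)
    m <- binary_metrics(cc)
    neg <- binary_metrics(confusion_counts(!pred, !truth))
    tibble::tibble(method = name, tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
                   sensitivity = m$sensitivity, specificity = m$specificity,
                   ppv = m$ppv, binary_f1 = m$binary_f1,
                   macro_f1 = mean(c(m$binary_f1, neg$binary_f1)),
                   accuracy = m$accuracy)
  })
  do.call(rbind, rows)
}
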