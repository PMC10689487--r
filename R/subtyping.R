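#' @title Four-T subtyping of PPH
#' @description Postpartum hemorrhage has four etiologic subtypes — Tone
#'   (uterine atony), Tissue (retained products / abnormal placentation),
#'   Trauma (lacerations, uterine rupture, surgical injury), and Thrombin
#'   (coagulopathy). A delivery may carry multiple subtypes. The NLP rule
#'   engine maps extracted concept flags to subtypes; an ICD-9 rule engine
#'   over dotted code families serves as the claims baseline.
#' @name subtyping
NULL

TONE_TRIGGERS     <- c("uterine_atony", "methylergonovine", "carboprost",
                       "misoprostol_uterotonic")
TISSUE_TRIGGERS   <- c("accreta_spectrum", "retained_products",
                       "dilation_curettage", "manual_extraction_placenta")
TRAUMA_TRIGGERS   <- c("uterine_rupture", "oleary_sutures", "pph_surgical")
THROMBIN_TRIGGERS <- c("coagulation_disorders", "platelets", "cryoprecipitate")

#' Concept ids consumed by the NLP subtype rule
#' @return Character vector of the 16 subtype-relevant concept ids.
#' @export
subtype_concepts <- function() {
  c(TONE_TRIGGERS, TISSUE_TRIGGERS, TRAUMA_TRIGGERS, "laceration",
    THROMBIN_TRIGGERS, "fresh_frozen_plasma")
}

#' NLP-based subtype classification for one delivery
#'
#' Applies the composite subtype definitions to extracted concept flags:
#' * tone — uterine atony, methylergonovine, carboprost, or misoprostol used
#'   as a uterotonic;
#' * tissue — placenta accreta spectrum, retained products of conception,
#'   dilation and curettage, or manual extraction of the placenta;
#' * thrombin — coagulation disorders (DIC), platelet or cryoprecipitate
#'   transfusion, or fresh frozen plasma in a ratio with red cells higher
#'   than 1:1:1;
#' * trauma — uterine rupture, O'Leary sutures, PPH due to surgical causes,
#'   or laceration *only when no other subtype trigger is present* (the
#'   laceration guard: lacerations are routine in delivery and only signify
#'   traumatic hemorrhage when nothing else explains the bleeding).
#'
#' The extracted FFP concept is binary, but the thrombin definition needs
#' unit counts: by default FFP qualifies only when `transfusion_counts`
#' supplies `ffp_units > rbc_units`; without counts, FFP alone does not
#' trigger thrombin (DIC, platelets, cryoprecipitate still do) and the
#' skipped check is recorded in `notes`. Set `ffp_alone_qualifies = TRUE`
#' for the permissive reading.
#'
#' @param flags Named logical vector/list covering [subtype_concepts()].
#' @param transfusion_counts Optional list with `ffp_units` and `rbc_units`.
#' @param ffp_alone_qualifies Permissive mode: a positive FFP flag triggers
#'   thrombin even without counts.
#' @return A list of class `pph_subtype`: logicals `tone`, `tissue`,
#'   `trauma`, `thrombin`; `evidence` (per-subtype triggering concept ids);
#'   `notes` (character, e.g. the skipped FFP-ratio check).
#' @export
nlp_subtype <- function(flags, transfusion_counts = NULL,
                        ffp_alone_qualifies = FALSE) {
  flags <- as.list(flags)
  missing <- setdiff(subtype_concepts(), names(flags))
  if (length(missing) > 0L) {
    stop("missing required concept flag(s): ", paste(missing, collapse = ", "))
  }
  on <- function(ids) ids[vapply(ids, function(i) isTRUE(flags[[i]]), logical(1))]

  tone_ev <- on(TONE_TRIGGERS)
  tissue_ev <- on(TISSUE_TRIGGERS)
  thrombin_ev <- on(THROMBIN_TRIGGERS)
  notes <- character(0)
  if (isTRUE(flags[["fresh_frozen_plasma"]])) {
    if (!is.null(transfusion_counts)) {
      if (transfusion_counts$ffp_units > transfusion_counts$rbc_units) {
        thrombin_ev <- c(thrombin_ev, "fresh_frozen_plasma")
      }
    } else if (ffp_alone_qualifies) {
      thrombin_ev <- c(thrombin_ev, "fresh_frozen_plasma")
    } else {
      notes <- c(notes, "ffp positive but transfusion counts unavailable; FFP:RBC ratio check skipped")
    }
  }
  trauma_ev <- on(TRAUMA_TRIGGERS)

  tone <- length(tone_ev) > 0L
  tissue <- length(tissue_ev) > 0L
  thrombin <- length(thrombin_ev) > 0L
  # Laceration guard: evaluated after every other trigger, incl. the other
  # trauma triggers — laceration counts only when no other subtype is valid.
  if (isTRUE(flags[["laceration"]]) && !tone && !tissue && !thrombin &&
      length(trauma_ev) == 0L) {
    trauma_ev <- "laceration"
  }
  trauma <- length(trauma_ev) > 0L

  structure(list(tone = tone, tissue = tissue, trauma = trauma,
                 thrombin = thrombin,
                 evidence = list(tone = tone_ev, tissue = tissue_ev,
                                 trauma = trauma_ev, thrombin = thrombin_ev),
                 notes = notes),
            class = "pph_subtype")
}

#' @export
print.pph_subtype <- function(x, ...) {
  on <- c("tone", "tissue", "trauma", "thrombin")[c(x$tone, x$tissue, x$trauma, x$thrombin)]
  cat(sprintf("<subtype> %s\n", if (length(on)) paste(on, collapse = "+") else "none"))
  invisible(x)
}

#' Match a dotted ICD-9 code against a wildcard pattern
#'
#' In a pattern like `"666.1x"` each trailing `x` stands for any single digit
#' 0-9; all other characters must match exactly. A code may extend beyond the
#' pattern's end only when the pattern ends in a wildcard, and only with
#' digits — so `"666.1x"` matches `666.14` and `666.145` but not `666.1`,
#' and `"666.x"` matches the whole 666 family.
#'
#' @param code Dotted code string.
#' @param pattern Dotted prefix pattern with trailing `x` wildcards.
#' @return Logical scalar.
#' @export
code_matches <- function(code, pattern) {
  stopifnot(is.character(code), length(code) == 1L,
            is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  first_x <- regexpr("x", pattern, fixed = TRUE)[1]
  if (first_x == -1L) return(identical(code, pattern))
  wild <- substring(pattern, first_x)
  if (grepl("[^x]", wild)) {
    stop("malformed pattern '", pattern, "': wildcards must be in final positions")
  }
  prefix <- substring(pattern, 1L, first_x - 1L)
  if (!startsWith(code, prefix)) return(FALSE)
  rest <- substring(code, first_x)
  nchar(rest) >= nchar(wild) && grepl("^[0-9]+$", rest)
}

ICD_SUBTYPE_PATTERNS <- list(tone = "666.1x", tissue = "666.0x",
                             thrombin = "666.3x")

#' ICD-based subtype classification for one delivery
#'
#' The claims baseline over ICD-9 diagnosis families: tone from any 666.1x,
#' tissue from any 666.0x, thrombin from any 666.3x, trauma from any 665.x —
#' or from any 664.x provided no 666.x code is present (664.x codes are
#' delivery lacerations, which only signify traumatic hemorrhage when no
#' other attributable cause was coded).
#'
#' @param codes Character vector of the delivery's dotted ICD-9 codes.
#' @return A `pph_subtype` whose evidence lists the triggering codes.
#' @export
icd_subtype <- function(codes) {
  codes <- as.character(codes)
  hits <- function(pattern) codes[vapply(codes, code_matches, logical(1), pattern)]
  tone_ev <- hits("666.1x")
  tissue_ev <- hits("666.0x")
  thrombin_ev <- hits("666.3x")
  trauma_ev <- hits("665.x")
  if (length(hits("666.x")) == 0L) trauma_ev <- c(trauma_ev, hits("664.x"))
  structure(list(tone = length(tone_ev) > 0L, tissue = length(tissue_ev) > 0L,
                 trauma = length(trauma_ev) > 0L,
                 thrombin = length(thrombin_ev) > 0L,
                 evidence = list(tone = tone_ev, tissue = tissue_ev,
                                 trauma = unname(trauma_ev),
                                 thrombin = thrombin_ev),
                 notes = character(0)),
            class = "pph_subtype")
}

#' Subtype every delivery in an assessment table
#'
#' @param assessments Tibble from [assess_deliveries()] (NLP method), whose
#'   `concept_flags` feed [nlp_subtype()].
#' @param method `"nlp"` or `"icd"`.
#' @param icd_codes For `method = "icd"`: list of [icd_record()]s; a
#'   delivery's codes are those of its patient dated within `window_days` of
#'   any of its notes... codes are matched per patient here, on the dotted
#'   string, with no date filter (supply pre-linked codes for stricter use).
#' @param ... Passed to [nlp_subtype()] (e.g. `ffp_alone_qualifies`).
#' @return A tibble: `delivery_id`, `tone`, `tissue`, `trauma`, `thrombin`,
#'   `evidence` (list), `notes` (list).
#' @export
subtype_deliveries <- function(assessments, method = c("nlp", "icd"),
                               icd_codes = NULL, ...) {
  method <- match.arg(method)
  rows <- lapply(seq_len(nrow(assessments)), function(i) {
    res <- if (method == "nlp") {
      nlp_subtype(assessments$concept_flags[[i]], ...)
    } else {
      if (is.null(icd_codes)) stop("method 'icd' requires icd_codes")
      pid <- assessments$patient_id[i]
      codes <- vapply(Filter(function(r) r$patient_id == pid, icd_codes),
                      `[[`, character(1), "code")
      icd_subtype(codes)
    }
    tibble::tibble(delivery_id = assessments$delivery_id[i],
                   tone = res$tone, tissue = res$tissue, trauma = res$trauma,
                   thrombin = res$thrombin, evidence = list(res$evidence),
                   notes = list(res$notes))
  })
  do.call(rbind, rows)
}

#' Subtype prevalence
#'
#' Fraction of deliveries carrying each subtype flag. Subtypes are
#' multi-label, so the fractions need not sum to 1.
#'
#' @param results A tibble with logical columns `tone`, `tissue`, `trauma`,
#'   `thrombin` (e.g. from [subtype_deliveries()]), or a list of
#'   `pph_subtype` objects.
#' @return A tibble `subtype`, `count`, `fraction`. Empty input yields an
#'   empty table with a warning.
#' @export
subtype_prevalence <- function(results) {
  if (!is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r) {
      tibble::tibble(tone = r$tone, tissue = r$tissue, trauma = r$trauma,
                     thrombin = r$thrombin)
    }))
  }
  if (is.null(results) || nrow(results) == 0L) {
    warning("no subtype results; prevalence table is empty")
    return(tibble::tibble(subtype = character(0), count = integer(0),
                          fraction = numeric(0)))
  }
  labels <- c("tone", "tissue", "trauma", "thrombin")
  tibble::tibble(
    subtype = labels,
    count = vapply(labels, function(l) sum(results[[l]]), integer(1),
                   USE.NAMES = FALSE),
    fraction = vapply(labels, function(l) mean(results[[l]]), numeric(1),
                      USE.NAMES = FALSE))
}
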