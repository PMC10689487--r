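#' @title Synthetic obstetric discharge summaries
#' @description Generates delivery discharge summaries with known ground
#'   truth: planted PPH-related concepts realized via phrase banks, blood
#'   loss written in heterogeneous formats (mL/cc/L, bare numbers,
#'   concatenated corruptions like "500ccs/p"), optional misspellings and
#'   abbreviation substitutions, and polysemy distractors ("artificial
#'   rupture of membranes", "misoprostol for cervical ripening"). The
#'   generator targets structural fidelity (formats, variants, traps), not
#'   clinical fluency. In clean mode (corruption and distractors off) every
#'   planted phrase is drawn from surface forms the registry patterns match,
#'   so the pattern backend provably recovers the planted truth — which is
#'   what makes the generator a valid oracle for end-to-end tests.
#' @name synthgen
NULL

# Clean surface realizations per concept. Invariants (enforced by tests):
# each phrase matches at least one of its own concept's patterns and none of
# any other concept's patterns.
phrase_bank <- function() {
  list(
    laceration = c(
      "a second degree perineal laceration was repaired with 3-0 vicryl",
      "a small periurethral laceration was repaired",
      "a sulcal tear was noted and repaired"),
    bakri_balloon = c(
      "a bakri balloon was placed with good effect",
      "bakri balloon inserted for tamponade"),
    methylergonovine = c(
      "methergine 0.2 mg IM was administered",
      "methylergonovine was given with good response"),
    placenta_previa = c(
      "known complete placenta previa",
      "marginal previa had been noted on ultrasound"),
    fresh_frozen_plasma = c(
      "she received two units of fresh frozen plasma",
      "FFP was transfused"),
    carboprost = c(
      "hemabate 250 mcg IM was administered",
      "carboprost was given with improvement in tone"),
    misoprostol_uterotonic = c(
      "rectal misoprostol was administered",
      "misoprostol 800 mcg was given for uterine bleeding",
      "cytotec was administered for hemorrhage"),
    hysterectomy = c(
      "a supracervical hysterectomy was performed",
      "the patient proceeded to peripartum hysterectomy"),
    oleary_sutures = c(
      "o'leary sutures were placed bilaterally",
      "bilateral o leary stitches were placed"),
    uterine_atony = c(
      "uterine atony was noted requiring bimanual massage",
      "the uterus remained atonic despite massage"),
    retained_products = c(
      "retained products of conception were noted",
      "retained placental fragments were seen on ultrasound"),
    pph_mention = c(
      "the course was complicated by postpartum hemorrhage",
      "pph was diagnosed and managed medically"),
    prbc = c(
      "she was transfused two units of packed red blood cells",
      "pRBCs were transfused for symptomatic anemia"),
    abruption = c(
      "placental abruption was suspected",
      "there was concern for abruption of the placenta"),
    coagulation_disorders = c(
      "she developed disseminated intravascular coagulation",
      "coagulopathy was noted with an elevated INR",
      "laboratory values were consistent with dic"),
    cryoprecipitate = c(
      "cryoprecipitate was transfused",
      "she received cryo with improvement in fibrinogen"),
    dilation_curettage = c(
      "a dilation and curettage was performed",
      "sharp curettage was performed at the bedside",
      "she underwent uterine d&c"),
    platelets = c(
      "one pack of platelets was transfused",
      "platelet transfusion was given"),
    accreta_spectrum = c(
      "findings were consistent with placenta accreta",
      "placenta increta was noted at surgery",
      "placenta percreta with bladder invasion was found"),
    manual_extraction_placenta = c(
      "manual extraction of the placenta was performed",
      "the placenta was removed manually",
      "manual removal of the placenta was required"),
    pph_surgical = c(
      "there was surgical bleeding from the hysterotomy angle",
      "bleeding from the uterine artery required ligation",
      "a surgical source of bleeding was identified"),
    uterine_rupture = c(
      "a complete uterine rupture was identified",
      "uterine rupture was noted at laparotomy"))
}

# Polysemy traps: clinically plausible sentences that must match no pattern.
distractor_bank <- function() {
  c("artificial rupture of membranes was performed to augment labor",
    "misoprostol was given for cervical ripening prior to induction",
    "spontaneous rupture of membranes occurred in early labor")
}

# Abbreviation substitutions (all still covered by the registry patterns, so
# abbreviation noise changes surface form without hiding the concept).
ABBREV_MAP <- c(
  "dilation and curettage" = "d&c",
  "postpartum hemorrhage" = "pph",
  "packed red blood cells" = "prbc",
  "fresh frozen plasma" = "ffp",
  "retained products of conception" = "retained poc",
  "estimated blood loss" = "ebl")

#' Synthetic corpus configuration
#'
#' Defaults emulate an annotated obstetric discharge cohort: per-concept
#' prevalences follow the frequencies observed in a PPH-enriched annotated
#' note set, roughly a third of deliveries are cesarean, one in ten
#' deliveries meets the blood-loss PPH definition, 15% of deliveries emit a
#' second (addendum) note restating the same blood loss 0-3 days later, and
#' 30% of non-PPH deliveries document no blood loss at all.
#'
#' @param n_notes Total number of notes to generate.
#' @param concept_prevalence Named numeric vector of per-note plant
#'   probabilities for binary concepts (cesarean status is governed by
#'   `cesarean_rate`, not listed here). Unknown names are an error.
#' @param cesarean_rate Probability a delivery is cesarean.
#' @param pph_rate Probability a delivery's blood loss exceeds its mode's
#'   threshold.
#' @param p_no_ebl Probability a non-PPH delivery documents no blood loss.
#' @param ebl_format_weights Named weights over formats `ml`, `cc`, `l`,
#'   `bare`, `bare_l`, `concat`.
#' @param two_note_fraction Fraction of deliveries emitting two notes.
#' @param misspell_rate,abbrev_rate,distractor_rate Corruption and trap
#'   rates; set all to 0 for clean mode.
#' @param seed Integer seed (mandatory; the corpus is a pure function of the
#'   config).
#' @return A list of class `pph_synth_config`.
#' @export
synth_config <- function(n_notes = 100L,
                         concept_prevalence = default_prevalence(),
                         cesarean_rate = 0.32, pph_rate = 0.1, p_no_ebl = 0.3,
                         ebl_format_weights = c(ml = 0.35, cc = 0.25, l = 0.15,
                                                bare = 0.1, bare_l = 0.05,
                                                concat = 0.1),
                         two_note_fraction = 0.15,
                         misspell_rate = 0.05, abbrev_rate = 0.1,
                         distractor_rate = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  unknown <- setdiff(names(concept_prevalence), names(phrase_bank()))
  if (length(unknown) > 0L) {
    stop("unknown concept(s) in prevalence map: ", paste(unknown, collapse = ", "))
  }
  probs <- c(concept_prevalence, cesarean_rate, pph_rate, p_no_ebl,
             two_note_fraction, misspell_rate, abbrev_rate, distractor_rate)
  stopifnot(all(probs >= 0), all(probs <= 1), n_notes >= 1)
  structure(list(n_notes = as.integer(n_notes),
                 concept_prevalence = concept_prevalence,
                 cesarean_rate = cesarean_rate, pph_rate = pph_rate,
                 p_no_ebl = p_no_ebl, ebl_format_weights = ebl_format_weights,
                 two_note_fraction = two_note_fraction,
                 misspell_rate = misspell_rate, abbrev_rate = abbrev_rate,
                 distractor_rate = distractor_rate, seed = as.integer(seed)),
            class = "pph_synth_config")
}

#' Default per-note concept prevalences
#'
#' Follows the relative frequencies of the 22 planted binary concepts in a
#' PPH-enriched annotated discharge cohort (cesarean status excluded: it is
#' the delivery mode).
#' @return Named numeric vector.
#' @export
default_prevalence <- function() {
  c(laceration = 0.36, bakri_balloon = 0.04, methylergonovine = 0.09,
    placenta_previa = 0.14, fresh_frozen_plasma = 0.07, carboprost = 0.04,
    misoprostol_uterotonic = 0.10, hysterectomy = 0.05, oleary_sutures = 0.01,
    uterine_atony = 0.09, retained_products = 0.09, pph_mention = 0.31,
    prbc = 0.14, abruption = 0.04, coagulation_disorders = 0.04,
    cryoprecipitate = 0.025, dilation_curettage = 0.10, platelets = 0.025,
    accreta_spectrum = 0.04, manual_extraction_placenta = 0.09,
    pph_surgical = 0.023, uterine_rupture = 0.01)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

pick <- function(x, w = NULL) {
  if (length(x) == 1L) return(x[[1]])
  x[[sample.int(length(x), 1L, prob = w)]]
}

ebl_sentence <- function(value, format) {
  if (format == "l" && value %% 10 != 0) format <- "ml"
  if (format == "bare_l" && value %% 1000 != 0) format <- "ml"
  switch(format,
         ml = sprintf("Estimated blood loss was %d mL.", value),
         cc = sprintf("EBL: %dcc.", value),
         l = sprintf("EBL %s L.", format(value / 1000)),
         bare = sprintf("Estimated blood loss %d.", value),
         bare_l = sprintf("EBL was %s.", format(value / 1000)),
         concat = sprintf("EBL %dccs/p repair.", value))
}

sample_ebl <- function(pph, mode) {
  if (pph) {
    if (mode == "cesarean") pick(seq(1100L, 3000L, 50L)) else pick(seq(600L, 3000L, 50L))
  } else {
    if (mode == "cesarean") pick(seq(200L, 1000L, 100L)) else pick(seq(100L, 500L, 50L))
  }
}

mode_sentence <- function(mode, addendum = FALSE) {
  if (mode == "cesarean") {
    if (addendum) "She is status post cesarean section."
    else "She underwent a primary low transverse cesarean section."
  } else {
    if (addendum) "She is status post vaginal delivery."
    else "She had a normal spontaneous vaginal delivery."
  }
}

#' Generate a synthetic corpus with gold labels and truth
#'
#' Deterministic given the config (same config + seed gives a byte-identical
#' corpus). Each note is assembled from templated sections: an admission
#' line, a delivery sentence carrying the mode phrase, an optional blood-loss
#' mention in one of the configured formats, one phrase-bank sentence per
#' planted concept, optional distractors, and a discharge line. A
#' configurable fraction of deliveries emit a second addendum note 0-3 days
#' later restating the same blood loss (exercising cross-note
#' de-duplication). Truth subtype and PPH flags are computed by applying the
#' package's own rule engines to the planted primitives, so truth is
#' self-consistent by construction.
#'
#' @param config A [synth_config()].
#' @return A list of class `pph_synth` with `notes` (list of
#'   [note_record()]s), `truth` (list: `notes` tibble, `deliveries` tibble),
#'   and `gold` (list of [gold_annotation()]s covering every note and all 24
#'   concepts).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "pph_synth_config"))
  with_local_seed(config$seed, {
    concepts <- names(config$concept_prevalence)
    notes <- list()
    gold <- list()
    note_rows <- list()
    delivery_rows <- list()
    base_date <- as.Date("2010-01-04")
    d <- 0L
    while (length(notes) < config$n_notes) {
      d <- d + 1L
      pid <- sprintf("p%05d", d)
      did <- sprintf("%s/d1", pid)
      mode <- if (stats::runif(1) < config$cesarean_rate) "cesarean" else "vaginal"
      pph <- stats::runif(1) < config$pph_rate
      has_ebl <- pph || stats::runif(1) >= config$p_no_ebl
      value <- if (has_ebl) sample_ebl(pph, mode) else NA_integer_
      format <- pick(names(config$ebl_format_weights), config$ebl_format_weights)
      flags <- stats::runif(length(concepts)) < config$concept_prevalence
      names(flags) <- concepts
      two_notes <- length(notes) + 2L <= config$n_notes &&
        stats::runif(1) < config$two_note_fraction
      note_date <- base_date + 14L * d
      n_in_group <- if (two_notes) 2L else 1L
      for (j in seq_len(n_in_group)) {
        nid <- sprintf("n%05d_%d", d, j)
        addendum <- j == 2L
        date_j <- if (addendum) note_date + sample(0:3, 1L) else note_date
        sentences <- c(
          sprintf("Admitted to labor and delivery on %s.", format(date_j, "%Y-%m-%d")),
          mode_sentence(mode, addendum))
        if (has_ebl) sentences <- c(sentences, ebl_sentence(value, format))
        if (!addendum) {
          for (cid in concepts[flags]) {
            sentences <- c(sentences, paste0(pick(phrase_bank()[[cid]]), "."))
          }
        }
        if (stats::runif(1) < config$distractor_rate) {
          sentences <- c(sentences, paste0(pick(distractor_bank()), "."))
        }
        sentences <- c(sentences,
                       "She was discharged home in stable condition.")
        text <- paste(sentences, collapse = " ")
        if (config$misspell_rate > 0 || config$abbrev_rate > 0) {
          text <- corrupt_text(text, config$misspell_rate, config$abbrev_rate,
                               seed = config$seed + 7919L * d + j,
                               preserve_numbers = TRUE)
        }
        notes[[length(notes) + 1L]] <- note_record(
          nid, pid, date_j, hospital = "synthetic-general",
          status = "final", department = "obstetrics", text = text)
        note_flags <- if (addendum) stats::setNames(rep(FALSE, length(concepts)), concepts) else flags
        note_flags <- c(note_flags, cesarean_delivery = (mode == "cesarean"))
        # planted values are always in mL; every surface format normalizes back
        values <- if (has_ebl) as.numeric(value) else numeric(0)
        note_rows[[length(note_rows) + 1L]] <- tibble::tibble(
          note_id = nid, patient_id = pid, delivery_id = did, mode = mode,
          ebl_values = list(values), flags = list(note_flags))
        for (cid in names(note_flags)) {
          gold[[length(gold) + 1L]] <- gold_annotation(nid, cid, label = unname(note_flags[[cid]]))
        }
        gold[[length(gold) + 1L]] <- gold_annotation(nid, "estimated_blood_loss",
                                                     values = values)
      }
      total <- summarize_ebl(if (has_ebl) normalize_to_ml(value, "none") else numeric(0))
      delivery_flags <- c(flags, cesarean_delivery = (mode == "cesarean"))
      st <- nlp_subtype(delivery_flags)
      delivery_rows[[length(delivery_rows) + 1L]] <- tibble::tibble(
        delivery_id = did, patient_id = pid, mode = mode, n_notes = n_in_group,
        total_ebl_ml = total$total_ml,
        pph = classify_pph(total$total_ml, mode),
        tone = st$tone, tissue = st$tissue, trauma = st$trauma,
        thrombin = st$thrombin, flags = list(delivery_flags))
    }
    structure(list(notes = notes,
                   truth = list(notes = do.call(rbind, note_rows),
                                deliveries = do.call(rbind, delivery_rows)),
                   gold = gold, config = config),
              class = "pph_synth")
  })
}

#' Corrupt text with misspellings and abbreviation substitutions
#'
#' Word-level perturbation: each eligible word (length >= 4; with
#' `preserve_numbers`, words containing digits are never touched, so planted
#' numeric blood-loss tokens always survive) has two adjacent interior
#' characters swapped with probability `misspell_rate`. Independently, each
#' known long form ("dilation and curettage", "postpartum hemorrhage", ...)
#' present in the text is replaced by its clinical abbreviation ("d&c",
#' "pph", ...) with probability `abbrev_rate`. Deterministic given `seed`;
#' rates 0 return the text unchanged.
#'
#' @param text A string.
#' @param misspell_rate,abbrev_rate Probabilities in `[0, 1)`.
#' @param seed Integer seed.
#' @param preserve_numbers Never perturb words containing digits.
#' @return The corrupted string.
#' @export
corrupt_text <- function(text, misspell_rate, abbrev_rate, seed,
                         preserve_numbers = TRUE) {
  stopifnot(misspell_rate >= 0, misspell_rate < 1,
            abbrev_rate >= 0, abbrev_rate < 1)
  if (misspell_rate == 0 && abbrev_rate == 0) return(text)
  with_local_seed(seed, {
    if (abbrev_rate > 0) {
      for (long in names(ABBREV_MAP)) {
        if (grepl(long, text, fixed = TRUE) && stats::runif(1) < abbrev_rate) {
          text <- gsub(long, ABBREV_MAP[[long]], text, fixed = TRUE)
        }
      }
    }
    if (misspell_rate > 0) {
      words <- strsplit(text, " ", fixed = TRUE)[[1]]
      for (i in seq_along(words)) {
        w <- words[i]
        if (nchar(w) < 4L) next
        if (preserve_numbers && grepl("[0-9]", w)) next
        if (stats::runif(1) < misspell_rate) {
          j <- sample(2:(nchar(w) - 2L), 1L)
          chars <- strsplit(w, "")[[1]]
          tmp <- chars[j]; chars[j] <- chars[j + 1L]; chars[j + 1L] <- tmp
          words[i] <- paste(chars, collapse = "")
        }
      }
      text <- paste(words, collapse = " ")
    }
    text
  })
}

#' Summary table of a synthetic corpus's planted truth
#'
#' @param truth The `truth` element of a [generate_corpus()] result.
#' @return A list: `n_notes`, `n_deliveries`, `pph_rate`, `cesarean_rate`,
#'   `concept_prevalence` (note-level, named), `subtype_fractions` (among
#'   PPH-positive deliveries).
#' @export
truth_report <- function(truth) {
  notes <- truth$notes
  dels <- truth$deliveries
  if (is.null(notes) || nrow(notes) == 0L) {
    return(list(n_notes = 0L, n_deliveries = 0L, pph_rate = NA_real_,
                cesarean_rate = NA_real_,
                concept_prevalence = numeric(0), subtype_fractions = numeric(0)))
  }
  cids <- names(notes$flags[[1]])
  prev <- vapply(cids, function(cid) {
    mean(vapply(notes$flags, function(f) isTRUE(f[[cid]]), logical(1)))
  }, numeric(1))
  pos <- dels[dels$pph, ]
  st <- if (nrow(pos) > 0L) {
    c(tone = mean(pos$tone), tissue = mean(pos$tissue),
      trauma = mean(pos$trauma), thrombin = mean(pos$thrombin))
  } else c(tone = NA_real_, tissue = NA_real_, trauma = NA_real_, thrombin = NA_real_)
  list(n_notes = nrow(notes), n_deliveries = nrow(dels),
       pph_rate = mean(dels$pph), cesarean_rate = mean(dels$mode == "cesarean"),
       concept_prevalence = prev, subtype_fractions = st)
}
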