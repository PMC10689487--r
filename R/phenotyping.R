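#' @title PPH phenotyping
#' @description Rolls note-level concept calls up to deliveries and applies
#'   the blood-loss definition of postpartum hemorrhage: total extracted EBL
#'   strictly greater than 500 mL for vaginal deliveries or strictly greater
#'   than 1000 mL for cesarean deliveries (the definition in clinical use
#'   before 2018). The post-2018 consensus definition (more than 1000 mL
#'   regardless of mode) is available as a preset, reflecting how a
#'   concept-based phenotype can be re-thresholded without re-extraction.
#' @name phenotyping
NULL

#' Phenotype decision rule
#'
#' @param vaginal_threshold_ml Threshold for vaginal deliveries (strict >).
#' @param cesarean_threshold_ml Threshold for cesarean deliveries (strict >);
#'   must be >= the vaginal threshold.
#' @param name Label carried into outputs.
#' @return A list of class `pph_rule`.
#' @export
phenotype_rule <- function(vaginal_threshold_ml = 500,
                           cesarean_threshold_ml = 1000,
                           name = "historical") {
  stopifnot(cesarean_threshold_ml >= vaginal_threshold_ml)
  structure(list(vaginal_threshold_ml = vaginal_threshold_ml,
                 cesarean_threshold_ml = cesarean_threshold_ml,
                 name = name),
            class = "pph_rule")
}

#' @rdname phenotype_rule
#' @details `rule_preset("historical")` is >500 vaginal / >1000 cesarean;
#'   `rule_preset("acog2017")` is >1000 regardless of delivery mode.
#' @param preset `"historical"` or `"acog2017"`.
#' @export
rule_preset <- function(preset = c("historical", "acog2017")) {
  preset <- match.arg(preset)
  if (preset == "historical") phenotype_rule(500, 1000, "historical")
  else phenotype_rule(1000, 1000, "acog2017")
}

#' Group notes into deliveries
#'
#' Notes of the same patient whose dates chain with gaps of at most
#' `max_gap_days` form one delivery group (sorted by date, so the result is
#' independent of input order). Deliveries are at least months apart, so any
#' small gap cleanly separates encounters.
#'
#' @param notes List of [note_record()]s (all dated).
#' @param max_gap_days Maximum day gap between consecutive notes of the same
#'   delivery; default 7.
#' @return A named list: `delivery_id -> list of notes`. Delivery ids are
#'   `"<patient_id>/d<k>"` with `k` counting a patient's deliveries in date
#'   order.
#' @export
group_notes <- function(notes, max_gap_days = 7) {
  if (length(notes) == 0L) return(list())
  pid <- vapply(notes, `[[`, character(1), "patient_id")
  date <- vapply(notes, function(n) as.numeric(n$note_date), numeric(1))
  if (anyNA(date)) stop("all notes must be dated for grouping")
  groups <- list()
  for (p in unique(pid)) {
    sel <- which(pid == p)
    sel <- sel[order(date[sel], vapply(notes[sel], `[[`, character(1), "note_id"))]
    k <- 0L
    last_date <- -Inf
    for (i in sel) {
      if (date[i] - last_date > max_gap_days) {
        k <- k + 1L
        groups[[sprintf("%s/d%d", p, k)]] <- list()
      }
      gid <- sprintf("%s/d%d", p, k)
      groups[[gid]][[length(groups[[gid]]) + 1L]] <- notes[[i]]
      last_date <- date[i]
    }
  }
  groups
}

#' Infer delivery mode from concept calls
#'
#' Cesarean iff the `cesarean_delivery` concept call is positive on any note
#' of the group; vaginal otherwise.
#'
#' @param calls Calls tibble (from [extract_corpus()]) restricted or not;
#'   must contain a `cesarean_delivery` row for every note id in `note_ids`.
#' @param note_ids Character vector of the group's note ids.
#' @return `"cesarean"` or `"vaginal"`.
#' @export
infer_mode <- function(calls, note_ids) {
  rows <- calls[calls$concept_id == "cesarean_delivery" & calls$note_id %in% note_ids, ]
  if (!all(note_ids %in% rows$note_id)) {
    stop("missing cesarean_delivery call for note(s): ",
         paste(setdiff(note_ids, rows$note_id), collapse = ", "))
  }
  if (any(rows$label, na.rm = TRUE)) "cesarean" else "vaginal"
}

#' Classify PPH from total blood loss and mode
#'
#' Strict comparison against the mode's threshold: exactly 500 mL vaginal or
#' exactly 1000 mL cesarean is *not* PPH. Monotone in `total_ebl_ml` for
#' fixed mode.
#'
#' @param total_ebl_ml Total normalized blood loss in mL (>= 0).
#' @param mode `"cesarean"` or `"vaginal"`.
#' @param rule A [phenotype_rule()].
#' @return Logical scalar.
#' @export
classify_pph <- function(total_ebl_ml, mode = c("vaginal", "cesarean"),
                         rule = phenotype_rule()) {
  mode <- match.arg(mode)
  stopifnot(total_ebl_ml >= 0)
  threshold <- if (mode == "cesarean") rule$cesarean_threshold_ml else rule$vaginal_threshold_ml
  total_ebl_ml > threshold
}

#' Assess deliveries: pool EBL, infer mode, classify PPH
#'
#' For each delivery group: pools the extracted EBL segments across the
#' group's notes, parses and summarizes them (the same-value de-duplication
#' applies across the whole group — two notes for one delivery typically
#' restate the same loss), infers the delivery mode, and applies the rule.
#' Carries per-concept evidence for interpretability.
#'
#' @param notes List of [note_record()]s.
#' @param calls Calls tibble from [extract_corpus()]; must cover
#'   `estimated_blood_loss` and `cesarean_delivery` for every note.
#' @param rule A [phenotype_rule()].
#' @param max_gap_days Grouping gap passed to [group_notes()].
#' @param groups Optional precomputed grouping (named list `delivery_id ->
#'   notes`) bypassing [group_notes()] — use this when a trusted delivery
#'   identifier already exists.
#' @return A tibble with one row per delivery: `delivery_id`, `patient_id`,
#'   `note_ids` (list), `n_notes`, `total_ebl_ml`, `ebl_values` (list),
#'   `mode`, `pph`, `concept_flags` (list: named logical over binary
#'   concepts, any-positive across the group's notes).
#' @export
assess_deliveries <- function(notes, calls, rule = phenotype_rule(),
                              max_gap_days = 7, groups = NULL) {
  if (is.null(groups)) groups <- group_notes(notes, max_gap_days)
  binary_ids <- unique(calls$concept_id[calls$kind == "binary"])
  rows <- lapply(names(groups), function(gid) {
    grp <- groups[[gid]]
    ids <- vapply(grp, `[[`, character(1), "note_id")
    ebl_rows <- calls[calls$concept_id == "estimated_blood_loss" & calls$note_id %in% ids, ]
    if (!all(ids %in% ebl_rows$note_id)) {
      stop("missing estimated_blood_loss call for note(s): ",
           paste(setdiff(ids, ebl_rows$note_id), collapse = ", "))
    }
    segments <- unique(unlist(ebl_rows$segments))
    summary <- summarize_ebl(parse_ebl_mentions(segments))
    mode <- infer_mode(calls, ids)
    flags <- vapply(binary_ids, function(cid) {
      sub <- calls[calls$concept_id == cid & calls$note_id %in% ids, ]
      any(sub$label, na.rm = TRUE)
    }, logical(1))
    tibble::tibble(delivery_id = gid, patient_id = grp[[1]]$patient_id,
                   note_ids = list(ids), n_notes = length(ids),
                   total_ebl_ml = summary$total_ml,
                   ebl_values = list(summary$values_ml),
                   mode = mode,
                   pph = classify_pph(summary$total_ml, mode, rule),
                   concept_flags = list(flags))
  })
  if (length(rows) == 0L) {
    return(tibble::tibble(delivery_id = character(0), patient_id = character(0),
                          note_ids = list(), n_notes = integer(0),
                          total_ebl_ml = numeric(0), ebl_values = list(),
                          mode = character(0), pph = logical(0),
                          concept_flags = list()))
  }
  do.call(rbind, rows)
}

#' Concept prevalence among predicted-PPH deliveries
#'
#' Counts and percentages of deliveries (not notes) positive for each binary
#' concept, with the PPH-positive deliveries as denominator.
#'
#' @param assessments Tibble from [assess_deliveries()].
#' @return A tibble `concept_id`, `count`, `percent`, sorted by count
#'   descending. Zero PPH-positive deliveries yields an empty table with a
#'   warning.
#' @export
prevalence_table <- function(assessments) {
  pos <- assessments[assessments$pph, ]
  if (nrow(pos) == 0L) {
    warning("no PPH-positive deliveries; prevalence table is empty")
    return(tibble::tibble(concept_id = character(0), count = integer(0),
                          percent = numeric(0)))
  }
  ids <- names(pos$concept_flags[[1]])
  counts <- vapply(ids, function(cid) {
    sum(vapply(pos$concept_flags, function(f) isTRUE(f[[cid]]), logical(1)))
  }, integer(1), USE.NAMES = FALSE)
  out <- tibble::tibble(concept_id = ids, count = counts,
                        percent = 100 * counts / nrow(pos))
  out[order(-out$count, out$concept_id), ]
}
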