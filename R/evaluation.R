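#' @title Evaluation metrics
#' @description Chart-review-style validation metrics: confusion-matrix
#'   metrics for binary concepts, pooled set metrics for the measurement
#'   concept, a per-concept report table, the McNemar paired test for
#'   comparing two extraction methods on the same notes, and the EBL-by-ICD
#'   cross-tabulation.
#' @name evaluation
NULL

#' Confusion counts from predicted and true labels
#'
#' @param pred,truth Logical vectors of equal length.
#' @return A list of class `pph_confusion` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), !anyNA(pred), !anyNA(truth))
  structure(list(tp = sum(pred & truth), fp = sum(pred & !truth),
                 fn = sum(!pred & truth), tn = sum(!pred & !truth)),
            class = "pph_confusion")
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Binary classification metrics
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp), binary F1
#' (harmonic mean of PPV and sensitivity), accuracy. A metric whose
#' denominator is zero is returned as `NA` and named in `undefined` — never
#' coerced to 0 by convention.
#'
#' @param c A `pph_confusion` (or list with `tp`, `fp`, `fn`, `tn`).
#' @return A list: `sensitivity`, `specificity`, `ppv`, `binary_f1`,
#'   `accuracy`, `undefined` (character vector of flagged metrics).
#' @export
binary_metrics <- function(c) {
  stopifnot(all(c(c$tp, c$fp, c$fn, c$tn) >= 0))
  total <- c$tp + c$fp + c$fn + c$tn
  sens <- safe_ratio(c$tp, c$tp + c$fn)
  spec <- safe_ratio(c$tn, c$tn + c$fp)
  ppv <- safe_ratio(c$tp, c$tp + c$fp)
  f1 <- if (is.na(sens) || is.na(ppv)) NA_real_
        else if (sens + ppv == 0) NA_real_
        else 2 * ppv * sens / (ppv + sens)
  acc <- safe_ratio(c$tp + c$tn, total)
  out <- list(sensitivity = sens, specificity = spec, ppv = ppv,
              binary_f1 = f1, accuracy = acc)
  out$undefined <- names(out)[vapply(out, function(x) is.na(x), logical(1))]
  out
}

#' Pooled metrics for value-set extraction
#'
#' Value-level sensitivity and PPV are pooled over notes (intersection sizes
#' summed before dividing); note-level accuracy is the fraction of notes
#' whose predicted set exactly equals the gold set (both possibly empty — an
#' empty-vs-empty note counts as correct but contributes nothing to the
#' pooled ratios).
#'
#' @param pred,gold Named lists mapping note id to a numeric value set; the
#'   two must cover the same note universe.
#' @return A list: `sensitivity`, `ppv`, `note_accuracy`, `undefined`.
#' @export
extraction_metrics <- function(pred, gold) {
  if (!setequal(names(pred), names(gold))) {
    stop("pred and gold must cover the same note universe")
  }
  ids <- names(gold)
  tp <- 0; n_gold <- 0; n_pred <- 0; correct <- 0
  for (id in ids) {
    g <- unique(as.numeric(gold[[id]]))
    p <- unique(as.numeric(pred[[id]]))
    tp <- tp + length(intersect(p, g))
    n_gold <- n_gold + length(g)
    n_pred <- n_pred + length(p)
    if (setequal(p, g)) correct <- correct + 1
  }
  out <- list(sensitivity = safe_ratio(tp, n_gold),
              ppv = safe_ratio(tp, n_pred),
              note_accuracy = safe_ratio(correct, length(ids)))
  out$undefined <- names(out)[vapply(out, is.na, logical(1))]
  out
}

#' Paired outcomes for two methods
#'
#' @param correct_a,correct_b Logical vectors: was each method correct on
#'   each item?
#' @return A list of class `pph_paired` with `n11`, `n10`, `n01`, `n00`.
#' @export
paired_outcomes <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  structure(list(n11 = sum(correct_a & correct_b),
                 n10 = sum(correct_a & !correct_b),
                 n01 = sum(!correct_a & correct_b),
                 n00 = sum(!correct_a & !correct_b)),
            class = "pph_paired")
}

#' McNemar paired test
#'
#' Tests whether two methods evaluated on the same items differ in accuracy,
#' using only the discordant counts b = n10, c = n01. Exact mode is the
#' two-sided binomial test of b successes in b + c trials at 0.5; chi2cc mode
#' is the continuity-corrected statistic (|b - c| - 1)^2 / (b + c) against
#' chi-square with 1 df. `auto` uses the exact test when b + c < 25 and the
#' corrected chi-square otherwise (standard practice; the exact test is
#' preferable with few discordant pairs). With b + c = 0 the methods never
#' disagree and p = 1.
#'
#' @param p A `pph_paired` (or list with `n10`, `n01`).
#' @param mode `"auto"`, `"exact"`, or `"chi2cc"`.
#' @return A list: `statistic` (chi-square statistic, or `NA` in exact
#'   mode), `p_value`, `mode_used`, `b`, `c`.
#' @export
mcnemar <- function(p, mode = c("auto", "exact", "chi2cc")) {
  mode <- match.arg(mode)
  b <- p$n10
  c <- p$n01
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) {
    return(list(statistic = NA_real_, p_value = 1.0,
                mode_used = "degenerate", b = b, c = c))
  }
  if (mode == "auto") mode <- if (b + c < 25) "exact" else "chi2cc"
  if (mode == "exact") {
    pv <- stats::binom.test(b, b + c, 0.5)$p.value
    list(statistic = NA_real_, p_value = min(1, pv), mode_used = "exact",
         b = b, c = c)
  } else {
    stat <- (abs(b - c) - 1)^2 / (b + c)
    list(statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         mode_used = "chi2cc", b = b, c = c)
  }
}

#' Per-concept performance report
#'
#' One row per concept with gold annotations: binary concepts are scored
#' with [binary_metrics()] against the gold labels; the measurement concept
#' is scored with [extraction_metrics()] on normalized mL value sets. `n` is
#' the gold positive count (binary) or the number of notes with a non-empty
#' gold value set (measurement). Concepts present in the calls but absent
#' from the gold are omitted with a warning.
#'
#' @param calls Calls tibble from [extract_corpus()].
#' @param gold List of [gold_annotation()]s.
#' @param registry Concept registry (for concept kinds); default
#'   [builtin_registry()].
#' @return A tibble sorted by descending binary F1: `concept_id`, `kind`,
#'   `n`, `sensitivity`, `specificity`, `ppv`, `binary_f1`, `accuracy`,
#'   `note_accuracy`.
#' @export
concept_report <- function(calls, gold, registry = builtin_registry()) {
  gold_ids <- unique(vapply(gold, `[[`, character(1), "concept_id"))
  eval_ids <- intersect(unique(calls$concept_id), gold_ids)
  skipped <- setdiff(unique(calls$concept_id), gold_ids)
  if (length(skipped) > 0L) {
    warning("concept(s) without gold annotations omitted: ",
            paste(skipped, collapse = ", "))
  }
  rows <- lapply(eval_ids, function(cid) {
    kind <- registry[[cid]]$kind
    g <- Filter(function(a) a$concept_id == cid, gold)
    note_ids <- vapply(g, `[[`, character(1), "note_id")
    sub <- calls[calls$concept_id == cid & calls$note_id %in% note_ids, ]
    sub <- sub[match(note_ids, sub$note_id), ]
    if (anyNA(sub$note_id)) {
      stop("calls missing for concept ", cid, " on annotated note(s)")
    }
    if (kind == "binary") {
      truth <- vapply(g, `[[`, logical(1), "label")
      m <- binary_metrics(confusion_counts(sub$label, truth))
      tibble::tibble(concept_id = cid, kind = kind, n = sum(truth),
                     sensitivity = m$sensitivity, specificity = m$specificity,
                     ppv = m$ppv, binary_f1 = m$binary_f1, accuracy = m$accuracy,
                     note_accuracy = NA_real_)
    } else {
      gold_sets <- lapply(g, function(a) a$values %||% numeric(0))
      names(gold_sets) <- note_ids
      pred_sets <- lapply(seq_len(nrow(sub)), function(i) {
        summarize_ebl(parse_ebl_mentions(sub$segments[[i]]))$values_ml
      })
      names(pred_sets) <- sub$note_id
      m <- extraction_metrics(pred_sets, gold_sets)
      tibble::tibble(concept_id = cid, kind = kind,
                     n = sum(lengths(gold_sets) > 0),
                     sensitivity = m$sensitivity, specificity = NA_real_,
                     ppv = m$ppv, binary_f1 = NA_real_, accuracy = NA_real_,
                     note_accuracy = m$note_accuracy)
    }
  })
  out <- do.call(rbind, rows)
  out[order(-ifelse(is.na(out$binary_f1), -Inf, out$binary_f1), out$concept_id), ]
}

#' PPH ICD-code prevalence by extracted blood-loss bin
#'
#' For each EBL bin (plus a "no EBL extracted" bin) the count and proportion
#' of deliveries whose patient carries at least one PPH ICD code. PPH code
#' definitions vary by study; supply them as wildcard patterns (see
#' [code_matches()]).
#'
#' @param assessments Tibble from [assess_deliveries()].
#' @param icd_codes List of [icd_record()]s.
#' @param bin_edges Increasing numeric vector of bin edges in mL; bins are
#'   `(edge_i, edge_{i+1}]`, with values above the last edge pooled into a
#'   final open bin.
#' @param pph_code_patterns Character vector of wildcard patterns defining a
#'   PPH code (e.g. `"666.x"`).
#' @return A tibble: `bin`, `n`, `n_coded`, `proportion`.
#' @export
ebl_icd_crosstab <- function(assessments, icd_codes,
                             bin_edges = c(0, 500, 1000, 1500, 2000),
                             pph_code_patterns = "666.x") {
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges, strictly = TRUE))
  coded_patients <- unique(vapply(
    Filter(function(r) any(vapply(pph_code_patterns, function(p)
      code_matches(r$code, p), logical(1))), icd_codes),
    `[[`, character(1), "patient_id"))
  edges <- c(bin_edges, Inf)
  labels <- c("no EBL extracted",
              vapply(seq_len(length(edges) - 1L), function(i) {
                if (is.infinite(edges[i + 1])) sprintf("> %g", edges[i])
                else sprintf("(%g, %g]", edges[i], edges[i + 1])
              }, character(1)))
  bin_of <- function(i) {
    if (length(assessments$ebl_values[[i]]) == 0L) return(labels[1])
    v <- assessments$total_ebl_ml[i]
    j <- findInterval(v, edges, left.open = TRUE, rightmost.closed = FALSE)
    labels[max(j, 1L) + 1L]
  }
  bins <- vapply(seq_len(nrow(assessments)), bin_of, character(1))
  coded <- assessments$patient_id %in% coded_patients
  rows <- lapply(labels, function(lb) {
    sel <- bins == lb
    tibble::tibble(bin = lb, n = sum(sel), n_coded = sum(coded[sel]),
                   proportion = safe_ratio(sum(coded[sel]), sum(sel)))
  })
  do.call(rbind, rows)
}
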