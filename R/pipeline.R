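#' @title Pipeline orchestration
#' @description Chains the stages — read/clean notes, identify delivery
#'   notes, extract concepts, phenotype deliveries, subtype, evaluate — and
#'   writes each stage's output plus a reproducibility manifest (config
#'   snapshot, input/output digests, row counts, seed). Rerunning the same
#'   config with a deterministic backend reproduces byte-identical outputs.
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param notes Path to a notes file (jsonl/csv) or a list of
#'   [note_record()]s.
#' @param icd Optional path to an ICD CSV or list of [icd_record()]s.
#' @param gold Optional path to a gold JSONL or list of
#'   [gold_annotation()]s.
#' @param registry Registry YAML path or a registry object; default the
#'   built-in registry.
#' @param backend `"pattern"` or a constructed `pph_backend`.
#' @param extraction An [extraction_config()].
#' @param rule A [phenotype_rule()] or preset name (`"historical"`,
#'   `"acog2017"`).
#' @param gap_days Note-grouping gap in days.
#' @param filter_method `"none"`, `"terms"`, `"icd"`, or `"prompt"` — how to
#'   restrict to delivery notes before extraction.
#' @param subtype_method `"nlp"`, `"icd"`, or `"both"`.
#' @param out_dir Output directory (created if missing).
#' @param log_level `"info"` or `"debug"`; debug writes per-chunk provenance
#'   into the calls output.
#' @param seed Integer recorded in the manifest (the pattern backend is
#'   deterministic; the seed matters for stochastic backends).
#' @return A list of class `pph_run_config`.
#' @export
run_config <- function(notes, icd = NULL, gold = NULL, registry = NULL,
                       backend = "pattern", extraction = extraction_config(),
                       rule = "historical", gap_days = 7,
                       filter_method = c("none", "terms", "icd", "prompt"),
                       subtype_method = c("nlp", "icd", "both"),
                       out_dir, log_level = c("info", "debug"), seed = 1L) {
  filter_method <- match.arg(filter_method)
  subtype_method <- match.arg(subtype_method)
  log_level <- match.arg(log_level)
  for (p in Filter(is.character, list(notes, icd, gold, registry))) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  if (is.character(rule)) rule <- rule_preset(rule)
  structure(list(notes = notes, icd = icd, gold = gold, registry = registry,
                 backend = backend, extraction = extraction, rule = rule,
                 gap_days = gap_days, filter_method = filter_method,
                 subtype_method = subtype_method, out_dir = out_dir,
                 log_level = log_level, seed = as.integer(seed)),
            class = "pph_run_config")
}

resolve_input <- function(x, reader) {
  if (is.character(x)) reader(x) else x
}

#' Run the full extract-then-phenotype pipeline
#'
#' Stages run in order; any stage error aborts with the stage name. Outputs
#' written under `out_dir`: `notes_kept.jsonl`, `calls.jsonl`,
#' `deliveries.jsonl`, `subtypes.jsonl`, `report.csv` (when gold labels are
#' supplied), and `manifest.json`. The manifest records the config snapshot,
#' input digests, per-stage row counts, the seed, and output digests; no
#' timestamps, so a rerun of an identical config is digest-identical.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pph_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  input_digests <- list()
  for (field in c("notes", "icd", "gold", "registry")) {
    if (is.character(config[[field]])) {
      input_digests[[field]] <- unname(tools::md5sum(config[[field]]))
    }
  }

  registry <- stage("registry", {
    if (is.null(config$registry)) builtin_registry()
    else resolve_input(config$registry, read_registry)
  })
  violations <- validate_registry(registry)
  if (length(violations) > 0L) {
    stop("pipeline stage 'registry' failed: ", paste(violations, collapse = "; "))
  }
  notes <- stage("read_notes", resolve_input(config$notes, read_notes))
  notes <- stage("clean_corpus", clean_corpus(notes))
  icd <- if (!is.null(config$icd)) stage("read_icd", resolve_input(config$icd, read_icd))
  backend <- stage("backend", {
    if (identical(config$backend, "pattern")) pattern_backend(registry)
    else config$backend
  })

  notes <- stage("delivery_filter", {
    keep <- switch(config$filter_method,
      none = rep(TRUE, length(notes)),
      terms = vapply(notes, term_filter, logical(1)),
      icd = {
        if (is.null(icd)) stop("filter_method 'icd' requires an icd input")
        vapply(notes, icd_window_filter, logical(1), codes = icd)
      },
      prompt = vapply(notes, prompted_filter, logical(1), backend = backend))
    notes[keep]
  })
  write_notes(notes, file.path(config$out_dir, "notes_kept.jsonl"))

  calls <- stage("extraction",
                 extract_corpus(notes, registry, backend, config$extraction))
  call_rows <- lapply(seq_len(nrow(calls)), function(i) {
    seg <- calls$segments[[i]]
    row <- list(note_id = calls$note_id[i], concept_id = calls$concept_id[i],
                kind = calls$kind[i], label = calls$label[i],
                segments = I(if (is.null(seg)) character(0) else seg))
    if (config$log_level == "debug" && !is.null(calls$provenance[[i]])) {
      row$provenance <- calls$provenance[[i]]
    }
    row
  })
  write_table(call_rows, file.path(config$out_dir, "calls.jsonl"))

  assessments <- stage("phenotyping",
                       assess_deliveries(notes, calls, config$rule, config$gap_days))
  del_rows <- lapply(seq_len(nrow(assessments)), function(i) {
    list(delivery_id = assessments$delivery_id[i],
         patient_id = assessments$patient_id[i],
         note_ids = I(assessments$note_ids[[i]]),
         total_ebl_ml = assessments$total_ebl_ml[i],
         ebl_values = I(assessments$ebl_values[[i]]),
         mode = assessments$mode[i], pph = assessments$pph[i])
  })
  write_table(del_rows, file.path(config$out_dir, "deliveries.jsonl"))

  pph_only <- assessments[assessments$pph, ]
  subtypes <- stage("subtyping", {
    if (nrow(pph_only) == 0L) NULL
    else if (config$subtype_method == "nlp") {
      subtype_deliveries(pph_only, "nlp")
    } else if (config$subtype_method == "icd") {
      subtype_deliveries(pph_only, "icd", icd_codes = icd)
    } else {
      nlp <- subtype_deliveries(pph_only, "nlp")
      icd_st <- subtype_deliveries(pph_only, "icd", icd_codes = icd)
      nlp$method <- "nlp"; icd_st$method <- "icd"
      rbind(nlp, icd_st)
    }
  })
  st_rows <- if (is.null(subtypes)) list() else
    lapply(seq_len(nrow(subtypes)), function(i) {
      row <- list(delivery_id = subtypes$delivery_id[i],
                  tone = subtypes$tone[i], tissue = subtypes$tissue[i],
                  trauma = subtypes$trauma[i], thrombin = subtypes$thrombin[i])
      if ("method" %in% names(subtypes)) row$method <- subtypes$method[i]
      row
    })
  write_table(st_rows, file.path(config$out_dir, "subtypes.jsonl"))

  report <- NULL
  if (!is.null(config$gold)) {
    gold <- stage("read_gold", {
      if (is.character(config$gold)) read_annotations(config$gold, registry)
      else config$gold
    })
    report <- stage("evaluation", concept_report(calls, gold, registry))
    utils::write.csv(report, file.path(config$out_dir, "report.csv"),
                     row.names = FALSE)
  }

  out_files <- c("notes_kept.jsonl", "calls.jsonl", "deliveries.jsonl",
                 "subtypes.jsonl", if (!is.null(report)) "report.csv")
  manifest <- list(
    config = list(rule = config$rule$name, gap_days = config$gap_days,
                  filter_method = config$filter_method,
                  subtype_method = config$subtype_method,
                  backend = if (is.character(config$backend)) config$backend
                            else config$backend$id,
                  window_tokens = config$extraction$window_tokens,
                  overlap_tokens = config$extraction$overlap_tokens,
                  log_level = config$log_level),
    seed = config$seed,
    input_digests = input_digests,
    counts = list(notes = length(notes), calls = nrow(calls),
                  deliveries = nrow(assessments),
                  pph_deliveries = sum(assessments$pph),
                  subtype_rows = if (is.null(subtypes)) 0L else nrow(subtypes)),
    output_digests = as.list(stats::setNames(
      unname(tools::md5sum(file.path(config$out_dir, out_files))), out_files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
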