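#' Construct a note record
#'
#' A note record is one discharge summary: identifiers, a calendar date, the
#' originating hospital and department, a status flag, and the free text.
#' Notes are the unit of text that the extraction engine consumes.
#'
#' @param note_id Unique opaque identifier for the note.
#' @param patient_id Opaque patient identifier.
#' @param note_date Calendar date of the note (`Date` or ISO-8601 string).
#'   Time-of-day, if present, is discarded: downstream ICD linkage operates at
#'   day granularity.
#' @param hospital Hospital label.
#' @param status Either `"final"` or `"draft"`.
#' @param department Department label (e.g. `"obstetrics"`, `"emergency"`).
#' @param text Free text of the discharge summary.
#' @return A list of class `pph_note`.
#' @export
note_record <- function(note_id, patient_id, note_date, hospital = "unknown",
                        status = "final", department = "unknown", text = "") {
  stopifnot(is.character(note_id), length(note_id) == 1L, nzchar(note_id))
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  status <- match.arg(status, c("final", "draft"))
  date <- as.Date(note_date)
  if (is.na(date)) stop("note_date is not a parseable calendar date: ", note_date)
  structure(
    list(note_id = note_id, patient_id = patient_id, note_date = date,
         hospital = hospital, status = status, department = department,
         text = text),
    class = "pph_note"
  )
}

#' @export
print.pph_note <- function(x, ...) {
  cat(sprintf("<note %s> patient %s, %s, %s/%s, %d chars\n",
              x$note_id, x$patient_id, format(x$note_date), x$hospital,
              x$department, nchar(x$text)))
  invisible(x)
}

NOTE_FIELDS <- c("note_id", "patient_id", "note_date", "hospital",
                 "status", "department", "text")

#' Read discharge-summary notes
#'
#' Reads notes from JSON-Lines (one JSON object per line; the canonical
#' format) or CSV (header row required). Both formats carry the keys/columns
#' `note_id`, `patient_id`, `note_date`, `hospital`, `status`, `department`,
#' `text`.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @return A list of [note_record()] objects in file order.
#' @export
read_notes <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  rows <- read_rows(path, format)
  notes <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    row <- rows[[i]]
    missing <- setdiff(NOTE_FIELDS, names(row))
    if (length(missing) > 0L) {
      stop(sprintf("row %d of %s: missing required field(s): %s",
                   i, path, paste(missing, collapse = ", ")))
    }
    notes[[i]] <- note_record(as.character(row$note_id),
                              as.character(row$patient_id),
                              row$note_date,
                              as.character(row$hospital),
                              as.character(row$status),
                              as.character(row$department),
                              as.character(row$text))
  }
  ids <- vapply(notes, `[[`, character(1), "note_id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate note_id in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  notes
}

# Shared row reader for jsonl/csv; returns a list of named lists.
read_rows <- function(path, format) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(seq_along(lines), function(i) {
      tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
               error = function(e) stop(sprintf("line %d of %s: malformed JSON (%s)",
                                                i, path, conditionMessage(e))))
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
}

#' Write notes to JSON-Lines or CSV
#'
#' Dates are serialized as ISO-8601 (`YYYY-MM-DD`), so write-then-read
#' round-trips byte-stable dates.
#'
#' @param notes List of [note_record()] objects.
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_notes <- function(notes, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  rows <- lapply(notes, function(n) {
    list(note_id = n$note_id, patient_id = n$patient_id,
         note_date = format(n$note_date, "%Y-%m-%d"), hospital = n$hospital,
         status = n$status, department = n$department, text = n$text)
  })
  write_rows(rows, path, format)
}

write_rows <- function(rows, path, format) {
  if (format == "jsonl") {
    lines <- vapply(rows, function(r) {
      jsonlite::toJSON(r, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Clean a note corpus
#'
#' Applies the note-level filters used to build a study corpus: drop draft
#' notes, drop notes from excluded departments (e.g. the emergency
#' department), and de-duplicate exact-identical texts within a patient,
#' keeping the earliest note. Duplicate means exact string equality of `text`
#' within the same `patient_id`; near-duplicate detection is out of scope.
#'
#' @param notes List of [note_record()] objects.
#' @param drop_drafts Drop notes with `status == "draft"`?
#' @param drop_departments Character vector of department labels to exclude
#'   (case-insensitive).
#' @param dedupe Remove exact duplicate texts per patient (earliest
#'   `note_date` kept; ties broken by `note_id`)?
#' @return The retained notes, with a `report` attribute: a named integer
#'   vector of removal counts by reason (`draft`, `department`, `duplicate`).
#' @export
clean_corpus <- function(notes, drop_drafts = TRUE,
                         drop_departments = "emergency", dedupe = TRUE) {
  report <- c(draft = 0L, department = 0L, duplicate = 0L)
  keep <- notes
  if (drop_drafts) {
    is_draft <- vapply(keep, function(n) identical(n$status, "draft"), logical(1))
    report[["draft"]] <- sum(is_draft)
    keep <- keep[!is_draft]
  }
  if (length(drop_departments) > 0L) {
    bad <- vapply(keep, function(n) tolower(n$department) %in% tolower(drop_departments), logical(1))
    report[["department"]] <- sum(bad)
    keep <- keep[!bad]
  }
  if (dedupe && length(keep) > 0L) {
    key <- vapply(keep, function(n) paste0(n$patient_id, "\r", n$text), character(1))
    date <- as.numeric(vapply(keep, function(n) as.numeric(n$note_date), numeric(1)))
    id <- vapply(keep, `[[`, character(1), "note_id")
    ord <- order(key, date, id)
    dup <- duplicated(key[ord])
    drop_idx <- ord[dup]
    report[["duplicate"]] <- length(drop_idx)
    if (length(drop_idx) > 0L) keep <- keep[-drop_idx]
  }
  structure(keep, report = report)
}

#' Construct an ICD/DRG code record
#'
#' @param patient_id Opaque patient identifier.
#' @param code Dotted code string (e.g. `"666.14"`).
#' @param code_date Calendar date the code was recorded.
#' @param vocabulary `"ICD9"`, `"ICD10"`, or `"DRG"`. Always explicit; never
#'   inferred from the code's shape.
#' @return A list of class `pph_icd`.
#' @export
icd_record <- function(patient_id, code, code_date, vocabulary = c("ICD9", "ICD10", "DRG")) {
  vocabulary <- match.arg(vocabulary)
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  date <- as.Date(code_date)
  if (is.na(date)) stop("code_date is not a parseable calendar date: ", code_date)
  structure(list(patient_id = as.character(patient_id), code = code,
                 code_date = date, vocabulary = vocabulary),
            class = "pph_icd")
}

#' Read an ICD code table
#'
#' CSV with columns `patient_id`, `code`, `code_date`, `vocabulary`.
#'
#' @param path File path.
#' @return List of [icd_record()] objects in file order.
#' @export
read_icd <- function(path) {
  rows <- read_rows(path, "csv")
  lapply(seq_along(rows), function(i) {
    row <- rows[[i]]
    missing <- setdiff(c("patient_id", "code", "code_date", "vocabulary"), names(row))
    if (length(missing) > 0L) {
      stop(sprintf("row %d of %s: missing required field(s): %s",
                   i, path, paste(missing, collapse = ", ")))
    }
    icd_record(row$patient_id, row$code, row$code_date, row$vocabulary)
  })
}

#' Write an ICD code table to CSV
#' @param codes List of [icd_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_icd <- function(codes, path) {
  rows <- lapply(codes, function(r) {
    list(patient_id = r$patient_id, code = r$code,
         code_date = format(r$code_date, "%Y-%m-%d"), vocabulary = r$vocabulary)
  })
  write_rows(rows, path, "csv")
}

#' Construct a gold annotation
#'
#' Exactly one of `label` (binary concepts) or `values` (the measurement
#' concept, normalized mL values) is populated, according to the concept's
#' kind in the registry.
#'
#' @param note_id Note identifier.
#' @param concept_id Concept identifier; must exist in the registry used for
#'   validation.
#' @param label Logical scalar, for binary concepts.
#' @param values Numeric vector of normalized mL values, for the measurement
#'   concept (may be empty).
#' @return A list of class `pph_gold`.
#' @export
gold_annotation <- function(note_id, concept_id, label = NULL, values = NULL) {
  if (is.null(label) == is.null(values)) {
    stop("exactly one of `label` or `values` must be supplied for concept ",
         concept_id)
  }
  if (!is.null(label)) stopifnot(is.logical(label), length(label) == 1L, !is.na(label))
  if (!is.null(values)) values <- sort(unique(as.numeric(values)))
  structure(list(note_id = as.character(note_id),
                 concept_id = as.character(concept_id),
                 label = label, values = values),
            class = "pph_gold")
}

#' Read gold annotations
#'
#' JSON-Lines with keys `note_id`, `concept_id`, and either `label` or
#' `values`. Every `concept_id` must be present in `registry`.
#'
#' @param path File path.
#' @param registry Concept registry used to validate `concept_id`s; default
#'   [builtin_registry()].
#' @return List of [gold_annotation()] objects.
#' @export
read_annotations <- function(path, registry = builtin_registry()) {
  known <- vapply(registry, `[[`, character(1), "concept_id")
  rows <- read_rows(path, "jsonl")
  lapply(seq_along(rows), function(i) {
    row <- rows[[i]]
    if (is.null(row$note_id) || is.null(row$concept_id)) {
      stop(sprintf("line %d of %s: missing note_id or concept_id", i, path))
    }
    if (!(row$concept_id %in% known)) {
      stop(sprintf("line %d of %s: unknown concept_id '%s'", i, path, row$concept_id))
    }
    gold_annotation(row$note_id, row$concept_id,
                    label = if (!is.null(row$label)) as.logical(row$label),
                    values = row$values)
  })
}

#' Write gold annotations to JSON-Lines
#' @param annotations List of [gold_annotation()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  lines <- vapply(annotations, function(a) {
    row <- list(note_id = a$note_id, concept_id = a$concept_id)
    if (!is.null(a$label)) row$label <- a$label else row$values <- I(a$values)
    jsonlite::toJSON(row, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a generic table of rows
#'
#' Convenience writer for stage outputs: a list of named lists (or a data
#' frame) written as JSON-Lines or CSV.
#'
#' @param rows List of named lists, or a data frame.
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (is.data.frame(rows)) rows <- lapply(seq_len(nrow(rows)), function(i) as.list(rows[i, ]))
  write_rows(rows, path, format)
}
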