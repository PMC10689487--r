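#' Extraction engine configuration
#'
#' Defaults mirror a sliding-window zero-shot setup for an instruction-tuned
#' text-to-text model: 512-token windows with a 128-token overlap (step =
#' window - overlap = 384), greedy decoding, at most 5 new tokens, temperature
#' 1.0, batch size 48. Only the windowing fields affect the pattern and mock
#' backends; the decoding fields are forwarded to generative backends.
#'
#' @param window_tokens Window width in tokens (> 0).
#' @param overlap_tokens Overlap between consecutive windows (>= 0, <
#'   `window_tokens`).
#' @param max_new_tokens Decoding budget for generative backends.
#' @param decode_mode Only `"greedy"` is supported.
#' @param temperature Decoding temperature forwarded to generative backends.
#' @param batch_size Chunk batch size hint for generative backends.
#' @return A list of class `pph_config`.
#' @export
extraction_config <- function(window_tokens = 512L, overlap_tokens = 128L,
                              max_new_tokens = 5L, decode_mode = "greedy",
                              temperature = 1.0, batch_size = 48L) {
  decode_mode <- match.arg(decode_mode, "greedy")
  window_tokens <- as.integer(window_tokens)
  overlap_tokens <- as.integer(overlap_tokens)
  stopifnot(window_tokens > 0L, overlap_tokens >= 0L)
  if (overlap_tokens >= window_tokens) {
    stop("overlap_tokens must be smaller than window_tokens")
  }
  structure(list(window_tokens = window_tokens, overlap_tokens = overlap_tokens,
                 max_new_tokens = as.integer(max_new_tokens),
                 decode_mode = decode_mode, temperature = temperature,
                 batch_size = as.integer(batch_size)),
            class = "pph_config")
}

#' Tokenize text with character offsets
#'
#' The default scheme splits on whitespace and punctuation: runs of
#' alphanumerics form one token, every other non-space character is its own
#' token. Offsets are 1-based inclusive character positions into the original
#' string, so `substring(text, start, end)` reproduces each token exactly.
#' The tokenizer is a pluggable contract: any function returning a data frame
#' with columns `token`, `start`, `end` may replace it (e.g. a model-specific
#' subword tokenizer for a generative backend).
#'
#' @param text A string.
#' @return A data frame with columns `token`, `start`, `end` (zero rows for
#'   empty/blank text).
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(token = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(token = substring(text, starts, starts + lens - 1L),
             start = starts, end = starts + lens - 1L,
             stringsAsFactors = FALSE)
}

#' Split a note into overlapping token windows
#'
#' With step = `window_tokens - overlap_tokens`, chunk *i* covers tokens
#' `[i * step, min(i * step + window, n))` (0-based, half-open); generation
#' stops once a chunk reaches the last token, so a note with at most
#' `window_tokens` tokens yields exactly one chunk and an empty note yields
#' none. Chunk text is the substring spanning the chunk's tokens, so matter
#' between tokens (whitespace) is preserved inside a chunk.
#'
#' @param note A [note_record()] (or any list with `note_id` and `text`).
#' @param config An [extraction_config()].
#' @param tokenizer Tokenizing function; defaults to [tokenize()].
#' @return A list of chunks, each a list with `note_id`, `index` (0-based),
#'   `token_start`, `token_end` (0-based half-open), and `text`.
#' @export
chunk_note <- function(note, config = extraction_config(), tokenizer = tokenize) {
  toks <- tokenizer(note$text)
  n <- nrow(toks)
  if (n == 0L) return(list())
  window <- config$window_tokens
  step <- window - config$overlap_tokens
  chunks <- list()
  i <- 0L
  repeat {
    s <- i * step
    e <- min(s + window, n)
    chunks[[length(chunks) + 1L]] <- list(
      note_id = note$note_id, index = i, token_start = s, token_end = e,
      text = substring(note$text, toks$start[s + 1L], toks$end[e]))
    if (e >= n) break
    i <- i + 1L
  }
  chunks
}

#' Parse a yes/no backend response
#'
#' Case-insensitive; leading non-letter characters are stripped; a response
#' beginning "yes" is positive, beginning "no" is negative, anything else is
#' unparseable. Unparseable responses count as negative under aggregation
#' (conservative: avoids inflating positives).
#'
#' @param response A response string (or a backend response list with a
#'   `generated_text` field).
#' @return One of `"positive"`, `"negative"`, `"unparseable"`.
#' @export
parse_yes_no <- function(response) {
  text <- if (is.list(response)) response$generated_text else response
  if (is.null(text) || is.na(text)) return("unparseable")
  text <- tolower(sub("^[^A-Za-z]*", "", text))
  if (startsWith(text, "yes")) return("positive")
  if (startsWith(text, "no")) return("negative")
  "unparseable"
}

query_backend <- function(backend, prompt, context) {
  out <- tryCatch(backend$respond(prompt, context),
                  error = function(e) {
                    stop(sprintf("backend '%s' failed on note %s, chunk %d, prompt %d: %s",
                                 backend$id, context$note_id, context$chunk_index,
                                 context$prompt_index, conditionMessage(e)),
                         call. = FALSE)
                  })
  if (!is.character(out) || length(out) != 1L || is.na(out)) {
    stop(sprintf("backend '%s' returned a non-string response on note %s, chunk %d",
                 backend$id, context$note_id, context$chunk_index))
  }
  out
}

#' Run one binary concept over one note
#'
#' Every (chunk x prompt) pair is queried; the note-level label is the OR over
#' all parsed outcomes — a concept is present if any chunk under any of its
#' chained prompts parses positive. Full per-chunk provenance is recorded.
#' A backend failure on any chunk is a hard error (phenotyping on silently
#' partial extractions is unsafe).
#'
#' @param note A [note_record()].
#' @param concept A binary [concept_spec()].
#' @param backend A backend (see [pattern_backend()], [mock_backend()]).
#' @param config An [extraction_config()].
#' @return A list of class `pph_call` with `note_id`, `concept_id`, `label`,
#'   and a `per_chunk` provenance data frame (`chunk_index`, `prompt_index`,
#'   `response`, `outcome`).
#' @export
run_binary_concept <- function(note, concept, backend, config = extraction_config()) {
  stopifnot(concept$kind == "binary")
  chunks <- chunk_note(note, config)
  prov <- list()
  for (ch in chunks) {
    for (pi in seq_along(concept$prompts)) {
      prompt <- render_prompt(concept$prompts[[pi]], ch$text)
      ctx <- list(note_id = note$note_id, concept = concept, chunk_text = ch$text,
                  chunk_index = ch$index, prompt_index = pi)
      resp <- query_backend(backend, prompt, ctx)
      prov[[length(prov) + 1L]] <- data.frame(
        chunk_index = ch$index, prompt_index = pi, response = resp,
        outcome = parse_yes_no(resp), stringsAsFactors = FALSE)
    }
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(chunk_index = integer(0), prompt_index = integer(0),
               response = character(0), outcome = character(0))
  structure(list(note_id = note$note_id, concept_id = concept$concept_id,
                 kind = "binary", label = any(prov$outcome == "positive"),
                 segments = NULL, per_chunk = prov),
            class = "pph_call")
}

# Fallback token a generative backend emits when a chunk holds no answer.
UNANSWERABLE <- "unanswerable"

#' Run the measurement concept over one note
#'
#' Each chunk's generated text is whitespace-trimmed; responses equal to the
#' fallback token `"unanswerable"` (case-insensitive) or empty are dropped;
#' the remaining segments are unioned as a set across chunks and prompts.
#'
#' @inheritParams run_binary_concept
#' @param concept The measurement [concept_spec()].
#' @return A `pph_call` with `segments` (character vector, possibly empty)
#'   instead of `label`.
#' @export
run_extraction_concept <- function(note, concept, backend, config = extraction_config()) {
  stopifnot(concept$kind == "measurement")
  chunks <- chunk_note(note, config)
  prov <- list()
  segments <- character(0)
  for (ch in chunks) {
    for (pi in seq_along(concept$prompts)) {
      prompt <- render_prompt(concept$prompts[[pi]], ch$text)
      ctx <- list(note_id = note$note_id, concept = concept, chunk_text = ch$text,
                  chunk_index = ch$index, prompt_index = pi)
      resp <- query_backend(backend, prompt, ctx)
      seg <- trimws(resp)
      keep <- nzchar(seg) && tolower(seg) != UNANSWERABLE
      if (keep) segments <- union(segments, seg)
      prov[[length(prov) + 1L]] <- data.frame(
        chunk_index = ch$index, prompt_index = pi, response = resp,
        outcome = if (keep) "segment" else "unanswerable",
        stringsAsFactors = FALSE)
    }
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(chunk_index = integer(0), prompt_index = integer(0),
               response = character(0), outcome = character(0))
  structure(list(note_id = note$note_id, concept_id = concept$concept_id,
                 kind = "measurement", label = NULL, segments = segments,
                 per_chunk = prov),
            class = "pph_call")
}

#' Run every registry concept over a corpus
#'
#' Convenience driver: applies [run_binary_concept()] /
#' [run_extraction_concept()] per (note, concept) and collects the calls into
#' a tibble.
#'
#' @param notes List of [note_record()]s.
#' @param registry Concept registry; default [builtin_registry()].
#' @param backend A backend.
#' @param config An [extraction_config()].
#' @param concepts Optional character vector restricting the concepts run.
#' @param keep_provenance Keep the per-chunk provenance as a list column?
#'   (Default `TRUE`; set `FALSE` to save memory on large corpora.)
#' @return A tibble with columns `note_id`, `concept_id`, `kind`, `label`
#'   (NA for the measurement concept), `segments` (list column), and
#'   optionally `provenance` (list column).
#' @export
extract_corpus <- function(notes, registry = builtin_registry(), backend,
                           config = extraction_config(), concepts = NULL,
                           keep_provenance = TRUE) {
  if (!is.null(concepts)) registry <- registry[concepts]
  rows <- vector("list", length(notes) * length(registry))
  k <- 0L
  for (note in notes) {
    for (spec in registry) {
      call <- if (spec$kind == "binary") {
        run_binary_concept(note, spec, backend, config)
      } else {
        run_extraction_concept(note, spec, backend, config)
      }
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        note_id = call$note_id, concept_id = call$concept_id, kind = call$kind,
        label = if (is.null(call$label)) NA else call$label,
        segments = list(call$segments),
        provenance = if (keep_provenance) list(call$per_chunk) else list(NULL))
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  if (!keep_provenance) out$provenance <- NULL
  out
}
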