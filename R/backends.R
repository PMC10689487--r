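#' @title Extraction backends
#' @description A backend is the component that answers one rendered prompt
#'   for one text chunk. Backends are pluggable: the pattern backend answers
#'   from the concept's regular expressions, the mock backend replays planted
#'   truth (optionally corrupted at a flip rate) for testing, and the
#'   generative backend adapts an external instruction-tuned text-to-text
#'   model endpoint. All are lists of class `pph_backend` with fields `id`
#'   and `respond(prompt, context)`; `context` carries `note_id`, `concept`,
#'   `chunk_text`, `chunk_index`, `prompt_index`.
#' @name backends
NULL

new_backend <- function(id, respond) {
  structure(list(id = id, respond = respond), class = "pph_backend")
}

#' @export
print.pph_backend <- function(x, ...) {
  cat(sprintf("<pph backend: %s>\n", x$id))
  invisible(x)
}

#' Pattern-matching backend
#'
#' A deterministic baseline that ignores the prompt text and answers from the
#' concept's pattern set: `"yes"`/`"no"` for binary concepts (any pattern
#' matching the chunk, case-insensitive), and for the measurement concept the
#' first capture-group match (the numeric span) or `"unanswerable"`.
#'
#' @param registry Concept registry; every concept must have at least one
#'   pattern (checked at construction).
#' @return A `pph_backend`.
#' @export
pattern_backend <- function(registry = builtin_registry()) {
  for (s in registry) {
    if (length(s$patterns) == 0L) {
      stop("concept without patterns: ", s$concept_id)
    }
  }
  new_backend("pattern", function(prompt, context) {
    concept <- context$concept
    if (concept$kind == "binary") {
      hit <- any(vapply(concept$patterns, function(p) {
        grepl(p, context$chunk_text, perl = TRUE, ignore.case = TRUE)
      }, logical(1)))
      if (hit) "yes" else "no"
    } else {
      for (p in concept$patterns) {
        m <- regexpr(p, context$chunk_text, perl = TRUE, ignore.case = TRUE)
        if (m[1] != -1L) {
          cs <- attr(m, "capture.start")
          if (!is.null(cs) && cs[1] > 0L) {
            cl <- attr(m, "capture.length")
            return(substring(context$chunk_text, cs[1], cs[1] + cl[1] - 1L))
          }
          return(substring(context$chunk_text, m[1], m[1] + attr(m, "match.length") - 1L))
        }
      }
      UNANSWERABLE
    }
  })
}

#' Mock backend replaying planted truth
#'
#' A test double: answers each call from a planted truth table, flipping each
#' answer independently with probability `flip_rate` under a private seeded
#' generator (call-by-call deterministic given `seed`, and isolated from the
#' global RNG). A flipped binary answer is inverted; a flipped measurement
#' answer becomes `"unanswerable"` (and a flipped empty answer becomes the
#' planted segment, when one exists, or stays unanswerable).
#'
#' @param truth A data frame with columns `note_id`, `concept_id`, and
#'   `label` (logical, binary concepts) and/or `segment` (character,
#'   measurement concept; `NA` for none).
#' @param flip_rate Probability in `[0, 1)` of corrupting each call.
#' @param seed Integer seed for the private generator.
#' @return A `pph_backend`. Unknown (note, concept) pairs are an error.
#' @export
mock_backend <- function(truth, flip_rate = 0, seed = 1L) {
  stopifnot(is.data.frame(truth), flip_rate >= 0, flip_rate < 1)
  stopifnot(all(c("note_id", "concept_id") %in% names(truth)))
  key <- paste(truth$note_id, truth$concept_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (note_id, concept_id) in mock truth")
  idx <- seq_len(nrow(truth))
  names(idx) <- key
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  draw <- function() {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(env$state)) set.seed(seed) else
      assign(".Random.seed", env$state, envir = globalenv())
    u <- stats::runif(1)
    env$state <- get(".Random.seed", globalenv())
    u
  }
  new_backend("mock", function(prompt, context) {
    k <- paste(context$note_id, context$concept$concept_id, sep = "\r")
    i <- unname(idx[k])
    if (is.na(i)) {
      stop("mock backend has no planted truth for note ", context$note_id,
           ", concept ", context$concept$concept_id)
    }
    flip <- flip_rate > 0 && draw() < flip_rate
    if (context$concept$kind == "binary") {
      lab <- isTRUE(truth$label[i])
      if (flip) lab <- !lab
      if (lab) "yes" else "no"
    } else {
      seg <- if ("segment" %in% names(truth)) truth$segment[i] else NA_character_
      has <- !is.na(seg) && nzchar(seg)
      if (flip) {
        if (has) UNANSWERABLE else UNANSWERABLE
      } else {
        if (has) seg else UNANSWERABLE
      }
    }
  })
}

#' Generative-model backend adapter
#'
#' Adapter for an external instruction-tuned text-to-text model endpoint.
#' The adapter sends the fully rendered prompt and requests greedy decoding
#' with `max_new_tokens` and `temperature` from the extraction config. No
#' model ships with this package: the caller supplies `generate_fn`, a
#' function `(prompt, params) -> character(1)` wrapping their serving stack;
#' construction fails with an installation hint otherwise. The backend never
#' silently degrades to another backend.
#'
#' @param endpoint A list describing the endpoint; recognised fields:
#'   `model` (label) and `max_context_tokens` (prompt-length guard; prompts
#'   longer than this are an error, since upstream chunking should prevent
#'   them).
#' @param config An [extraction_config()]; decoding fields are forwarded on
#'   every call as `params`.
#' @param generate_fn The user-supplied generation function.
#' @return A `pph_backend`.
#' @export
generative_backend <- function(endpoint = list(model = NULL,
                                               max_context_tokens = NULL),
                               config = extraction_config(),
                               generate_fn = NULL) {
  if (is.null(generate_fn)) {
    stop("no generative model adapter is available: supply `generate_fn`, a ",
         "function(prompt, params) wrapping your model server (e.g. an ",
         "httr/curl call to a local text-generation endpoint)")
  }
  stopifnot(is.function(generate_fn))
  params <- list(decode_mode = config$decode_mode,
                 max_new_tokens = config$max_new_tokens,
                 temperature = config$temperature,
                 batch_size = config$batch_size,
                 model = endpoint$model)
  new_backend(paste0("generative:", endpoint$model %||% "unknown"),
              function(prompt, context) {
    limit <- endpoint$max_context_tokens
    if (!is.null(limit) && nrow(tokenize(prompt)) > limit) {
      stop("rendered prompt exceeds the model context of ", limit,
           " tokens; reduce window_tokens so chunks fit")
    }
    generate_fn(prompt, params)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
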