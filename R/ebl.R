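#' @title Estimated blood loss (EBL) post-processing
#' @description Clinicians document blood loss in heterogeneous free-text
#'   forms: "800 cc", "EBL 1.5 L", bare numbers, or corrupted concatenations
#'   like "500ccf/b". This module parses numeric mentions out of extracted
#'   segments, normalizes them to milliliters (single-digit values are read
#'   as liters), de-duplicates repeated values within a note (repeated equal
#'   values are taken to restate the same loss, not separate events), and
#'   sums the remainder.
#' @name ebl
NULL

EBL_NUMBER_RE <- "[0-9]{1,3}(?:,[0-9]{3})+(?:\\.[0-9]+)?|[0-9]*\\.[0-9]+|[0-9]+"

# Unit token adjoining the number (optionally after one space). ml/cc may be
# concatenated into a longer letter run ("500ccf/b"); a bare "l" must not be
# followed by another letter so "lbs"/"lac" never read as liters.
sniff_unit <- function(tail) {
  tail <- sub("^ ", "", tail)
  low <- tolower(tail)
  if (grepl("^(milliliters|milliliter|millilitres|millilitre|mls|ml|cc)", low)) {
    return(if (startsWith(low, "cc")) "cc" else "ml")
  }
  if (grepl("^(liters|liter|litres|litre)", low)) return("l")
  if (grepl("^l($|[^a-z])", low)) return("l")
  "none"
}

#' Parse EBL mentions out of extracted segments
#'
#' Every maximal numeric token (integer or decimal, optional comma thousands
#' separators) in each segment yields one mention; a unit token adjoining the
#' number (ml, cc, l, liters, milliliters — case-insensitive, possibly
#' concatenated as in "800cc") sets the unit hint. Non-numeric segments yield
#' nothing. A numeric range like "400-600" parses to two mentions.
#'
#' @param segments Character vector of extracted segments (a set; order
#'   irrelevant).
#' @return A data frame with columns `raw` (source segment), `value`
#'   (non-negative number), `unit_hint` (`"ml"`, `"cc"`, `"l"`, `"none"`).
#' @export
parse_ebl_mentions <- function(segments) {
  out <- list()
  for (seg in segments) {
    if (is.na(seg) || !nzchar(seg)) next
    m <- gregexpr(EBL_NUMBER_RE, seg, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (j in seq_along(starts)) {
      numtext <- substring(seg, starts[j], starts[j] + lens[j] - 1L)
      value <- as.numeric(gsub(",", "", numtext, fixed = TRUE))
      tail <- substring(seg, starts[j] + lens[j])
      out[[length(out) + 1L]] <- data.frame(
        raw = seg, value = value, unit_hint = sniff_unit(tail),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(raw = character(0), value = numeric(0),
                      unit_hint = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Normalize an EBL value to milliliters
#'
#' Liters convert by x1000; ml/cc pass through; a unit-less value below 10 is
#' read as liters and converted (no plausible delivery blood loss is under
#' 10 mL, and none is over 10 L, so the boundary is safe for decimals like
#' "1.5" as well as the literal single digits); a unit-less value of 10 or
#' more is assumed to already be milliliters.
#'
#' @param value Non-negative numeric vector.
#' @param unit_hint Character vector in `{"ml", "cc", "l", "none"}` (recycled).
#' @return Numeric vector of values in mL. Monotone non-decreasing in `value`
#'   within each unit class.
#' @export
normalize_to_ml <- function(value, unit_hint = "none") {
  stopifnot(all(value >= 0))
  if (length(value) == 0L) return(numeric(0))
  n <- max(length(value), length(unit_hint))
  value <- rep_len(as.numeric(value), n)
  unit_hint <- rep_len(unit_hint, n)
  out <- value
  out[unit_hint == "l"] <- value[unit_hint == "l"] * 1000
  bare <- !(unit_hint %in% c("l", "ml", "cc"))
  out[bare & value < 10] <- value[bare & value < 10] * 1000
  out
}

#' Summarize EBL mentions for one note (or delivery)
#'
#' Normalizes each mention to mL, collapses equal normalized values to a
#' single instance (repeated identical values are multiple mentions of the
#' same loss), and totals the remainder. Permutation-invariant and idempotent
#' on its collapsed output.
#'
#' @param mentions A data frame from [parse_ebl_mentions()], or a numeric
#'   vector of already-normalized mL values.
#' @return A list of class `pph_ebl` with `values_ml` (sorted distinct
#'   normalized values) and `total_ml` (their sum).
#' @export
summarize_ebl <- function(mentions) {
  values <- if (is.data.frame(mentions)) {
    normalize_to_ml(mentions$value, mentions$unit_hint)
  } else {
    as.numeric(mentions)
  }
  values <- sort(unique(values))
  structure(list(values_ml = values, total_ml = sum(values)), class = "pph_ebl")
}

#' @export
print.pph_ebl <- function(x, ...) {
  cat(sprintf("<ebl> values: {%s} mL, total %g mL\n",
              paste(x$values_ml, collapse = ", "), x$total_ml))
  invisible(x)
}
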