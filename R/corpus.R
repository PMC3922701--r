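#' Build a comment corpus
#'
#' A corpus is a tibble with one row per comment and columns `id` (unique
#' string), `text` (raw, unprocessed), `key` (sampling key in `[0, 1)`,
#' `NA` until assigned) and `source_tag` (free string recording e.g. the
#' search query that retrieved the comment). Text is stored exactly as
#' ingested; all normalisation happens downstream.
#'
#' @param id Character vector of unique comment ids.
#' @param text Character vector of raw comment texts.
#' @param key Optional numeric sampling keys in `[0, 1)`; default `NA`.
#' @param source_tag Optional character source labels; default `""`.
#' @return A tibble of class `toxitext_corpus`.
#' @export
corpus <- function(id, text, key = NA_real_, source_tag = "") {
  stopifnot(is.character(id), is.character(text), length(id) == length(text))
  if (anyDuplicated(id)) {
    stop("comment ids must be unique", call. = FALSE)
  }
  out <- tibble::tibble(
    id = id,
    text = text,
    key = as.numeric(key),
    source_tag = as.character(source_tag)
  )
  bad_key <- !is.na(out$key) & (out$key < 0 | out$key >= 1)
  if (any(bad_key)) {
    stop("sampling keys must lie in [0, 1)", call. = FALSE)
  }
  class(out) <- c("toxitext_corpus", class(out))
  out
}

as_corpus <- function(df) {
  corpus(
    id = as.character(df$id),
    text = as.character(df$text),
    key = if ("key" %in% names(df)) as.numeric(df$key) else NA_real_,
    source_tag = if ("source_tag" %in% names(df)) df$source_tag else ""
  )
}

#' Read a JSON-lines comment corpus
#'
#' One JSON object per line with fields `id` and `text` (required) and
#' `key`, `source_tag` (optional). Malformed lines are skipped and counted
#' with a warning; if more than 10% of non-empty lines are malformed the
#' file is rejected outright, since that signals the wrong file rather than
#' isolated corruption.
#'
#' @param path Path to a JSON-lines file.
#' @return A corpus tibble; the number of skipped lines is attached as
#'   attribute `n_malformed`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) {
    stop("corpus file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- corpus(character(), character())
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  parsed <- lapply(lines, function(ln) {
    rec <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
    if (is.null(rec) || is.null(rec$id) || is.null(rec$text)) {
      return(NULL)
    }
    list(
      id = as.character(rec$id),
      text = as.character(rec$text),
      key = if (is.null(rec$key)) NA_real_ else as.numeric(rec$key),
      source_tag = if (is.null(rec$source_tag)) "" else as.character(rec$source_tag)
    )
  })
  ok <- !vapply(parsed, is.null, logical(1))
  n_bad <- sum(!ok)
  if (n_bad > 0.1 * length(lines)) {
    stop(
      sprintf(
        "%d of %d lines malformed (>10%%); refusing to read %s",
        n_bad, length(lines), path
      ),
      call. = FALSE
    )
  }
  if (n_bad > 0) {
    warning(sprintf("skipped %d malformed line(s) in %s", n_bad, path),
      call. = FALSE
    )
  }
  recs <- parsed[ok]
  out <- corpus(
    id = vapply(recs, `[[`, character(1), "id"),
    text = vapply(recs, `[[`, character(1), "text"),
    key = vapply(recs, `[[`, numeric(1), "key"),
    source_tag = vapply(recs, `[[`, character(1), "source_tag")
  )
  attr(out, "n_malformed") <- n_bad
  out
}

#' Write a corpus as JSON-lines
#'
#' Sampling keys are emitted as 16-digit decimal strings so that a written
#' key re-parses to the identical double (no float round-trip drift).
#'
#' @param x A corpus tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    key <- x$key[i]
    rec <- list(
      id = x$id[i],
      text = x$text[i],
      source_tag = x$source_tag[i]
    )
    body <- jsonlite::toJSON(rec, auto_unbox = TRUE)
    if (!is.na(key)) {
      # splice the key in as a raw 16-digit literal
      body <- sub("\\}$", sprintf(",\"key\":%.16f}", key), body)
    }
    as.character(body)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Assign reproducible sampling keys
#'
#' Every comment receives an i.i.d. Uniform(0, 1) key rounded to 16 decimal
#' digits, mirroring the scheme in which each record is tagged with a
#' 16-digit random key at ingest so that the same random subset can be drawn
#' repeatedly as the corpus grows. Keys are a pure function of the corpus
#' order and the seed.
#'
#' @param x A corpus tibble.
#' @param seed Integer seed.
#' @return The corpus with its `key` column filled in.
#' @export
assign_keys <- function(x, seed) {
  stopifnot(length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  # canonicalise through the 16-digit decimal form so the stored double is
  # exactly the parse of its own serialisation
  x$key <- as.numeric(sprintf("%.16f", stats::runif(nrow(x))))
  x
}

#' Draw the key-range sample of a corpus
#'
#' Returns exactly the comments whose key falls in the half-open interval
#' `[lo, hi)`. Because keys are stored with the comments, the same range
#' always returns the identical subset, even after more comments are added.
#' `[0, f)` draws a fraction-`f` sample; arbitrary sub-intervals such as
#' `[0.1, 0.2)` draw disjoint 10% samples.
#'
#' @param x A corpus with keys assigned.
#' @param lo,hi Range bounds, `0 <= lo < hi <= 1`.
#' @return The sub-corpus with `lo <= key < hi`, in original order.
#' @export
sample_by_key <- function(x, lo = 0, hi = 1) {
  if (!(is.numeric(lo) && is.numeric(hi) && lo >= 0 && hi <= 1 && lo < hi)) {
    stop("need 0 <= lo < hi <= 1", call. = FALSE)
  }
  if (anyNA(x$key)) {
    stop("corpus has unassigned keys; call assign_keys() first", call. = FALSE)
  }
  x[x$key >= lo & x$key < hi, ]
}

#' De-duplicate a corpus by exact text match
#'
#' Texts are compared after Unicode NFC normalisation, within each
#' `source_tag`; the first occurrence is kept. Fuzzy near-duplicate
#' detection is deliberately out of scope.
#'
#' @param x A corpus tibble.
#' @return The de-duplicated corpus.
#' @export
dedup_corpus <- function(x) {
  norm <- stringi::stri_trans_nfc(x$text)
  keep <- !duplicated(paste0(x$source_tag, "\r", norm))
  x[keep, ]
}
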