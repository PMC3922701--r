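#' Load the bundled stopword lists
#'
#' Three standard lists (English, French, Spanish) plus a custom list of
#' punctuation-elision variants ("dont", "im", ...) and internet
#' abbreviations ("lol", "jk", "ftw", ...). All lists ship as plain text in
#' the package so no download is ever needed. A different directory with
#' the same file layout can be supplied.
#'
#' @param dir Directory holding `english.txt`, `french.txt`, `spanish.txt`
#'   and `custom.txt`, one lowercase word per line, `#` comments allowed.
#' @return A list with character-vector elements `standard` and `custom`.
#' @export
load_stopwords <- function(dir = system.file("extdata", "stopwords",
                             package = "toxitext"
                           )) {
  read_list <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) stop("missing stopword file: ", path, call. = FALSE)
    x <- readLines(path, warn = FALSE, encoding = "UTF-8")
    x <- trimws(x)
    x <- x[nzchar(x) & !startsWith(x, "#")]
    tolower(x)
  }
  list(
    standard = unique(c(
      read_list("english.txt"), read_list("french.txt"),
      read_list("spanish.txt")
    )),
    custom = unique(read_list("custom.txt"))
  )
}

all_stopwords <- function(stopwords) {
  if (is.character(stopwords)) {
    return(stopwords)
  }
  unique(c(stopwords$standard, stopwords$custom))
}

#' Normalise raw comment text
#'
#' Applies, in order: removal of every character that cannot be encoded in
#' ASCII; removal (or replacement by space) of non-alphanumeric ASCII
#' characters; case-folding to lowercase. With `punct = "delete"` (the
#' default) punctuation inside words is deleted, so "don't" becomes "dont"
#' and "drunk-high" becomes "drunkhigh" — the behaviour that produces the
#' characteristic fused tokens seen in noisy comment corpora. Use
#' `punct = "space"` to split at punctuation instead.
#'
#' @param text Character vector of raw texts.
#' @param punct Either "delete" or "space".
#' @return Character vector of normalised texts (lowercase alphanumerics
#'   and spaces only).
#' @export
normalize_text <- function(text, punct = c("delete", "space")) {
  punct <- match.arg(punct)
  x <- iconv(text, from = "UTF-8", to = "ASCII", sub = "")
  x[is.na(x)] <- ""
  repl <- if (punct == "delete") "" else " "
  x <- gsub("[^A-Za-z0-9 \t\r\n]", repl, x)
  tolower(x)
}

#' Tokenize normalised text
#'
#' Splits on whitespace and removes stopwords. With `strip_numbers = TRUE`
#' all digits are deleted from tokens (and purely numeric tokens dropped);
#' this is applied only after dose extraction, which needs the digits, when
#' comments are pooled by plateau.
#'
#' @param text Character vector of already-normalised texts.
#' @param stopwords Stopword list from [load_stopwords()] (or a plain
#'   character vector).
#' @param strip_numbers Remove digits from tokens?
#' @return A list of character vectors, one per input text.
#' @export
tokenize <- function(text, stopwords = load_stopwords(),
                     strip_numbers = FALSE) {
  sw <- all_stopwords(stopwords)
  lapply(strsplit(text, "[ \t\r\n]+"), function(tok) {
    tok <- tok[nzchar(tok)]
    tok <- tok[!(tok %in% sw)]
    if (strip_numbers) {
      tok <- gsub("[0-9]", "", tok)
      tok <- tok[nzchar(tok)]
      tok <- tok[!(tok %in% sw)]
    }
    tok
  })
}

#' Tokenize a whole corpus
#'
#' Convenience wrapper: normalises and tokenizes every comment, keeping the
#' comment id alongside its token list.
#'
#' @inheritParams tokenize
#' @param x A corpus tibble.
#' @param punct Punctuation policy, see [normalize_text()].
#' @return A tibble with columns `id` and `tokens` (list-column).
#' @export
tokenize_corpus <- function(x, stopwords = load_stopwords(),
                            strip_numbers = FALSE,
                            punct = c("delete", "space")) {
  tibble::tibble(
    id = x$id,
    tokens = tokenize(normalize_text(x$text, punct = punct),
      stopwords = stopwords, strip_numbers = strip_numbers
    )
  )
}

#' Histogram of comment lengths in words
#'
#' Counts comments per half-open word-count bin `[k*b, (k+1)*b)`. The
#' conventional view of short-comment corpora uses a bin size of 9 words.
#'
#' @param tokenized Tibble from [tokenize_corpus()].
#' @param bin_size Bin width in words (>= 1).
#' @return A tibble with columns `bin_lo`, `bin_hi`, `n`; empty input gives
#'   an empty histogram.
#' @export
word_count_histogram <- function(tokenized, bin_size = 9) {
  stopifnot(bin_size >= 1)
  lengths <- vapply(tokenized$tokens, length, integer(1))
  bin_histogram(lengths, bin_size)
}

# shared half-open binning for word-count and dose histograms
bin_histogram <- function(values, bin_width) {
  if (length(values) == 0) {
    return(tibble::tibble(
      bin_lo = numeric(), bin_hi = numeric(),
      n = integer()
    ))
  }
  lo <- floor(values / bin_width) * bin_width
  tab <- table(lo)
  tibble::tibble(
    bin_lo = as.numeric(names(tab)),
    bin_hi = as.numeric(names(tab)) + bin_width,
    n = as.integer(tab)
  )
}
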