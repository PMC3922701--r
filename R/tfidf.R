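#' Bag-of-words term vector
#'
#' Raw term counts over a token list, the document representation in which
#' each distinct word is one dimension and repeated words lengthen the
#' vector: "dogs run and dogs run" (stopword "and" removed) has exactly
#' twice the Euclidean norm of "cats run".
#'
#' @param tokens Character vector of preprocessed tokens.
#' @return A named numeric count vector (possibly empty).
#' @export
term_vector <- function(tokens) {
  if (length(tokens) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  tab <- table(tokens)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Euclidean norm of a term vector
#' @param v Named numeric vector from [term_vector()].
#' @return `sqrt(sum(v^2))`.
#' @export
vector_norm <- function(v) sqrt(sum(v^2))

#' Cosine similarity between two term vectors
#'
#' The cosine of the angle between two bag-of-words vectors over their
#' shared vocabulary; 1 for parallel vectors, 0 for disjoint vocabularies.
#'
#' @param a,b Named numeric vectors from [term_vector()].
#' @return A number in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  na <- vector_norm(a)
  nb <- vector_norm(b)
  if (na == 0 || nb == 0) {
    stop("cosine similarity is undefined for a zero vector", call. = FALSE)
  }
  shared <- intersect(names(a), names(b))
  sum(a[shared] * b[shared]) / (na * nb)
}

#' Plateau-level tf-idf table
#'
#' Treats each plateau's pooled text as one document. For term `t` in
#' plateau `p`: `tf = count(t, p) / total_tokens(p)` (length-normalised so
#' longer pools carry no advantage) and `idf = log(N / n_t)` with `N` the
#' number of non-empty plateau documents and `n_t` the number containing
#' the term; the score is their product. A term present in every plateau
#' has idf 0 and hence score 0 everywhere. Per-plateau keyword thresholds
#' are the 75th percentile (configurable) of that plateau's nonzero-score
#' distribution, and the global threshold is the greatest of these.
#'
#' @param pools Tibble with columns `plateau`, `term`, `count` (from
#'   [build_plateau_corpora()]).
#' @param percentile Threshold percentile in (0, 1); default 0.75.
#' @param log_base Logarithm base for idf; natural log by default. Changing
#'   the base rescales all scores uniformly and cannot reorder keywords.
#' @param quantile_type Quantile algorithm passed to [stats::quantile()]
#'   (7 = linear interpolation, the default; 1 = nearest rank).
#' @return An object of class `tfidf_table`: list with `scores` (tibble
#'   `term`, `plateau`, `tf`, `idf`, `score`), `thresholds` (tibble
#'   `plateau`, `threshold`), `global_threshold`, `n_docs`, `percentile`.
#' @export
tfidf_table <- function(pools, percentile = 0.75, log_base = exp(1),
                        quantile_type = 7) {
  stopifnot(percentile > 0, percentile < 1)
  totals <- pools |>
    dplyr::group_by(.data$plateau) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  totals <- totals[totals$total > 0, ]
  n_docs <- nrow(totals)
  if (n_docs < 2) {
    stop("tf-idf needs at least 2 non-empty plateau documents", call. = FALSE)
  }
  pools <- pools[pools$plateau %in% totals$plateau & pools$count > 0, ]
  doc_freq <- pools |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(n_t = dplyr::n_distinct(.data$plateau), .groups = "drop")
  scores <- pools |>
    dplyr::left_join(totals, by = "plateau") |>
    dplyr::left_join(doc_freq, by = "term") |>
    dplyr::mutate(
      tf = .data$count / .data$total,
      idf = log(n_docs / .data$n_t, base = log_base),
      score = .data$tf * .data$idf
    ) |>
    dplyr::select("term", "plateau", "tf", "idf", "score")
  thresholds <- scores |>
    dplyr::filter(.data$score > 0) |>
    dplyr::group_by(.data$plateau) |>
    dplyr::summarise(
      threshold = stats::quantile(.data$score, percentile,
        type = quantile_type, names = FALSE
      ),
      .groups = "drop"
    )
  global <- if (nrow(thresholds) == 0) 0 else max(thresholds$threshold)
  structure(
    list(
      scores = scores, thresholds = thresholds,
      global_threshold = global, n_docs = n_docs, percentile = percentile
    ),
    class = "tfidf_table"
  )
}

#' @export
print.tfidf_table <- function(x, ...) {
  cat(
    "tf-idf table:", dplyr::n_distinct(x$scores$term), "terms x",
    x$n_docs, "plateau documents\n"
  )
  cat(sprintf(
    "global threshold (%.0fth percentile of nonzero scores): %.4g\n",
    100 * x$percentile, x$global_threshold
  ))
  invisible(x)
}

#' Extract plateau-specific keywords
#'
#' A term is a keyword for plateau `p` when its score there strictly
#' exceeds the global threshold (ties at the threshold are excluded).
#'
#' @param table A `tfidf_table`.
#' @return A tibble with columns `plateau`, `term`, `score`, sorted by
#'   plateau and decreasing score.
#' @export
extract_keywords <- function(table) {
  stopifnot(inherits(table, "tfidf_table"))
  out <- table$scores |>
    dplyr::filter(.data$score > table$global_threshold) |>
    dplyr::select("plateau", "term", "score") |>
    dplyr::arrange(.data$plateau, dplyr::desc(.data$score))
  out
}

#' Keyword sets as a plateau-indexed list
#'
#' @param keywords Tibble from [extract_keywords()].
#' @param plateaus Plateau ids to report (default 1:4).
#' @return Named list of character vectors, one per plateau.
#' @export
keyword_sets <- function(keywords, plateaus = 1:4) {
  stats::setNames(
    lapply(plateaus, function(p) keywords$term[keywords$plateau == p]),
    paste0("plateau_", plateaus)
  )
}
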