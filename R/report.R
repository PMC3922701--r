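placeholder_plot <- function(label) {
  ggplot2::ggplot() +
    ggplot2::annotate("text", x = 0, y = 0, label = label) +
    ggplot2::theme_void()
}

#' Overall word-frequency plot
#'
#' Probability density of the most frequent words after stopword removal,
#' across the whole tokenized corpus.
#'
#' @param tokenized Tibble from [tokenize_corpus()].
#' @param top_n Number of words to show (default 40).
#' @return A ggplot object ("no data" panel when the corpus is empty).
#' @export
plot_word_frequency <- function(tokenized, top_n = 40) {
  words <- unlist(tokenized$tokens)
  if (length(words) == 0) {
    return(placeholder_plot("no data"))
  }
  freq <- tibble::tibble(word = words) |>
    dplyr::count(.data$word, sort = TRUE) |>
    dplyr::mutate(density = .data$n / sum(.data$n)) |>
    utils::head(top_n)
  ggplot2::ggplot(
    freq,
    ggplot2::aes(stats::reorder(.data$word, .data$density), .data$density)
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "probability density") +
    ggplot2::theme_minimal()
}

#' Most frequent terms per plateau
#'
#' @param pools Pool tibble from [build_plateau_corpora()].
#' @param n Terms per plateau (default 5).
#' @return A tibble `plateau`, `term`, `count`, `rank`.
#' @export
top_terms_by_plateau <- function(pools, n = 5) {
  if (nrow(pools) == 0) {
    return(tibble::tibble(
      plateau = integer(), term = character(),
      count = integer(), rank = integer()
    ))
  }
  pools |>
    dplyr::group_by(.data$plateau) |>
    dplyr::slice_max(.data$count, n = n, with_ties = FALSE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Dose-mention histogram plot (200 mg bins by default)
#'
#' @param doses Tibble from [extract_doses()].
#' @param bin_mg Bin width in mg.
#' @return A ggplot object.
#' @export
plot_dose_histogram <- function(doses, bin_mg = 200) {
  h <- dose_histogram(doses, bin_mg)
  if (nrow(h) == 0) {
    return(placeholder_plot("no data"))
  }
  ggplot2::ggplot(h, ggplot2::aes(.data$bin_lo + bin_mg / 2, .data$n)) +
    ggplot2::geom_col(width = bin_mg * 0.95) +
    ggplot2::labs(x = "dose (mg)", y = "mentions") +
    ggplot2::theme_minimal()
}

#' Per-plateau tf-idf score distributions with the global threshold
#'
#' @param tfidf A `tfidf_table`.
#' @return A ggplot object with one panel per plateau and a dotted line at
#'   the global keyword threshold.
#' @export
plot_tfidf_distributions <- function(tfidf) {
  sc <- tfidf$scores[tfidf$scores$score > 0, ]
  if (nrow(sc) == 0) {
    return(placeholder_plot("no data"))
  }
  ggplot2::ggplot(sc, ggplot2::aes(.data$score)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(
      xintercept = tfidf$global_threshold,
      linetype = "dotted"
    ) +
    ggplot2::facet_wrap(~plateau, scales = "free_y") +
    ggplot2::labs(x = "tf-idf score", y = "terms") +
    ggplot2::theme_minimal()
}

#' Plateau keyword table with the medical-relatedness rubric
#'
#' Classifies every extracted keyword as Yes/Maybe/No and, by default,
#' keeps only the Yes rows — the table of plateau-specific words likely
#' related to medicine.
#'
#' @param keywords Keyword tibble from [extract_keywords()].
#' @param tax A `taxonomy`.
#' @param synsets Synset tibble.
#' @param filter_yes Keep only category "Yes" rows?
#' @param ... Passed to [is_medical()].
#' @return A tibble `plateau`, `term`, `score`, `category`.
#' @export
keyword_table <- function(keywords, tax = read_taxonomy(),
                          synsets = read_synsets(), filter_yes = TRUE, ...) {
  if (nrow(keywords) == 0) {
    return(tibble::tibble(
      plateau = integer(), term = character(),
      score = numeric(), category = character()
    ))
  }
  keywords$category <- suppressMessages(
    is_medical(keywords$term, tax, synsets, ...)
  )
  if (filter_yes) keywords <- keywords[keywords$category == "Yes", ]
  keywords
}

#' Bar chart of median similarity, treatment vs control, per plateau
#'
#' @param comparison Result of [compare_to_control()].
#' @return A ggplot object.
#' @export
plot_similarity_comparison <- function(comparison) {
  pp <- comparison$per_plateau
  if (is.null(pp) || nrow(pp) == 0) {
    return(placeholder_plot("no data"))
  }
  long <- tibble::tibble(
    plateau = rep(pp$plateau, 2),
    corpus = rep(c("drug videos", "popular videos"), each = nrow(pp)),
    median_similarity = c(pp$median_treatment, pp$median_control)
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(factor(.data$plateau), .data$median_similarity,
      fill = .data$corpus
    )
  ) +
    ggplot2::geom_col(position = "dodge", colour = "black") +
    ggplot2::scale_fill_manual(values = c(
      "drug videos" = "black",
      "popular videos" = "white"
    )) +
    ggplot2::labs(x = "plateau", y = "median path similarity") +
    ggplot2::theme_minimal()
}
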