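#' Run the full keyword pipeline on a corpus
#'
#' Chains preprocessing, dose extraction, plateau pooling, tf-idf scoring
#' and threshold keyword extraction, returning every intermediate product.
#'
#' @param x A corpus tibble.
#' @param stopwords Stopword list from [load_stopwords()].
#' @param spec Plateau specification from [plateau_spec()].
#' @param percentile Keyword threshold percentile (default 0.75).
#' @param rule Multi-dose assignment rule, see [build_plateau_corpora()].
#' @param punct Punctuation policy, see [normalize_text()].
#' @return A list with `tokenized`, `doses`, `plateaus` (pools +
#'   assignments), `tfidf`, `keywords`.
#' @export
analyze_corpus <- function(x, stopwords = load_stopwords(),
                           spec = plateau_spec(), percentile = 0.75,
                           rule = "first", punct = "delete") {
  tokenized <- tokenize_corpus(x, stopwords = stopwords, punct = punct)
  doses <- extract_doses(x$text, id = x$id)
  plateaus <- build_plateau_corpora(tokenized, doses, spec = spec, rule = rule)
  tfidf <- tfidf_table(plateaus$pools, percentile = percentile)
  keywords <- extract_keywords(tfidf)
  list(
    tokenized = tokenized, doses = doses, plateaus = plateaus,
    tfidf = tfidf, keywords = keywords
  )
}

#' Recovery of injected symptom words
#'
#' Measures how well the pipeline recovers the generator's ground truth:
#' the fraction of injected plateau-specific words extracted as keywords of
#' their true plateau, and the number extracted in any wrong plateau.
#'
#' @param keywords Keyword tibble from [extract_keywords()].
#' @param truth Ground-truth list from [generate_corpus()].
#' @return A list with `recovered` (fraction in `[0, 1]`), `n_injected`,
#'   `wrong_plateau` (count).
#' @export
recovery_rate <- function(keywords, truth) {
  inj <- truth$injected
  if (nrow(inj) == 0) {
    return(list(recovered = NA_real_, n_injected = 0L, wrong_plateau = 0L))
  }
  hit <- mapply(
    function(w, p) any(keywords$term == w & keywords$plateau == p),
    inj$word, inj$plateau
  )
  wrong <- mapply(
    function(w, p) any(keywords$term == w & keywords$plateau != p),
    inj$word, inj$plateau
  )
  list(
    recovered = mean(hit),
    n_injected = nrow(inj),
    wrong_plateau = sum(wrong)
  )
}

#' Compare plateau keywords against a control corpus
#'
#' For each plateau, scores the treatment and control keyword sets against
#' that plateau's row of the clinical symptom lexicon (per-keyword
#' best-match path similarity) and compares the two similarity samples with
#' a two-tailed Mann-Whitney test. Keyword sets are size-matched first by
#' down-sampling the larger (reproducibly, from `seed`). Plateaus with an
#' empty keyword set on either side, or whose keywords all fail taxonomy
#' lookup, are skipped with a warning. Because the published analysis
#' reports a single pooled significance level, the per-plateau samples are
#' also concatenated and tested jointly; per-plateau p-values additionally
#' get a Holm adjustment.
#'
#' @param treatment_keywords,control_keywords Keyword tibbles from
#'   [extract_keywords()].
#' @param reference Plateau symptom lexicon from [load_plateau_lexicon()].
#' @param tax A `taxonomy`.
#' @param synsets Synset tibble.
#' @param measure Similarity measure, see [path_similarity()].
#' @param seed Seed for the down-sampling step.
#' @return A list with `per_plateau` (tibble) and `pooled` (list with the
#'   two similarity samples, medians, `U`, `p_value`).
#' @export
compare_to_control <- function(treatment_keywords, control_keywords,
                               reference = load_plateau_lexicon(),
                               tax = read_taxonomy(),
                               synsets = read_synsets(),
                               measure = "paper", seed = 1) {
  rows <- list()
  pooled_treat <- numeric(0)
  pooled_ctrl <- numeric(0)
  for (p in sort(unique(reference$plateau))) {
    tr <- treatment_keywords$term[treatment_keywords$plateau == p]
    ct <- control_keywords$term[control_keywords$plateau == p]
    if (length(tr) == 0 || length(ct) == 0) {
      warning("plateau ", p, " skipped: empty keyword set", call. = FALSE)
      next
    }
    ref <- reference$word[reference$plateau == p]
    sims <- tryCatch(
      list(
        treat = set_similarity(tr, ref, tax, synsets, measure),
        ctrl = set_similarity(ct, ref, tax, synsets, measure)
      ),
      error = function(e) NULL
    )
    if (is.null(sims)) {
      warning("plateau ", p, " skipped: no keywords mapped to the taxonomy",
        call. = FALSE
      )
      next
    }
    ts <- sims$treat$values$similarity
    cs <- sims$ctrl$values$similarity
    # size-match after taxonomy lookup, so unmappable tokens cost no sample
    m <- min(length(ts), length(cs))
    matched <- with_local_seed(seed + p, list(sample(ts, m), sample(cs, m)))
    ts <- matched[[1]]
    cs <- matched[[2]]
    mw <- mann_whitney_u(ts, cs)
    rows[[length(rows) + 1]] <- tibble::tibble(
      plateau = p,
      n_treatment = length(ts), n_control = length(cs),
      median_treatment = stats::median(ts), median_control = stats::median(cs),
      U = mw$U, p_value = mw$p_value
    )
    pooled_treat <- c(pooled_treat, ts)
    pooled_ctrl <- c(pooled_ctrl, cs)
  }
  per_plateau <- dplyr::bind_rows(rows)
  if (nrow(per_plateau) > 0) {
    per_plateau$p_holm <- stats::p.adjust(per_plateau$p_value,
      method = "holm"
    )
  }
  pooled <- if (length(pooled_treat) > 0 && length(pooled_ctrl) > 0) {
    mw <- mann_whitney_u(pooled_treat, pooled_ctrl)
    list(
      treatment = pooled_treat, control = pooled_ctrl,
      median_treatment = stats::median(pooled_treat),
      median_control = stats::median(pooled_ctrl),
      U = mw$U, p_value = mw$p_value,
      n_treatment = length(pooled_treat), n_control = length(pooled_ctrl)
    )
  } else {
    NULL
  }
  list(per_plateau = per_plateau, pooled = pooled)
}

#' End-to-end enriched-vs-control comparison on synthetic corpora
#'
#' Generates an enriched corpus and a size-matched unenriched control from
#' the same configuration, runs the keyword pipeline on both, and compares
#' the per-keyword similarity samples. Mirroring the published comparison,
#' the drug-corpus side is by default the medically-related keyword table
#' (keywords classified "Yes" by [is_medical()], the Table-2 analog), while
#' the control side is its raw keywords — a random sample of words from
#' comments with no drug-specific content.
#'
#' @param config A [generator_config()].
#' @param medical_filter Restrict the treatment side to "Yes" keywords?
#' @inheritParams compare_to_control
#' @return A list with `comparison` (from [compare_to_control()]),
#'   `treatment` and `control` pipeline results, and `truth`.
#' @export
run_synthetic_comparison <- function(config = generator_config(),
                                     reference = load_plateau_lexicon(),
                                     tax = read_taxonomy(),
                                     synsets = read_synsets(),
                                     measure = "paper",
                                     medical_filter = TRUE) {
  gen <- generate_corpus(config)
  ctrl <- generate_control(config)
  treatment <- analyze_corpus(gen$corpus)
  control <- analyze_corpus(ctrl)
  treat_kw <- if (medical_filter) {
    keyword_table(treatment$keywords, tax = tax, synsets = synsets)
  } else {
    treatment$keywords
  }
  comparison <- suppressMessages(compare_to_control(
    treat_kw, control$keywords,
    reference = reference, tax = tax, synsets = synsets,
    measure = measure, seed = config$seed
  ))
  list(
    comparison = comparison, treatment = treatment, control = control,
    truth = gen$truth
  )
}
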