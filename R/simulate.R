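# run code under a local RNG state, restoring the caller's afterwards
with_local_seed <- function(seed, code) {
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
  force(code)
}

# triangular distribution on [lo, hi] with the given mode, by inverse CDF
rtriangular <- function(n, lo, mode, hi) {
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc,
    lo + sqrt(u * (hi - lo) * (mode - lo)),
    hi - sqrt((1 - u) * (hi - lo) * (hi - mode))
  )
}

default_background_vocab <- function() {
  # Zipf-weighted common head: frequent, plateau-nonspecific comment words.
  common <- c(
    "like", "get", "got", "one", "take", "took", "really", "time", "good",
    "first", "know", "think", "going", "go", "made", "make", "feel", "felt",
    "never", "ever", "much", "still", "back", "right", "way", "day", "night",
    "people", "say", "said", "see", "saw", "thing", "want", "trip", "dxm",
    "robo", "watch", "best", "man"
  )
  # Sparse tail: words rare enough to be plateau-specific by chance. Includes
  # the object-branch taxonomy words so control keywords map into the
  # taxonomy, plus everyday out-of-vocabulary filler.
  rare <- c(
    "video", "music", "bottle", "party", "penguin", "vid", "vids", "clip",
    "song", "tune", "beat", "syrup", "chug", "rave", "bird",
    "friend", "house", "school", "work", "game", "phone", "story", "week",
    "month", "year", "morning", "evening", "weekend", "summer", "winter",
    "money", "store", "road", "town", "city", "room", "couch", "floor",
    "window", "door", "light", "sound", "voice", "face", "hand", "head",
    "mouth", "water", "food", "pizza", "candy", "coffee", "shirt", "shoes",
    "dog", "cat", "fish", "tree", "rain", "snow", "wind", "fire", "book",
    "movie", "show", "channel", "comment", "account", "internet", "computer",
    "keyboard", "screen", "camera", "picture", "photo", "guitar", "drums",
    "band", "concert", "ticket", "bus", "train", "plane", "beach", "lake",
    "mountain", "garden", "kitchen", "table", "chair", "lamp", "mirror",
    "wall", "ceiling", "street", "corner", "bridge", "river", "island",
    "forest", "field", "grass", "cloud", "moon", "star"
  )
  tibble::tibble(
    word = c(common, rare),
    weight = c(1 / seq_along(common), rep(0.00126, length(rare)))
  )
}

default_symptom_enrichment <- function(multiplier = 5) {
  tibble::tibble(
    plateau = rep(1:4, each = 3),
    word = c(
      "buzzed", "racing", "jittery", # 1: stimulant-like
      "trippin", "dizzy", "wobbly", # 2: intoxication, hallucinations
      "numb", "slurred", "floating", # 3: dissociative, out-of-body
      "puking", "blackout", "overdosed" # 4: full dissociation, overdose
    ),
    multiplier = multiplier
  )
}

#' Configuration for the synthetic comment generator
#'
#' Defaults encode the statistical structure the analysis assumes of a
#' short-comment drug-discussion corpus: negative-binomial comment lengths
#' with the bulk of the mass at 15-20 words and a heavy right tail; dose
#' mentions in roughly a third of comments, spanning 0-1500 mg as a mixture
#' over the four plateaus with per-plateau triangular distributions peaking
#' at 375 mg in plateau 2; plateau-confined symptom vocabulary injected at
#' `multiplier` times the median background-word rate; and noise channels
#' mirroring real comment artifacts (internet slang, non-ASCII characters,
#' punctuation-fused tokens such as "drunk-high").
#'
#' @param n_comments Number of comments.
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @param length_size,length_mu Negative-binomial size and mean for comment
#'   length; lengths are shifted by `length_min`.
#' @param length_min Minimum comment length in words.
#' @param dose_mention_rate Fraction of comments containing a dose mention.
#' @param plateau_weights Mixture weights over plateaus 1-4 (sum to 1).
#' @param dose_ranges Tibble `plateau`, `lo`, `mode`, `hi` (mg) for the
#'   per-plateau triangular dose distributions.
#' @param symptom_enrichment Tibble `plateau`, `word`, `multiplier`: words
#'   injected only into comments of their plateau, at `multiplier` x the
#'   median background-word frequency; multiplier 0 removes a word.
#' @param background_vocab Tibble `word`, `weight`.
#' @param slang_rate Per-token probability of an internet-slang token.
#' @param nonascii_rate Per-comment probability of a non-ASCII token.
#' @param punct_fusion_rate Per-comment probability of hyphen-fusing two
#'   adjacent words.
#' @param id_prefix Prefix for generated comment ids.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_comments = 2000,
                             seed = 1,
                             length_size = 12,
                             length_mu = 16,
                             length_min = 3,
                             dose_mention_rate = 0.35,
                             plateau_weights = c(0.20, 0.45, 0.22, 0.13),
                             dose_ranges = tibble::tibble(
                               plateau = 1:4,
                               lo = c(100, 250, 450, 800),
                               mode = c(150, 375, 600, 900),
                               hi = c(250, 450, 800, 1500)
                             ),
                             symptom_enrichment = default_symptom_enrichment(),
                             background_vocab = default_background_vocab(),
                             slang_rate = 0.08,
                             nonascii_rate = 0.03,
                             punct_fusion_rate = 0.05,
                             id_prefix = "c") {
  cfg <- list(
    n_comments = n_comments, seed = seed, length_size = length_size,
    length_mu = length_mu, length_min = length_min,
    dose_mention_rate = dose_mention_rate,
    plateau_weights = plateau_weights, dose_ranges = dose_ranges,
    symptom_enrichment = symptom_enrichment,
    background_vocab = background_vocab, slang_rate = slang_rate,
    nonascii_rate = nonascii_rate, punct_fusion_rate = punct_fusion_rate,
    id_prefix = id_prefix
  )
  check_field <- function(ok, field) {
    if (!ok) stop("invalid generator config field: ", field, call. = FALSE)
  }
  check_field(is.numeric(n_comments) && n_comments >= 0, "n_comments")
  check_field(is.numeric(seed) && length(seed) == 1, "seed")
  check_field(length_size > 0 && length_mu > 0, "length_size/length_mu")
  check_field(
    dose_mention_rate >= 0 && dose_mention_rate <= 1,
    "dose_mention_rate"
  )
  check_field(
    length(plateau_weights) == 4 && all(plateau_weights >= 0) &&
      abs(sum(plateau_weights) - 1) < 1e-8,
    "plateau_weights"
  )
  check_field(
    all(c("plateau", "word", "multiplier") %in% names(symptom_enrichment)) &&
      all(symptom_enrichment$multiplier >= 0),
    "symptom_enrichment"
  )
  check_field(
    all(c("word", "weight") %in% names(background_vocab)) &&
      all(background_vocab$weight > 0),
    "background_vocab"
  )
  for (f in c("slang_rate", "nonascii_rate", "punct_fusion_rate")) {
    check_field(cfg[[f]] >= 0 && cfg[[f]] <= 1, f)
  }
  structure(cfg, class = "generator_config")
}

# elision slang is sometimes written with its apostrophe so that
# preprocessing (which deletes punctuation) is genuinely exercised
elision_forms <- c(
  dont = "don't", cant = "can't", im = "i'm", ive = "i've",
  youre = "you're", thats = "that's", id = "i'd"
)

format_dose <- function(mg) {
  style <- sample(4, 1)
  if (style == 1) sprintf("%dmg", mg)
  else if (style == 2) sprintf("%d mg", mg)
  else if (style == 3 && mg %% 100 == 0) sprintf("%gg", mg / 1000)
  else sprintf("%d milligrams", mg)
}

#' Generate a synthetic comment corpus with ground truth
#'
#' Deterministic in `config$seed`. Returns both the corpus (with sampling
#' keys assigned from the same seed) and a ground-truth record: the true
#' dose and plateau of every comment and the injected symptom-word table,
#' for parameter-recovery tests. Ground truth is never embedded in the
#' comment text.
#'
#' @param config A [generator_config()].
#' @return A list with elements `corpus` (a corpus tibble) and `truth`
#'   (list: `comments` tibble `id`, `dose_mg`, `plateau`; `injected`
#'   enrichment tibble).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_comments
  vocab <- config$background_vocab
  base_freq <- stats::median(vocab$weight) / sum(vocab$weight)
  enrich <- config$symptom_enrichment
  enrich <- enrich[enrich$multiplier > 0, ]
  slang <- load_stopwords()$custom
  nonascii_tokens <- c("caf\u00e9", "\u00fcber", "ni\u00f1o", "na\u00efve")

  out <- with_local_seed(config$seed, {
    lengths <- config$length_min +
      stats::rnbinom(n, size = config$length_size, mu = config$length_mu)
    has_dose <- stats::runif(n) < config$dose_mention_rate
    plateau <- rep(NA_integer_, n)
    plateau[has_dose] <- sample(1:4, sum(has_dose),
      replace = TRUE,
      prob = config$plateau_weights
    )
    dose_mg <- rep(NA_real_, n)
    for (p in 1:4) {
      idx <- which(plateau == p)
      if (length(idx) == 0) next
      rng <- config$dose_ranges[config$dose_ranges$plateau == p, ]
      raw <- rtriangular(length(idx), rng$lo, rng$mode, rng$hi)
      mg <- pmin(pmax(round(raw / 5) * 5, rng$lo), rng$hi - 5)
      dose_mg[idx] <- mg
    }

    texts <- character(n)
    for (i in seq_len(n)) {
      words <- vocab$word
      wts <- vocab$weight
      if (!is.na(plateau[i]) && nrow(enrich) > 0) {
        inj <- enrich[enrich$plateau == plateau[i], ]
        if (nrow(inj) > 0) {
          words <- c(words, inj$word)
          wts <- c(wts, inj$multiplier * base_freq * sum(vocab$weight))
        }
      }
      tok <- sample(words, lengths[i], replace = TRUE, prob = wts)
      is_slang <- stats::runif(lengths[i]) < config$slang_rate
      if (any(is_slang)) {
        sl <- sample(slang, sum(is_slang), replace = TRUE)
        restore <- sl %in% names(elision_forms) & stats::runif(length(sl)) < 0.5
        sl[restore] <- elision_forms[sl[restore]]
        tok[is_slang] <- sl
      }
      if (length(tok) >= 2 && stats::runif(1) < config$punct_fusion_rate) {
        j <- sample(length(tok) - 1, 1)
        tok <- c(
          utils::head(tok, j - 1),
          paste0(tok[j], "-", tok[j + 1]),
          utils::tail(tok, -(j + 1))
        )
      }
      if (stats::runif(1) < config$nonascii_rate) {
        tok <- append(tok, sample(nonascii_tokens, 1), sample(length(tok), 1))
      }
      if (!is.na(dose_mg[i])) {
        tok <- append(tok, format_dose(dose_mg[i]), sample(length(tok), 1))
      }
      if (stats::runif(1) < 0.5) {
        tok[1] <- paste0(toupper(substr(tok[1], 1, 1)), substring(tok[1], 2))
      }
      texts[i] <- paste0(
        paste(tok, collapse = " "),
        sample(c(".", "!", "!!", "...", ""), 1)
      )
    }
    list(texts = texts, plateau = plateau, dose_mg = dose_mg)
  })

  corp <- corpus(
    id = sprintf("%s%05d", config$id_prefix, seq_len(n)),
    text = out$texts,
    source_tag = "synthetic"
  )
  corp <- assign_keys(corp, config$seed)
  list(
    corpus = corp,
    truth = list(
      comments = tibble::tibble(
        id = corp$id, dose_mg = out$dose_mg,
        plateau = out$plateau
      ),
      injected = enrich
    )
  )
}

#' Generate an unenriched control corpus
#'
#' Same length, noise and dose model as [generate_corpus()] but with all
#' symptom enrichment removed: dose mentions are present (so plateau pools
#' form) yet carry no symptom vocabulary, emulating a size-matched sample
#' of comments from popular videos with no drug-specific content.
#'
#' @param config A [generator_config()]; its enrichment table is zeroed and
#'   its id prefix replaced by `"ctrl"`.
#' @return A corpus tibble.
#' @export
generate_control <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  config$symptom_enrichment$multiplier <- 0
  config$id_prefix <- "ctrl"
  generate_corpus(config)$corpus
}
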