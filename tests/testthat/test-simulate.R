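test_that("generator configuration is validated field by field", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(n_comments = -1), "n_comments")
  expect_error(generator_config(dose_mention_rate = 1.5), "dose_mention_rate")
  expect_error(
    generator_config(plateau_weights = c(0.5, 0.5, 0.5, 0.5)),
    "plateau_weights"
  )
  expect_error(generator_config(slang_rate = 2), "slang_rate")
})

test_that("the generator is deterministic in its seed", {
  cfg <- generator_config(n_comments = 150, seed = 77)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$corpus, b$corpus)
  expect_identical(a$truth$comments, b$truth$comments)
  c <- generate_corpus(generator_config(n_comments = 150, seed = 78))
  expect_false(identical(a$corpus$text, c$corpus$text))
})

test_that("dose mention fraction stays within the binomial bound", {
  cfg <- generator_config(n_comments = 2000, seed = 12)
  gen <- generate_corpus(cfg)
  frac <- mean(!is.na(gen$truth$comments$dose_mg))
  sigma <- sqrt(0.35 * 0.65 / 2000)
  expect_lt(abs(frac - cfg$dose_mention_rate), 3 * sigma)
})

test_that("every generated dose string re-parses to its true milligrams", {
  gen <- generate_corpus(generator_config(n_comments = 800, seed = 13))
  doses <- extract_doses(gen$corpus$text, id = gen$corpus$id)
  truth <- gen$truth$comments
  truth <- truth[!is.na(truth$dose_mg), ]
  # exactly one mention per dosed comment, matching the ground truth
  expect_setequal(doses$comment_id, truth$id)
  merged <- dplyr::inner_join(doses, truth,
    by = c("comment_id" = "id")
  )
  expect_equal(merged$value_mg, merged$dose_mg)
  # and its plateau is the ground-truth plateau
  expect_equal(assign_plateau(merged$value_mg), as.integer(merged$plateau))
})

test_that("zeroed enrichment removes the word from its plateau pool", {
  cfg <- generator_config(n_comments = 1200, seed = 14)
  cfg$symptom_enrichment$multiplier[cfg$symptom_enrichment$word == "dizzy"] <- 0
  gen <- generate_corpus(cfg)
  toks <- unlist(tokenize_corpus(gen$corpus)$tokens)
  # "dizzy" has no background rate, so zero multiplier means absent
  expect_false("dizzy" %in% toks)
  # the other plateau-2 words are still injected
  expect_true("trippin" %in% toks)
})

test_that("the control corpus is unenriched but otherwise comparable", {
  cfg <- generator_config(n_comments = 600, seed = 15)
  ctrl <- generate_control(cfg)
  expect_equal(nrow(ctrl), 600)
  toks <- unlist(tokenize_corpus(ctrl)$tokens)
  injected <- default_symptom_enrichment()$word
  expect_length(intersect(toks, injected), 0)
  # dose mentions remain so plateau pools still form
  expect_gt(nrow(extract_doses(ctrl$text, id = ctrl$id)), 0)
})

test_that("noise channels produce the documented artifacts", {
  cfg <- generator_config(
    n_comments = 400, seed = 16,
    punct_fusion_rate = 1, nonascii_rate = 1
  )
  gen <- generate_corpus(cfg)
  has_nonascii <- function(s) {
    any(vapply(s, function(t) any(utf8ToInt(t) > 127L), logical(1)))
  }
  expect_true(any(grepl("[a-z]-[a-z]", gen$corpus$text))) # fused pairs
  expect_true(has_nonascii(gen$corpus$text))
  # zero noise leaves pure ASCII background text
  quiet <- generator_config(
    n_comments = 100, seed = 17,
    slang_rate = 0, nonascii_rate = 0, punct_fusion_rate = 0
  )
  gq <- generate_corpus(quiet)
  expect_false(has_nonascii(gq$corpus$text))
})
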