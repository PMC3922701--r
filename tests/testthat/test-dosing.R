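test_that("extract_doses finds number+unit patterns and converts to mg", {
  d <- extract_doses("took 375mg last night")
  expect_equal(d$value_mg, 375)
  expect_equal(d$raw_span, "375mg")
  expect_equal(extract_doses("did 1.5g of dxm")$value_mg, 1500)
  expect_equal(extract_doses("600 milligrams then 0.3 grams")$value_mg, c(600, 300))
  expect_equal(nrow(extract_doses("no doses here")), 0)
  # matches come back in text order
  expect_equal(extract_doses("375mg then 900 mg")$value_mg, c(375, 900))
  # words ending in g are not doses
  expect_equal(nrow(extract_doses("a strong song 12 dogs")), 0)
})

test_that("assign_plateau applies half-open clinical bins", {
  expect_equal(assign_plateau(375), 2L)
  expect_equal(assign_plateau(800), 4L) # upper bounds exclusive
  expect_equal(assign_plateau(250), 2L)
  expect_equal(assign_plateau(c(100, 249, 449, 799)), c(1L, 1L, 2L, 3L))
  expect_true(is.na(assign_plateau(50))) # therapeutic range
  expect_true(is.na(assign_plateau(6000))) # implausible, excluded
  expect_equal(assign_plateau(6000, max_plausible_mg = 10000), 4L)
})

test_that("assign_plateau is a monotone step function of dose", {
  doses <- seq(100, 4999, by = 7)
  p <- assign_plateau(doses)
  expect_false(anyNA(p))
  expect_true(all(diff(p) >= 0))
})

test_that("dose_histogram counts half-open 200 mg bins", {
  d <- tibble::tibble(
    comment_id = c("a", "a", "b"),
    value_mg = c(375, 375, 900), raw_span = ""
  )
  h <- dose_histogram(d, bin_mg = 200)
  expect_equal(h$n[h$bin_lo == 200], 2L)
  expect_equal(h$n[h$bin_lo == 800], 1L)
  expect_equal(nrow(dose_histogram(d[0, ], 200)), 0)
})

test_that("generated dose distribution has its mode in the bin containing 375 mg", {
  gen <- generate_corpus(generator_config(n_comments = 2000, seed = 9))
  doses <- extract_doses(gen$corpus$text, id = gen$corpus$id)
  h <- dose_histogram(doses, bin_mg = 200)
  modal <- h[which.max(h$n), ]
  expect_true(modal$bin_lo <= 375 && 375 < modal$bin_hi)
})

test_that("build_plateau_corpora pools numeric-stripped tokens per plateau", {
  sw <- load_stopwords()
  x <- corpus(
    id = c("a", "b", "c"),
    text = c(
      "took 375mg wild trip", # plateau 2
      "375mg then 900mg crazy", # first-mention rule -> plateau 2
      "no dose just chatting"
    )
  )
  tk <- tokenize_corpus(x, sw)
  doses <- extract_doses(x$text, id = x$id)
  res <- build_plateau_corpora(tk, doses)
  expect_setequal(res$assignments$id, c("a", "b"))
  expect_true(all(res$assignments$plateau == 2))
  expect_equal(res$n_excluded, 1)
  p2 <- res$pools$term[res$pools$plateau == 2]
  expect_true("trip" %in% p2)
  expect_false(any(grepl("[0-9]", p2))) # dose numerals never enter the pool

  res_max <- build_plateau_corpora(tk, doses, rule = "max")
  expect_equal(
    sort(res_max$assignments$plateau[res_max$assignments$id == "b"]), 4L
  )
  res_drop <- build_plateau_corpora(tk, doses, rule = "drop")
  expect_false("b" %in% res_drop$assignments$id)
})

test_that("plateau pooling conserves comments", {
  gen <- generate_corpus(generator_config(n_comments = 400, seed = 2))
  tk <- tokenize_corpus(gen$corpus)
  doses <- extract_doses(gen$corpus$text, id = gen$corpus$id)
  res <- build_plateau_corpora(tk, doses)
  expect_equal(nrow(res$assignments) + res$n_excluded, nrow(gen$corpus))
  # every pooled comment's dose lies inside its plateau's interval
  spec <- plateau_spec()
  merged <- dplyr::inner_join(res$assignments, spec, by = "plateau")
  expect_true(all(
    merged$dose_mg >= merged$lower_mg & merged$dose_mg < merged$upper_mg
  ))
  # a corpus with no doses yields empty pools
  nodose <- corpus(id = "z", text = "nothing here")
  res0 <- build_plateau_corpora(
    tokenize_corpus(nodose),
    extract_doses(nodose$text, id = nodose$id)
  )
  expect_equal(nrow(res0$pools), 0)
})
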