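test_that("term vectors reproduce the repeated-sentence worked example", {
  sw <- load_stopwords()
  dogs <- term_vector(tokenize(normalize_text("Dogs run and dogs run."), sw)[[1]])
  cats <- term_vector(tokenize(normalize_text("Cats run."), sw)[[1]])
  expect_equal(unname(dogs[c("dogs", "run")]), c(2, 2))
  expect_equal(vector_norm(dogs), 2 * sqrt(2))
  expect_equal(vector_norm(cats), sqrt(2))
  expect_equal(vector_norm(dogs) / vector_norm(cats), 2) # exactly twice
  expect_equal(cosine_similarity(dogs, cats), 0.5)
  expect_equal(vector_norm(term_vector(character(0))), 0)
})

test_that("cosine similarity is 1 on identical and 0 on disjoint vectors", {
  v <- term_vector(c("a", "b", "b", "c"))
  expect_equal(cosine_similarity(v, v), 1)
  w <- term_vector(c("x", "y"))
  expect_equal(cosine_similarity(v, w), 0)
  expect_error(cosine_similarity(v, term_vector(character(0))), "zero vector")
})

test_that("tf-idf reproduces hand-computed toy corpus scores", {
  pools <- docs_to_pools(list(`1` = c("a", "a", "b"), `2` = c("b", "c")))
  tab <- tfidf_table(pools)
  sc <- function(t, p) tab$scores$score[tab$scores$term == t & tab$scores$plateau == p]
  expect_equal(sc("a", 1), (2 / 3) * log(2))
  expect_equal(sc("c", 2), (1 / 2) * log(2))
  expect_equal(sc("b", 1), 0) # present in every document
  expect_equal(sc("b", 2), 0)
})

test_that("idf takes the textbook values for 4 documents", {
  docs <- list(
    `1` = c("everywhere", "only1", "in2"),
    `2` = c("everywhere", "in2"),
    `3` = c("everywhere", "filler"),
    `4` = c("everywhere", "filler2")
  )
  tab <- tfidf_table(docs_to_pools(docs))
  idf_of <- function(t) unique(tab$scores$idf[tab$scores$term == t])
  expect_equal(idf_of("everywhere"), 0) # ln 1
  expect_equal(idf_of("only1"), log(4))
  expect_equal(idf_of("in2"), log(2))
})

test_that("tf-idf matches the brute-force oracle on random toy corpora", {
  set.seed(101)
  for (i in 1:40) {
    vocab <- letters[1:sample(2:5, 1)]
    docs <- lapply(1:4, function(d) {
      sample(vocab, sample(0:8, 1), replace = TRUE)
    })
    names(docs) <- 1:4
    if (sum(lengths(docs) > 0) < 2) next
    tab <- tfidf_table(docs_to_pools(docs))
    ora <- oracle_tfidf(docs)
    merged <- merge(tab$scores, ora, by = c("term", "plateau"))
    expect_equal(nrow(merged), nrow(tab$scores))
    expect_true(all(abs(merged$score.x - merged$score.y) < 1e-12))
  }
})

test_that("tf-idf scores are invariant to plateau order and count doubling", {
  docs <- list(
    `1` = c("a", "a", "b"), `2` = c("b", "c", "c"),
    `3` = c("d", "a"), `4` = c("e")
  )
  pools <- docs_to_pools(docs)
  tab1 <- tfidf_table(pools)
  shuffled <- pools[sample(nrow(pools)), ]
  tab2 <- tfidf_table(shuffled)
  m <- merge(tab1$scores, tab2$scores, by = c("term", "plateau"))
  expect_equal(m$score.x, m$score.y)
  # doubling all counts leaves tf (hence scores) unchanged
  doubled <- pools
  doubled$count <- doubled$count * 2
  tab3 <- tfidf_table(doubled)
  m2 <- merge(tab1$scores, tab3$scores, by = c("term", "plateau"))
  expect_equal(m2$score.x, m2$score.y)
})

test_that("degenerate corpora are rejected", {
  pools <- docs_to_pools(list(`1` = c("a", "b")))
  expect_error(tfidf_table(pools), "at least 2")
})

test_that("threshold sits at the 75th percentile and keywords exceed it strictly", {
  # scores 1..8 in one plateau: type-7 75th percentile is 6.25
  fake <- structure(
    list(
      scores = tibble::tibble(
        term = letters[1:8], plateau = 1L,
        tf = NA_real_, idf = NA_real_, score = as.numeric(1:8)
      ),
      thresholds = tibble::tibble(plateau = 1L, threshold = 6.25),
      global_threshold = 6.25, n_docs = 2, percentile = 0.75
    ),
    class = "tfidf_table"
  )
  expect_equal(stats::quantile(1:8, 0.75, type = 7, names = FALSE), 6.25)
  kw <- extract_keywords(fake)
  expect_setequal(kw$term, c("g", "h")) # scores 7 and 8
  # all scores equal: nothing strictly above the threshold
  flat <- fake
  flat$scores$score <- rep(2, 8)
  flat$global_threshold <- 2
  expect_equal(nrow(extract_keywords(flat)), 0)
})

test_that("raising the threshold never adds a keyword", {
  gen <- generate_corpus(generator_config(n_comments = 600, seed = 4))
  res <- analyze_corpus(gen$corpus)
  tab <- res$tfidf
  kw_lo <- extract_keywords(tab)
  tab$global_threshold <- tab$global_threshold * 2
  kw_hi <- extract_keywords(tab)
  key <- function(k) paste(k$plateau, k$term)
  expect_true(all(key(kw_hi) %in% key(kw_lo)))
})
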