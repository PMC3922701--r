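tax <- read_taxonomy()
syn <- read_synsets()

test_that("the bundled taxonomy loads with a single root and cached diameter", {
  expect_s3_class(tax, "taxonomy")
  expect_equal(tax$root, "entity")
  expect_length(tax$nodes, 50)
  expect_equal(tax$diameter, 8)
})

test_that("path similarity satisfies its axioms on the toy fixture", {
  toy <- toy_taxonomy()
  expect_equal(toy$diameter, 3)
  expect_equal(path_similarity(toy, "x1", "x1"), 1) # identity
  expect_equal(path_similarity(toy, "x1", "y"), 0) # diameter-separated
  expect_equal(path_similarity(toy, "x1", "x"), 2 / 3)
  expect_equal(
    path_similarity(toy, "x1", "y"),
    path_similarity(toy, "y", "x1")
  ) # symmetry
  expect_equal(path_similarity(toy, "x1", "y", measure = "reciprocal"), 1 / 4)
  expect_error(path_similarity(toy, "x1", "nope"), "not in taxonomy")
})

test_that("similarities agree with brute-force shortest paths on fixtures", {
  fixtures <- list(
    toy = tibble::tibble(
      parent = c("root", "x", "root"),
      child = c("x", "x1", "y")
    ),
    bundled = {
      lines <- readLines(system.file("extdata", "taxonomy",
        "mini_taxonomy.tsv",
        package = "toxitext"
      ))
      lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
      parts <- strsplit(lines, "\t")
      tibble::tibble(
        parent = sapply(parts, `[`, 1),
        child = sapply(parts, `[`, 2)
      )
    }
  )
  for (edges in fixtures) {
    t <- taxonomy_from_edges(edges)
    d <- oracle_shortest_paths(edges)
    expect_equal(max(d), t$diameter)
    nodes <- sample(t$nodes, min(12, length(t$nodes)))
    for (a in nodes) {
      for (b in nodes) {
        expect_equal(
          path_similarity(t, a, b),
          1 - d[a, b] / max(d),
          info = paste(a, b)
        )
      }
    }
  }
})

test_that("random trees keep similarity within bounds, 1 only at identity", {
  set.seed(21)
  for (i in 1:5) {
    t <- random_tree_taxonomy(sample(5:30, 1))
    pairs <- expand.grid(a = t$nodes, b = t$nodes, stringsAsFactors = FALSE)
    pairs <- pairs[sample(nrow(pairs), 40, replace = TRUE), ]
    for (j in seq_len(nrow(pairs))) {
      s <- path_similarity(t, pairs$a[j], pairs$b[j])
      expect_gte(s, 0)
      expect_lte(s, 1)
      if (pairs$a[j] != pairs$b[j]) expect_lt(s, 1)
      expect_equal(s, path_similarity(t, pairs$b[j], pairs$a[j]))
    }
  }
})

test_that("a shortcut edge never decreases similarity at fixed diameter", {
  chain <- function(prefix, n) {
    tibble::tibble(
      parent = c("root", paste0(prefix, seq_len(n - 1))),
      child = paste0(prefix, seq_len(n))
    )
  }
  base <- dplyr::bind_rows(chain("a", 4), chain("b", 4), chain("c", 6))
  t1 <- taxonomy_from_edges(base)
  shortcut <- dplyr::bind_rows(
    base,
    tibble::tibble(parent = "a2", child = "b1")
  )
  t2 <- taxonomy_from_edges(shortcut)
  expect_equal(t1$diameter, t2$diameter) # the c-chain pins the diameter
  expect_gte(
    path_similarity(t2, "a4", "b1"),
    path_similarity(t1, "a4", "b1")
  )
})

test_that("word lookup unions synsets with direct node names", {
  expect_equal(word_nodes("dizzy", tax, syn), "dizziness")
  expect_equal(word_nodes("vomiting", tax, syn), "vomiting")
  expect_length(word_nodes("qwertyuiop", tax, syn), 0)
  expect_equal(word_similarity("puking", "vomiting", tax, syn), 1)
})

test_that("set_similarity returns best-match distributions and medians", {
  toy <- toy_taxonomy()
  empty_syn <- tibble::tibble(word = character(), node = character())
  res <- set_similarity(c("x1"), c("x", "y"), toy, empty_syn)
  expect_equal(res$values$similarity, 2 / 3) # max(2/3, 0)
  ref <- load_plateau_lexicon()
  p4 <- ref$word[ref$plateau == 4]
  ident <- set_similarity(p4, p4, tax, syn)
  expect_true(all(ident$values$similarity == 1))
  expect_equal(ident$median, 1)
  expect_error(
    set_similarity(c("zzz"), c("x"), toy, empty_syn),
    "keyword set is empty"
  )
  expect_error(
    set_similarity(c("x1"), c("zzz"), toy, empty_syn),
    "reference set is empty"
  )
})

test_that("is_medical reproduces the Yes/Maybe/No rubric examples", {
  expect_equal(is_medical("dizzy", tax, syn), "Yes")
  expect_equal(is_medical("penguin", tax, syn), "No")
  expect_equal(is_medical("heavy", tax, syn), "Maybe")
  expect_equal(is_medical("satan", tax, syn), "No") # manual override
  expect_equal(
    suppressMessages(is_medical("qwertyuiop", tax, syn)), "No"
  ) # unknown words default to No
  expect_equal(
    is_medical(c("bleeding", "dxm", "video"), tax, syn),
    c("Yes", "Yes", "No")
  )
})
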