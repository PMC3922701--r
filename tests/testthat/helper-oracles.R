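# Independent oracles and small fixtures shared across test files. Each
# oracle is written as directly as possible (loops, enumeration) so it
# shares no code path with the implementation it checks.

# brute-force tf-idf over a named list of token vectors (names = plateau ids)
oracle_tfidf <- function(docs) {
  docs <- docs[lengths(docs) > 0]
  n_docs <- length(docs)
  rows <- list()
  for (d in names(docs)) {
    for (term in unique(docs[[d]])) {
      cnt <- sum(docs[[d]] == term)
      tf <- cnt / length(docs[[d]])
      n_t <- 0
      for (e in names(docs)) {
        if (term %in% docs[[e]]) n_t <- n_t + 1
      }
      rows[[length(rows) + 1]] <- data.frame(
        term = term, plateau = as.integer(d),
        score = tf * log(n_docs / n_t), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# pools tibble (plateau, term, count) from a named list of token vectors
docs_to_pools <- function(docs) {
  rows <- lapply(names(docs), function(d) {
    if (length(docs[[d]]) == 0) {
      return(NULL)
    }
    tab <- table(docs[[d]])
    tibble::tibble(
      plateau = as.integer(d), term = names(tab),
      count = as.integer(tab)
    )
  })
  dplyr::bind_rows(rows)
}

# all-pairs shortest paths by Floyd-Warshall on an undirected edge list
oracle_shortest_paths <- function(edges) {
  nodes <- unique(c(edges$parent, edges$child))
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- match(edges$parent[i], nodes)
    b <- match(edges$child[i], nodes)
    d[a, b] <- 1
    d[b, a] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# exact two-tailed Mann-Whitney p by enumerating every group labelling
oracle_mw <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  list(U = u_obs, p_value = min(1, 2 * min(p_lo, p_hi)))
}

# the 4-node toy taxonomy: root - x - x1, root - y (diameter 3)
toy_taxonomy <- function() {
  taxonomy_from_edges(tibble::tibble(
    parent = c("root", "x", "root"),
    child = c("x", "x1", "y")
  ))
}

# a random rooted tree on n nodes, for property tests
random_tree_taxonomy <- function(n) {
  stopifnot(n >= 2)
  nodes <- paste0("n", seq_len(n))
  parent_idx <- vapply(2:n, function(i) sample(i - 1, 1), integer(1))
  taxonomy_from_edges(tibble::tibble(
    parent = nodes[parent_idx],
    child = nodes[2:n]
  ))
}

# write a corpus tibble's rows as JSON lines and return the path
write_jsonl <- function(lines, path = tempfile(fileext = ".jsonl")) {
  writeLines(lines, path, useBytes = TRUE)
  path
}
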