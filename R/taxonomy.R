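#' Read a hypernym/hyponym taxonomy
#'
#' Edge-list text format: one `parent<TAB>child` pair per line, `#`
#' comments allowed, exactly one root (a node that never appears as a
#' child), and the undirected graph must be connected. The graph diameter
#' (longest shortest path, in edges) is computed once and cached on the
#' object; path similarity is normalised by it.
#'
#' @param path Path to the edge-list file; defaults to the bundled
#'   mini-taxonomy, a ~50-node synthetic WordNet-style hierarchy with drug,
#'   clinical-condition and everyday-object branches.
#' @return An object of class `taxonomy`.
#' @export
read_taxonomy <- function(path = system.file("extdata", "taxonomy",
                            "mini_taxonomy.tsv",
                            package = "toxitext"
                          )) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2
  if (any(bad)) {
    stop("malformed taxonomy line(s): ", paste(lines[bad], collapse = "; "),
      call. = FALSE
    )
  }
  edges <- tibble::tibble(
    parent = vapply(parts, `[[`, character(1), 1),
    child = vapply(parts, `[[`, character(1), 2)
  )
  taxonomy_from_edges(edges)
}

#' Build a taxonomy from a parent/child edge table
#'
#' A node may have several parents (the hierarchy is a rooted DAG, as in
#' WordNet); the hypernym chain used by [is_medical()] follows each node's
#' primary (first-listed) parent.
#'
#' @param edges Tibble or data frame with columns `parent`, `child`.
#' @return An object of class `taxonomy` with fields `graph` (undirected
#'   igraph), `parents` (named child -> primary parent lookup), `root`,
#'   `nodes`, `diameter`.
#' @export
taxonomy_from_edges <- function(edges) {
  stopifnot(all(c("parent", "child") %in% names(edges)))
  g <- igraph::graph_from_data_frame(
    edges[, c("parent", "child")],
    directed = FALSE
  )
  if (!igraph::is_connected(g)) {
    stop("taxonomy must be connected", call. = FALSE)
  }
  roots <- setdiff(unique(edges$parent), edges$child)
  if (length(roots) != 1) {
    stop(
      "taxonomy must have exactly one root, found: ",
      paste(roots, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      graph = g,
      parents = stats::setNames(edges$parent, edges$child),
      root = roots,
      nodes = igraph::V(g)$name,
      diameter = igraph::diameter(g, unconnected = FALSE)
    ),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(
    "taxonomy:", length(x$nodes), "nodes, root", shQuote(x$root),
    ", diameter", x$diameter, "\n"
  )
  invisible(x)
}

#' Shortest path length between two concepts
#'
#' @param tax A `taxonomy`.
#' @param a,b Node names.
#' @return Integer edge count of the shortest path.
#' @export
path_length <- function(tax, a, b) {
  check_nodes(tax, c(a, b))
  as.integer(igraph::distances(tax$graph, v = a, to = b))
}

check_nodes <- function(tax, nodes) {
  missing <- setdiff(nodes, tax$nodes)
  if (length(missing) > 0) {
    stop("concept(s) not in taxonomy: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Path similarity between two concepts
#'
#' With `measure = "paper"` (default) the similarity is the complement of
#' the ratio of the shortest-path length to the taxonomy diameter,
#' `1 - L(a, b) / diameter`: identical concepts score 1 and
#' diameter-separated concepts score 0. With `measure = "reciprocal"` the
#' toolkit-style `1 / (1 + L)` is used instead; both are normalised with
#' maximum similarity unity.
#'
#' @param tax A `taxonomy`.
#' @param a,b Node names (`b` may be a vector).
#' @param measure "paper" or "reciprocal".
#' @return Numeric similarity(ies) in `[0, 1]`.
#' @export
path_similarity <- function(tax, a, b, measure = c("paper", "reciprocal")) {
  measure <- match.arg(measure)
  check_nodes(tax, c(a, b))
  len <- as.numeric(igraph::distances(tax$graph, v = a, to = b))
  if (measure == "paper") 1 - len / tax$diameter else 1 / (1 + len)
}

#' Read a synset table
#'
#' `word<TAB>node` lines mapping surface words onto taxonomy nodes. A word
#' may map to several nodes (polysemy). Every node name is implicitly a
#' member of its own synset, so node names need not be listed.
#'
#' @param path Path to the synset file; defaults to the bundled table.
#' @return A tibble with columns `word`, `node`.
#' @export
read_synsets <- function(path = system.file("extdata", "taxonomy",
                           "synsets.tsv",
                           package = "toxitext"
                         )) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    word = tolower(vapply(parts, `[[`, character(1), 1)),
    node = vapply(parts, `[[`, character(1), 2)
  )
}

#' Taxonomy nodes for a word
#'
#' Union of the word's synset nodes and, if the word is itself a node name,
#' that node. Unknown words give `character(0)`.
#'
#' @param word Single word (lowercase).
#' @param tax A `taxonomy`.
#' @param synsets Synset tibble from [read_synsets()].
#' @return Character vector of node names.
#' @export
word_nodes <- function(word, tax, synsets = read_synsets()) {
  nodes <- synsets$node[synsets$word == word]
  if (word %in% tax$nodes) nodes <- c(nodes, word)
  intersect(unique(nodes), tax$nodes)
}

#' Best-sense path similarity between two words
#'
#' Maximum path similarity over all sense (node) pairs of the two words;
#' `NA` if either word maps to no taxonomy node.
#'
#' @inheritParams word_nodes
#' @param word_a,word_b Words to compare.
#' @param measure Similarity measure, see [path_similarity()].
#' @return Similarity in `[0, 1]`, or `NA_real_`.
#' @export
word_similarity <- function(word_a, word_b, tax, synsets = read_synsets(),
                            measure = "paper") {
  na <- word_nodes(word_a, tax, synsets)
  nb <- word_nodes(word_b, tax, synsets)
  if (length(na) == 0 || length(nb) == 0) {
    return(NA_real_)
  }
  max(vapply(
    na, function(n) max(path_similarity(tax, n, nb, measure)),
    numeric(1)
  ))
}

#' Similarity distribution of a keyword set against a reference set
#'
#' For each keyword that maps into the taxonomy, its best-match similarity:
#' the maximum (default aggregator) over reference terms of the best-sense
#' path similarity. Keywords with no taxonomy node are dropped with a
#' message; an empty side after lookup is an error naming that side.
#'
#' @param keywords Character vector of keywords.
#' @param reference Character vector of reference symptom terms.
#' @param tax A `taxonomy`.
#' @param synsets Synset tibble.
#' @param measure Similarity measure, see [path_similarity()].
#' @param aggregator Function combining a keyword's per-reference
#'   similarities (default `max`).
#' @return A list with `values` (tibble `keyword`, `similarity`), `median`,
#'   `n_dropped`.
#' @export
set_similarity <- function(keywords, reference, tax,
                           synsets = read_synsets(), measure = "paper",
                           aggregator = max) {
  keywords <- unique(tolower(keywords))
  reference <- unique(tolower(reference))
  kw_known <- keywords[vapply(
    keywords,
    function(w) length(word_nodes(w, tax, synsets)) > 0, logical(1)
  )]
  ref_known <- reference[vapply(
    reference,
    function(w) length(word_nodes(w, tax, synsets)) > 0, logical(1)
  )]
  if (length(ref_known) == 0) {
    stop("reference set is empty after taxonomy lookup", call. = FALSE)
  }
  if (length(kw_known) == 0) {
    stop("keyword set is empty after taxonomy lookup", call. = FALSE)
  }
  n_dropped <- length(keywords) - length(kw_known)
  if (n_dropped > 0) {
    message(n_dropped, " keyword(s) not found in taxonomy; dropped")
  }
  sims <- vapply(kw_known, function(kw) {
    aggregator(vapply(
      ref_known,
      function(r) word_similarity(kw, r, tax, synsets, measure),
      numeric(1)
    ))
  }, numeric(1))
  list(
    values = tibble::tibble(keyword = kw_known, similarity = unname(sims)),
    median = stats::median(sims),
    n_dropped = n_dropped
  )
}

#' Load the medical seed node list
#' @param path Plain-text file, one taxonomy node per line.
#' @return Character vector of node names.
#' @export
load_medical_seed <- function(path = system.file("extdata", "lexicon",
                                "medical_seed.txt",
                                package = "toxitext"
                              )) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Load Yes/Maybe/No manual overrides
#' @param path `word<TAB>category` file, categories Yes/Maybe/No.
#' @return Named character vector (word -> category).
#' @export
load_overrides <- function(path = system.file("extdata", "lexicon",
                             "overrides.tsv",
                             package = "toxitext"
                           )) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(
    vapply(parts, `[[`, character(1), 2),
    tolower(vapply(parts, `[[`, character(1), 1))
  )
}

#' Medical-relatedness rubric for keywords
#'
#' Classifies each word as Yes / Maybe / No (likely / possible / very
#' unlikely semantic relation to medicine). Manual overrides are consulted
#' first. Otherwise the word's concept nodes are walked up the hypernym
#' chain: a seed node reached within fewer than `k` hops gives Yes, at
#' exactly `k` hops Maybe, otherwise (or for words with no taxonomy node,
#' which are logged) No.
#'
#' @param words Character vector of words.
#' @param tax A `taxonomy`.
#' @param synsets Synset tibble.
#' @param seed Medical seed nodes from [load_medical_seed()].
#' @param overrides Named category vector from [load_overrides()].
#' @param k Hop budget (default 3).
#' @return Character vector of "Yes"/"Maybe"/"No", one per word.
#' @export
is_medical <- function(words, tax, synsets = read_synsets(),
                       seed = load_medical_seed(),
                       overrides = load_overrides(), k = 3) {
  check_nodes(tax, seed)
  ancestor_dist <- function(node) {
    # hops up the hypernym chain to the nearest seed node
    d <- 0L
    cur <- node
    repeat {
      if (cur %in% seed) {
        return(d)
      }
      if (!cur %in% names(tax$parents)) {
        return(NA_integer_)
      }
      cur <- tax$parents[[cur]]
      d <- d + 1L
    }
  }
  vapply(tolower(words), function(w) {
    if (w %in% names(overrides)) {
      return(overrides[[w]])
    }
    nodes <- word_nodes(w, tax, synsets)
    if (length(nodes) == 0) {
      message("word not in taxonomy, classified No: ", w)
      return("No")
    }
    d <- suppressWarnings(min(vapply(nodes, ancestor_dist, integer(1)),
      na.rm = TRUE
    ))
    if (!is.finite(d)) {
      "No"
    } else if (d < k) {
      "Yes"
    } else if (d == k) {
      "Maybe"
    } else {
      "No"
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Load the per-plateau clinical symptom lexicon
#'
#' The reference rows against which extracted keywords are scored: for each
#' plateau, the symptom concepts of the established clinical description of
#' dextromethorphan toxicity at that dose range.
#'
#' @param path `plateau<TAB>word` file; defaults to the bundled lexicon.
#' @return A tibble with columns `plateau` (integer), `word`.
#' @export
load_plateau_lexicon <- function(path = system.file("extdata", "lexicon",
                                   "plateau_symptoms.tsv",
                                   package = "toxitext"
                                 )) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    plateau = as.integer(vapply(parts, `[[`, character(1), 1)),
    word = tolower(vapply(parts, `[[`, character(1), 2))
  )
}
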