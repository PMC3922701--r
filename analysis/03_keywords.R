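#!/usr/bin/env Rscript
# Stage 3: plateau pools, tf-idf and keyword extraction.
#
# Bins dosed comments into the four clinical plateaus, pools their
# numeric-stripped tokens, scores every term with plateau-level tf-idf and
# extracts keywords above the greatest per-plateau 75th-percentile
# threshold. The medically-related subset (Yes under the taxonomy rubric)
# is the analog of a published per-plateau symptom-word table.

suppressPackageStartupMessages(library(toxitext))

x <- read_corpus("results/data/treatment.jsonl")
res <- analyze_corpus(x)

cat(sprintf(
  "plateau pools: %s comments; %d excluded (no in-range dose)\n",
  paste(table(res$plateaus$assignments$plateau), collapse = "/"),
  res$plateaus$n_excluded
))
cat(sprintf(
  "global tf-idf threshold: %.3g (75th percentile, max over plateaus)\n",
  res$tfidf$global_threshold
))

top5 <- top_terms_by_plateau(res$plateaus$pools, n = 5)
utils::write.table(top5, "results/top_terms_by_plateau.tsv",
  sep = "\t", row.names = FALSE, quote = FALSE
)

kw <- res$keywords
kw$above_threshold <- TRUE
utils::write.table(kw, "results/keywords.tsv",
  sep = "\t", row.names = FALSE, quote = FALSE
)
cat(sprintf(
  "keywords per plateau: %s\n",
  paste(table(factor(kw$plateau, levels = 1:4)), collapse = "/")
))

medical <- keyword_table(res$keywords)
utils::write.table(medical, "results/keywords_medical.tsv",
  sep = "\t", row.names = FALSE, quote = FALSE
)
cat("medically related keywords (Yes category):\n")
for (p in sort(unique(medical$plateau))) {
  cat(sprintf(
    "  plateau %d: %s\n", p,
    paste(medical$term[medical$plateau == p], collapse = ", ")
  ))
}

truth <- utils::read.delim("results/data/truth_injected.tsv")
rec <- recovery_rate(res$keywords, list(injected = truth))
cat(sprintf(
  "ground-truth recovery: %.0f%% of injected words in their true plateau, %d in wrong plateaus\n",
  100 * rec$recovered, rec$wrong_plateau
))

ggplot2::ggsave("results/fig_tfidf_distributions.png",
  plot_tfidf_distributions(res$tfidf),
  width = 7, height = 5, dpi = 150
)
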