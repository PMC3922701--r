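#!/usr/bin/env Rscript
# Stage 4: semantic similarity against the clinical lexicon, vs control.
#
# Scores the medically-related treatment keywords and the raw control
# keywords against each plateau's row of the clinical symptom lexicon
# (best-match path similarity on the bundled taxonomy), size-matches the
# samples, and runs per-plateau and pooled two-tailed Mann-Whitney tests.

suppressPackageStartupMessages(library(toxitext))

treat <- analyze_corpus(read_corpus("results/data/treatment.jsonl"))
ctrl <- analyze_corpus(read_corpus("results/data/control.jsonl"))

tax <- read_taxonomy()
syn <- read_synsets()
treat_kw <- keyword_table(treat$keywords, tax = tax, synsets = syn)

cmp <- suppressMessages(compare_to_control(
  treat_kw, ctrl$keywords,
  reference = load_plateau_lexicon(), tax = tax, synsets = syn, seed = 1
))

utils::write.table(cmp$per_plateau, "results/similarity_per_plateau.tsv",
  sep = "\t", row.names = FALSE, quote = FALSE
)
print(cmp$per_plateau)

po <- cmp$pooled
cat(sprintf(
  "pooled: median similarity %.3f (drug corpus) vs %.3f (control), U = %.1f, two-tailed p = %.3g (n = %d vs %d)\n",
  po$median_treatment, po$median_control, po$U, po$p_value,
  po$n_treatment, po$n_control
))
jsonlite::write_json(
  list(
    per_plateau = cmp$per_plateau,
    pooled = po[c(
      "median_treatment", "median_control", "U", "p_value",
      "n_treatment", "n_control"
    )]
  ),
  "results/similarity_summary.json",
  auto_unbox = TRUE, digits = NA
)

ggplot2::ggsave("results/fig_similarity_comparison.png",
  plot_similarity_comparison(cmp),
  width = 6, height = 4, dpi = 150
)
cat("stage-4 outputs written to results/\n")
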