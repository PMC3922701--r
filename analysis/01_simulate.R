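#!/usr/bin/env Rscript
# Stage 1: build the study corpora.
#
# Generates the enriched "drug-video" comment corpus (2000 synthetic
# comments with plateau-confined symptom vocabulary and dose mentions
# peaking at 375 mg) and a size-matched unenriched control standing in for
# comments on popular videos. Writes both as JSON-lines plus the
# ground-truth sidecar used by later stages to judge recovery.

suppressPackageStartupMessages(library(toxitext))

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
cfg <- generator_config(n_comments = 2000, seed = 1)

gen <- generate_corpus(cfg)
ctrl <- generate_control(cfg)

write_corpus(gen$corpus, "results/data/treatment.jsonl")
write_corpus(ctrl, "results/data/control.jsonl")
utils::write.table(gen$truth$comments, "results/data/truth_comments.tsv",
  sep = "\t", row.names = FALSE, quote = FALSE
)
utils::write.table(gen$truth$injected, "results/data/truth_injected.tsv",
  sep = "\t", row.names = FALSE, quote = FALSE
)

dosed <- sum(!is.na(gen$truth$comments$dose_mg))
cat(sprintf(
  "generated %d treatment comments (%d with dose mentions, %.1f%%)\n",
  nrow(gen$corpus), dosed, 100 * dosed / nrow(gen$corpus)
))
cat(sprintf(
  "injected %d plateau-specific symptom words at %gx background rate\n",
  nrow(gen$truth$injected), unique(gen$truth$injected$multiplier)
))
cat(sprintf("control corpus: %d comments, no symptom enrichment\n", nrow(ctrl)))
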