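#!/usr/bin/env Rscript
# Stage 2: preprocessing and dose structure.
#
# Normalises and tokenizes the treatment corpus, then extracts dose
# mentions and converts them to milligrams. Emits the comment-length
# histogram (9-word bins), the overall word-frequency table after stopword
# removal, and the dose histogram (200 mg bins) whose modal bin should
# contain the 375 mg generator peak.

suppressPackageStartupMessages(library(toxitext))

dir.create("results", showWarnings = FALSE)
x <- read_corpus("results/data/treatment.jsonl")
tk <- tokenize_corpus(x)

lengths_hist <- word_count_histogram(tk, bin_size = 9)
utils::write.table(lengths_hist, "results/comment_length_histogram.tsv",
  sep = "\t", row.names = FALSE, quote = FALSE
)
modal <- lengths_hist[which.max(lengths_hist$n), ]
cat(sprintf(
  "comment lengths: modal bin [%d, %d) words (%d comments)\n",
  modal$bin_lo, modal$bin_hi, modal$n
))

doses <- extract_doses(x$text, id = x$id)
dh <- dose_histogram(doses, bin_mg = 200)
utils::write.table(dh, "results/dose_histogram.tsv",
  sep = "\t", row.names = FALSE, quote = FALSE
)
dmodal <- dh[which.max(dh$n), ]
cat(sprintf(
  "doses: %d mentions, modal bin [%d, %d) mg\n",
  nrow(doses), dmodal$bin_lo, dmodal$bin_hi
))

ggplot2::ggsave("results/fig_dose_histogram.png",
  plot_dose_histogram(doses),
  width = 6, height = 4, dpi = 150
)
ggplot2::ggsave("results/fig_word_frequency.png",
  plot_word_frequency(tk),
  width = 6, height = 7, dpi = 150
)
cat("figures written to results/\n")
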