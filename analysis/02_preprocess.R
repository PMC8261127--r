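#!/usr/bin/env Rscript
# Stage 2: preprocess the training expression matrix.
#
# Low-count filter (counts < 10 in more than 80% of samples), variance
# stabilization by median-of-ratios log2, two surrogate variables estimated
# as residual principal components (protecting rhythm, adjusting for sex),
# residualization of sex + SVs, and selection of the top 5,000 variance
# genes for network construction.

library(afcerna)

counts <- read_matrix_tsv("results/data/train_counts.tsv")
phenotypes <- utils::read.delim("results/data/phenotypes.tsv",
                                stringsAsFactors = FALSE)

prep <- preprocess_expression(counts, phenotypes,
                              min_count = 10, max_low_fraction = 0.8,
                              n_sv = 2, top_k = 5000)
write_matrix_tsv(round(prep$expr, 6), "results/cleaned_expression.tsv")
utils::write.table(
  data.frame(sample_id = rownames(prep$svs), prep$svs),
  "results/surrogate_variables.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE
)

message(sprintf(
  "filtered %d genes, selected %d high-variance genes; %d surrogate variables regressed out together with sex",
  prep$n_filtered, nrow(prep$expr), ncol(prep$svs)
))
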