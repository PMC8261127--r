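#!/usr/bin/env Rscript
# Stage 1: generate the synthetic atrial-rhythm cohort.
#
# Emulates the study design: 235 training samples in three rhythm groups
# (SR/SR 43, AF/SR 74, AF/AF 118), 5,000 genes (460 lncRNAs) with six
# planted co-expression modules (module 1 tracks AF susceptibility, module
# 2 AF persistence), a miRNA-target database with 60 planted ceRNA pairs
# and one hub lncRNA wired to all 20 seed genes, a functional second-layer
# edge list, and a 38-sample microarray-like test cohort (32 AF / 6 SR)
# with a strong platform shift.

library(afcerna)

seed <- 1L
out <- "results/data"

config <- simulation_config(rng_seed = seed)
dataset <- generate_dataset(config)
paths <- write_dataset(dataset, out)
gene_sets <- generate_gene_sets(dataset, rng_seed = seed + 101L)
write_gmt(gene_sets, file.path(out, "gene_sets.gmt"))
utils::write.table(
  data.frame(gene_id = names(dataset$biotypes), biotype = dataset$biotypes),
  file.path(out, "biotypes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
)

message(sprintf(
  "wrote %d x %d training counts, %d x %d test matrix, %d miRNA-target pairs (N = %d), %d planted ceRNA pairs, hub lncRNA %s",
  nrow(dataset$train_counts), ncol(dataset$train_counts),
  nrow(dataset$test_expression), ncol(dataset$test_expression),
  nrow(dataset$mirna_db$lnc_pairs) + nrow(dataset$mirna_db$mrna_pairs),
  dataset$mirna_db$N, nrow(dataset$truth$planted_pairs),
  dataset$truth$hub_lncrna
))
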