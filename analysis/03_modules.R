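#!/usr/bin/env Rscript
# Stage 3: signed co-expression network, modules, and trait contrasts.
#
# Builds the signed adjacency ((1 + cor)/2)^beta with beta chosen as the
# smallest power reaching scale-free fit 0.9 (falling back to the
# conventional power 12 when the fit plateau stays below the threshold, as
# it does on block-structured data), computes topological overlap, cuts the
# average-linkage dendrogram (minimum module size 30), merges modules with
# eigengene dissimilarity < 0.25, and correlates every module eigengene
# with the AF susceptibility (AF/SR = 1 vs SR/SR = 0) and AF persistence
# (AF/AF = 1 vs AF/SR = 0) contrasts.

library(afcerna)

expr <- read_matrix_tsv("results/cleaned_expression.tsv")
phenotypes <- utils::read.delim("results/data/phenotypes.tsv",
                                stringsAsFactors = FALSE)
biotypes <- with(utils::read.delim("results/data/biotypes.tsv"),
                 stats::setNames(biotype, gene_id))

beta <- tryCatch(as.integer(pick_beta(expr, 1:20, fit_threshold = 0.9)),
                 error = function(e) {
                   message("scale-free threshold not reached; using power 12")
                   12L
                 })
adjacency <- signed_adjacency(expr, beta)
tom <- compute_tom(adjacency)
rm(adjacency)
clustering <- cluster_modules(tom, min_module_size = 30, deep_split = 2)
rm(tom)
merged <- merge_modules(clustering$labels, expr, cut_height = 0.25)
labels <- merged$labels
mes <- module_eigengenes(expr, labels)

utils::write.table(
  data.frame(gene_id = names(labels), module = labels,
             biotype = biotypes[names(labels)]),
  "results/modules.tsv", sep = "\t", quote = FALSE, row.names = FALSE
)
write_matrix_tsv(round(t(mes), 6), "results/eigengenes.tsv")

trait <- lapply(c("susceptibility", "persistence"), function(ct) {
  module_trait_correlation(mes, phenotypes, ct)
})
names(trait) <- c("susceptibility", "persistence")
jsonlite::write_json(trait, "results/module_trait.json", auto_unbox = TRUE,
                     digits = NA, dataframe = "rows")

message(sprintf("beta = %d; %d modules (%d genes unassigned)",
                beta, max(labels), sum(labels == 0)))
for (ct in names(trait)) {
  top <- trait[[ct]][1, ]
  message(sprintf("top %s module: %d (r = %.2f, p = %.2g, n = %d)",
                  ct, top$module, top$r, top$p, top$n))
}
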