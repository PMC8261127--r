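#!/usr/bin/env Rscript
# Stage 6: pathway associations of the key lncRNAs.
#
# Scores every gene set per sample (mean z of the member genes) and, for
# each key lncRNA, fits score ~ rhythm + lncRNA expression with rhythm as
# an ordinal covariate (SR/SR = 0, AF/SR = 1, AF/AF = 2); the lncRNA
# coefficient measures pathway-lncRNA association free of the rhythm
# effect. Sets outside [10, 500] genes (after intersection with the
# expression universe) are excluded.

library(afcerna)

expr <- read_matrix_tsv("results/cleaned_expression.tsv")
phenotypes <- utils::read.delim("results/data/phenotypes.tsv",
                                stringsAsFactors = FALSE)
gene_sets <- load_gmt("results/data/gene_sets.gmt", min_size = 10,
                      max_size = 500, universe = rownames(expr))
top <- jsonlite::fromJSON("results/top_lncrnas.json")
rhythm <- c("SR/SR" = 0, "AF/SR" = 1, "AF/AF" = 2)[phenotypes$rhythm]

for (lnc in top$node) {
  pa <- pathway_association(expr, gene_sets, rhythm, lnc)
  utils::write.table(pa, sprintf("results/pathways_%s.tsv", lnc), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  top10 <- utils::head(pa[pa$coefficient > 0, ], 10)
  message(sprintf("%s: %d sets tested; strongest positive association %s (coef %.2f, p = %.2g)",
                  lnc, nrow(pa), top10$set[1], top10$coefficient[1], top10$p[1]))
}
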