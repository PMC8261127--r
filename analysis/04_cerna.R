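#!/usr/bin/env Rscript
# Stage 4: module-specific ceRNA networks.
#
# Takes the two most trait-associated modules per contrast, tests every
# intramodule lncRNA x mRNA pair sharing at least one miRNA with the
# upper-tail hypergeometric test (universe N computed from the loaded
# database), keeps pairs with p < 0.05 (BH-adjusted p-values are recorded
# for the sensitivity network), and aggregates the module networks into one
# bipartite network annotated with the known disease genes.

library(afcerna)

modules <- utils::read.delim("results/modules.tsv", stringsAsFactors = FALSE)
labels <- stats::setNames(modules$module, modules$gene_id)
biotypes <- stats::setNames(modules$biotype, modules$gene_id)
db <- read_mirna_targets("results/data/mirna_targets.tsv")
seed_genes <- read_seed_genes("results/data/seed_genes.txt")
trait <- jsonlite::fromJSON("results/module_trait.json")

selected <- unique(unlist(lapply(trait, function(tt) tt$module[1:2])))
networks <- lapply(selected, function(m) {
  nw <- build_module_cerna(names(labels)[labels == m], biotypes, db,
                           module_id = m, alpha = 0.05)
  utils::write.table(nw$edges, sprintf("results/cerna_module%d.tsv", m),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nw
})
network <- aggregate_networks(networks, seed_genes)
utils::write.table(network$edges, "results/cerna_aggregated.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(network$nodes, "results/cerna_nodes.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

message(sprintf(
  "modules %s: %s edges; aggregated network has %d edges over %d nodes, %d known disease genes present",
  paste(selected, collapse = "/"),
  paste(vapply(networks, function(nw) nrow(nw$edges), integer(1)),
        collapse = "/"),
  nrow(network$edges), nrow(network$nodes),
  sum(network$nodes$is_known_disease_gene)
))
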