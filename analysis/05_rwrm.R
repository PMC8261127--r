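#!/usr/bin/env Rscript
# Stage 5: lncRNA prioritization by random walk with restart on the
# two-layer multiplex network.
#
# Layer 1 is the aggregated ceRNA network; layer 2 keeps the functional
# gene-gene edges whose endpoints both occur in layer 1. Layer weights
# follow tau = [2/(1+R), 2R/(1+R)] with R the layer-1/layer-2 edge-count
# ratio; the walk uses layer-jump probability 0.5 and restart probability
# 0.7, restarting on the known disease genes present in the network. The
# top two non-seed lncRNAs by layer-summed stationary probability are the
# key lncRNAs.

library(afcerna)

edges <- utils::read.delim("results/cerna_aggregated.tsv",
                           stringsAsFactors = FALSE)
nodes_df <- utils::read.delim("results/cerna_nodes.tsv",
                              stringsAsFactors = FALSE)
layer2_edges <- utils::read.delim("results/data/layer2_edges.tsv",
                                  stringsAsFactors = FALSE)
seed_genes <- read_seed_genes("results/data/seed_genes.txt")

nodes <- nodes_df$gene
biotypes <- stats::setNames(nodes_df$biotype, nodes)
layer1 <- edges_to_adjacency(edges[, c("lncrna", "mrna")], nodes)
layer2 <- edges_to_adjacency(layer2_edges, nodes)
n1 <- sum(layer1[upper.tri(layer1)] > 0)
n2 <- sum(layer2[upper.tri(layer2)] > 0)
graph <- multiplex_graph(list(cerna = layer1, functional = layer2))
result <- rwrm_scores(graph, intersect(seed_genes, nodes),
                      delta = 0.5, r = 0.7, tau = layer_weights(n1 / n2))

ranking <- result$ranking
ranking$biotype <- biotypes[ranking$node]
utils::write.table(ranking, "results/rwrm_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
top <- prioritize_lncrnas(result, biotypes, top_k = 2)
jsonlite::write_json(top, "results/top_lncrnas.json", auto_unbox = TRUE,
                     digits = NA, dataframe = "rows")

message(sprintf(
  "layers: %d ceRNA edges, %d functional edges (tau = %.2f/%.2f); converged in %d iterations; key lncRNAs: %s",
  n1, n2, result$tau[1], result$tau[2], result$iterations,
  paste(sprintf("%s (%.3g)", top$node, top$score), collapse = ", ")
))
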