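#' Upper-tail hypergeometric probability of shared-miRNA overlap
#'
#' For a lncRNA targeted by `n` of the `N` miRNAs in the database and an
#' mRNA targeted by `M` of them, the probability of sharing at least `t`
#' miRNAs by chance is `P(X >= t)` for X hypergeometric, i.e.
#' `1 - sum_{k=0}^{t-1} C(M,k) C(N-M,n-k) / C(N,n)`. The sum is evaluated
#' from the upper tail in log space (`lchoose`) for numerical stability; it
#' equals the finite complement sum exactly. `t = 0` returns exactly 1.
#' The formula is symmetric in `n` and `M` (swapping which partner is
#' treated as the draw does not change the probability).
#'
#' @param N miRNA universe size.
#' @param M miRNAs targeting the mRNA.
#' @param n miRNAs targeting the lncRNA.
#' @param t shared miRNAs. All four arguments are recycled to a common
#'   length.
#' @return vector of upper-tail probabilities in (0, 1\].
#' @export
hypergeom_p <- function(N, M, n, t) {
  args <- cbind(N = N, M = M, n = n, t = t)
  if (any(args < 0) || any(args[, "M"] > args[, "N"]) ||
      any(args[, "n"] > args[, "N"]) ||
      any(args[, "t"] > pmin(args[, "n"], args[, "M"]))) {
    stop("require 0 <= t <= min(n, M) and M, n <= N")
  }
  apply(args, 1, function(a) {
    N <- a["N"]; M <- a["M"]; n <- a["n"]; t <- a["t"]
    if (t == 0) return(1)
    ks <- seq.int(t, min(n, M))
    p <- sum(exp(lchoose(M, ks) + lchoose(N - M, n - ks) - lchoose(N, n)))
    min(1, p)
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up control of the false discovery rate; a thin wrapper around
#' `stats::p.adjust(method = "BH")` that validates the input range and
#' preserves input order.
#'
#' @param pvalues numeric vector with values in (0, 1\].
#' @return adjusted p-values, same order and length.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' miRNA-target database
#'
#' Holds the lncRNA-miRNA and mRNA-miRNA pair tables, the per-gene target
#' sets and the miRNA universe (all distinct miRNAs appearing in either
#' table); `N` is its size and is always computed from the loaded data.
#'
#' @param lnc_pairs data.frame with columns `gene_id`, `mirna_id` (lncRNA
#'   pairs).
#' @param mrna_pairs data.frame with the same columns for mRNAs.
#' @return object of class `mirna_target_db` with elements `lnc_pairs`,
#'   `mrna_pairs`, `lnc_targets`/`mrna_targets` (named lists of character
#'   vectors), `universe` and `N`.
#' @export
mirna_target_db <- function(lnc_pairs, mrna_pairs) {
  stopifnot(
    all(c("gene_id", "mirna_id") %in% names(lnc_pairs)),
    all(c("gene_id", "mirna_id") %in% names(mrna_pairs))
  )
  lnc_pairs <- unique(lnc_pairs[, c("gene_id", "mirna_id")])
  mrna_pairs <- unique(mrna_pairs[, c("gene_id", "mirna_id")])
  universe <- sort(unique(c(lnc_pairs$mirna_id, mrna_pairs$mirna_id)))
  if (!length(universe)) stop("empty miRNA universe")
  structure(list(
    lnc_pairs = lnc_pairs, mrna_pairs = mrna_pairs,
    lnc_targets = split(lnc_pairs$mirna_id, lnc_pairs$gene_id),
    mrna_targets = split(mrna_pairs$mirna_id, mrna_pairs$gene_id),
    universe = universe, N = length(universe)
  ), class = "mirna_target_db")
}

#' Module-specific ceRNA network
#'
#' Tests every intramodule lncRNA x mRNA pair that shares at least one
#' miRNA (pairs with no overlap are not tested, keeping the BH family
#' small) and keeps pairs significant at `alpha` by raw p (default) or
#' BH-adjusted p. The BH family is, by default, the module's own set of
#' tested pairs; `bh_family = "global"` defers adjustment to
#' [aggregate_networks()] across all modules.
#'
#' @param module_genes character vector of the module's gene IDs.
#' @param biotypes named character vector (`lncRNA`/`mRNA`) covering the
#'   module genes.
#' @param db a [mirna_target_db()].
#' @param module_id label stored on the edges.
#' @param alpha significance threshold (default 0.05).
#' @param use_adjusted select on BH-adjusted p instead of raw p.
#' @param bh_family `"module"` (default) or `"global"`.
#' @return object of class `cerna_network`: list with `edges` (data.frame
#'   lncrna, mrna, module, t, n, M, N, p, p_adj, shared_mirnas) and `tested`
#'   (the pre-filter table).
#' @export
build_module_cerna <- function(module_genes, biotypes, db, module_id = 1,
                               alpha = 0.05, use_adjusted = FALSE,
                               bh_family = c("module", "global")) {
  stopifnot(inherits(db, "mirna_target_db"))
  bh_family <- match.arg(bh_family)
  lncs <- intersect(module_genes[biotypes[module_genes] == "lncRNA"],
                    names(db$lnc_targets))
  mrnas <- intersect(module_genes[biotypes[module_genes] == "mRNA"],
                     names(db$mrna_targets))
  empty <- data.frame(
    lncrna = character(0), mrna = character(0), module = integer(0),
    t = integer(0), n = integer(0), M = integer(0), N = integer(0),
    p = numeric(0), p_adj = numeric(0), shared_mirnas = character(0),
    stringsAsFactors = FALSE
  )
  if (!length(lncs) || !length(mrnas)) {
    warning("module ", module_id, " has no lncRNA or no mRNA with miRNA targets")
    return(structure(list(edges = empty, tested = empty), class = "cerna_network"))
  }
  rows <- list()
  for (lnc in lncs) {
    ltar <- db$lnc_targets[[lnc]]
    for (mr in mrnas) {
      shared <- intersect(ltar, db$mrna_targets[[mr]])
      if (!length(shared)) next
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna = lnc, mrna = mr, module = module_id,
        t = length(shared), n = length(ltar),
        M = length(db$mrna_targets[[mr]]), N = db$N,
        shared_mirnas = paste(sort(shared), collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(structure(list(edges = empty, tested = empty), class = "cerna_network"))
  }
  tested <- do.call(rbind, rows)
  tested$p <- hypergeom_p(tested$N, tested$M, tested$n, tested$t)
  tested$p_adj <- if (bh_family == "module") bh_adjust(tested$p) else NA_real_
  crit <- if (use_adjusted) tested$p_adj else tested$p
  edges <- tested[crit < alpha, , drop = FALSE]
  rownames(edges) <- NULL
  cols <- c("lncrna", "mrna", "module", "t", "n", "M", "N", "p", "p_adj",
            "shared_mirnas")
  structure(list(edges = edges[, cols], tested = tested[, cols]),
            class = "cerna_network")
}

#' Aggregate module-specific ceRNA networks
#'
#' Unions the edges of several module networks into one bipartite
#' lncRNA-mRNA network (modules are disjoint, so no duplicate edges can
#' arise; this is checked) and annotates nodes with biotype, module and a
#' known-disease-gene flag from the seed list.
#'
#' @param networks list of [build_module_cerna()] results.
#' @param seed_genes character vector of known disease genes.
#' @return object of class `cerna_network` with `edges` and `nodes`
#'   (data.frame gene, biotype, module, is_known_disease_gene).
#' @export
aggregate_networks <- function(networks, seed_genes = character(0)) {
  stopifnot(length(networks) >= 1)
  edges <- do.call(rbind, lapply(networks, `[[`, "edges"))
  rownames(edges) <- NULL
  if (anyDuplicated(edges[, c("lncrna", "mrna")])) {
    stop("duplicate lncRNA-mRNA edges across modules; modules must be disjoint")
  }
  nodes <- rbind(
    data.frame(gene = edges$lncrna, biotype = "lncRNA", module = edges$module,
               stringsAsFactors = FALSE),
    data.frame(gene = edges$mrna, biotype = "mRNA", module = edges$module,
               stringsAsFactors = FALSE)
  )
  nodes <- nodes[!duplicated(nodes$gene), , drop = FALSE]
  nodes <- nodes[order(nodes$gene), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes$is_known_disease_gene <- nodes$gene %in% seed_genes
  structure(list(edges = edges, nodes = nodes), class = "cerna_network")
}

#' Over-representation analysis against user-supplied gene sets
#'
#' For each set, tests the overlap of `gene_list` with the set inside
#' `universe` by the upper-tail hypergeometric probability and adjusts
#' across sets by Benjamini-Hochberg.
#'
#' @param gene_list character vector, must be contained in `universe`.
#' @param universe character vector of all candidate genes.
#' @param gene_sets named list of character vectors.
#' @return data.frame (set, overlap, set_size, p, p_adj) sorted by p.
#' @export
enrich_ora <- function(gene_list, universe, gene_sets) {
  if (!length(universe)) stop("empty universe")
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe)) stop("gene_list must be a subset of universe")
  N <- length(unique(universe))
  n <- length(gene_list)
  res <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    t <- length(intersect(set, gene_list))
    data.frame(set = nm, overlap = t, set_size = length(set),
               p = hypergeom_p(N, length(set), n, t), stringsAsFactors = FALSE)
  }))
  res$p_adj <- bh_adjust(res$p)
  res[order(res$p), ]
}
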