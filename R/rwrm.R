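#' Multiplex graph over a shared node set
#'
#' @param layers named list of symmetric nonnegative adjacency matrices, all
#'   indexed by the same ordered node set (dimnames required and identical);
#'   diagonals are forced to zero.
#' @return object of class `multiplex_graph` with `layers`, `nodes`, `n`,
#'   `L`.
#' @export
multiplex_graph <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers))) names(layers) <- paste0("layer", seq_along(layers))
  nodes <- rownames(layers[[1]])
  if (is.null(nodes)) stop("layer adjacency matrices need dimnames")
  for (i in seq_along(layers)) {
    a <- layers[[i]]
    stopifnot(is.matrix(a), identical(rownames(a), nodes),
              identical(colnames(a), nodes))
    if (any(a < 0)) stop("negative weights in layer ", i)
    if (max(abs(a - t(a))) > 1e-12) stop("layer ", i, " not symmetric")
    diag(a) <- 0
    layers[[i]] <- a
  }
  structure(list(layers = layers, nodes = nodes, n = length(nodes),
                 L = length(layers)), class = "multiplex_graph")
}

#' Build a layer adjacency from an edge list
#'
#' @param edges data.frame whose first two columns are node IDs; an optional
#'   `weight` column is used when `weighted = TRUE`, otherwise edges are
#'   0/1.
#' @param nodes ordered node set of the layer.
#' @param weighted use edge weights instead of 0/1.
#' @return symmetric adjacency matrix over `nodes`.
#' @export
edges_to_adjacency <- function(edges, nodes, weighted = FALSE) {
  a <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  keep <- edges[[1]] %in% nodes & edges[[2]] %in% nodes
  e <- edges[keep, , drop = FALSE]
  w <- if (weighted && "weight" %in% names(e)) e$weight else rep(1, nrow(e))
  for (i in seq_len(nrow(e))) {
    a[e[[1]][i], e[[2]][i]] <- w[i]
    a[e[[2]][i], e[[1]][i]] <- w[i]
  }
  diag(a) <- 0
  a
}

#' Supra-transition matrix of a multiplex graph
#'
#' Assembles the nL x nL block matrix with `(1 - delta) A^[alpha]` on the
#' diagonal blocks and `delta / (L - 1) I` off-diagonal (the probability of
#' jumping to the same node in another layer), then column-normalizes it.
#' With a single layer delta degenerates to 0, reducing to the
#' column-normalized adjacency. A node isolated in every layer (all-zero
#' column) is given the uniform teleportation column so the matrix stays
#' column-stochastic.
#'
#' @param graph a [multiplex_graph()].
#' @param delta layer-jump probability in \[0, 1\] (default 0.5).
#' @return column-stochastic nL x nL matrix, rows/cols named
#'   `node@layer`.
#' @export
build_supra_transition <- function(graph, delta = 0.5) {
  stopifnot(inherits(graph, "multiplex_graph"), delta >= 0, delta <= 1)
  n <- graph$n
  L <- graph$L
  if (L == 1) delta <- 0
  S <- matrix(0, n * L, n * L)
  idx <- function(a) seq.int((a - 1) * n + 1, a * n)
  for (a in seq_len(L)) {
    S[idx(a), idx(a)] <- (1 - delta) * graph$layers[[a]]
    if (L > 1) {
      for (b in seq_len(L)[-a]) {
        S[idx(b), idx(a)] <- diag(delta / (L - 1), n)
      }
    }
  }
  cs <- colSums(S)
  zero <- cs == 0
  if (any(zero)) {
    S[, zero] <- 1 / (n * L) # teleport from fully isolated nodes
    cs[zero] <- 1
  }
  S <- sweep(S, 2, cs, "/")
  nm <- as.vector(outer(graph$nodes, names(graph$layers), paste, sep = "@"))
  dimnames(S) <- list(nm, nm)
  S
}

#' Layer weights from the two-layer edge-count ratio
#'
#' `tau = [2 / (1 + R), 2 R / (1 + R)]`, where `R` is the ratio of the
#' number of first-layer (ceRNA-guided) edges to second-layer
#' (functional-interaction) edges; the weights always sum to 2 = L.
#'
#' @param R positive edge-count ratio.
#' @return numeric vector of length 2.
#' @export
layer_weights <- function(R) {
  if (!is.numeric(R) || length(R) != 1 || R <= 0) stop("R must be a positive number")
  c(2 / (1 + R), 2 * R / (1 + R))
}

#' Random walk with restart on a multiplex graph
#'
#' Iterates `p_{t+1} = (1 - r) M p_t + r p_RS` until the L1 change drops
#' below `tolerance`, where `M` is the column-normalized supra-transition
#' matrix, the initial distribution assigns `1/k` to each of the `k` seed
#' nodes within every layer, and the restart distribution reweights layer
#' alpha by `tau_alpha / L` (so it remains a probability vector). The
#' stationary probabilities measure each node's proximity to the seed set;
#' a node's global score aggregates its probabilities across layers (sum by
#' default, geometric mean optionally).
#'
#' @param graph a [multiplex_graph()].
#' @param seeds character vector of seed nodes (must intersect the node
#'   set).
#' @param delta layer-jump probability (default 0.5).
#' @param r restart probability in (0, 1\] (default 0.7).
#' @param tau per-layer weights, length L, nonnegative, summing to L
#'   (default equal weights).
#' @param tolerance L1 convergence threshold (default 1e-10).
#' @param max_iter iteration cap (default 1e4).
#' @param aggregate `"sum"` or `"geometric"`.
#' @return object of class `rwrm_result`: list with `probabilities`
#'   (node x layer matrix), `global` (named vector), `ranking` (data.frame
#'   node, score, per-layer columns, is_seed), `iterations`, `delta`, `r`,
#'   `tau`.
#' @export
rwrm_scores <- function(graph, seeds, delta = 0.5, r = 0.7, tau = NULL,
                        tolerance = 1e-10, max_iter = 1e4,
                        aggregate = c("sum", "geometric")) {
  stopifnot(inherits(graph, "multiplex_graph"), r > 0, r <= 1)
  aggregate <- match.arg(aggregate)
  seeds <- intersect(seeds, graph$nodes)
  if (!length(seeds)) stop("no seed present in the network")
  n <- graph$n
  L <- graph$L
  if (is.null(tau)) tau <- rep(1, L)
  stopifnot(length(tau) == L, all(tau >= 0))
  if (abs(sum(tau) - L) > 1e-8) stop("tau must sum to the number of layers")
  S <- build_supra_transition(graph, delta)
  p0 <- rep(as.numeric(graph$nodes %in% seeds) / length(seeds), L)
  p_rs <- p0 * rep(tau / L, each = n)
  p <- p_rs
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p_new <- (1 - r) * as.vector(S %*% p) + r * p_rs
    delta_l1 <- sum(abs(p_new - p))
    p <- p_new
    if (delta_l1 < tolerance) break
    if (iter >= max_iter) {
      stop("random walk did not converge in ", max_iter, " iterations")
    }
  }
  probs <- matrix(p, n, L, dimnames = list(graph$nodes, names(graph$layers)))
  global <- switch(aggregate,
    sum = rowSums(probs),
    geometric = apply(probs, 1, function(x) exp(mean(log(pmax(x, 1e-300)))))
  )
  ranking <- data.frame(node = graph$nodes, score = global, probs,
                        is_seed = graph$nodes %in% seeds,
                        row.names = NULL, check.names = FALSE,
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$score, ranking$node), ]
  rownames(ranking) <- NULL
  structure(list(probabilities = probs, global = global, ranking = ranking,
                 iterations = iter, delta = delta, r = r, tau = tau,
                 seeds = seeds),
            class = "rwrm_result")
}

#' Prioritize lncRNAs by global random-walk score
#'
#' Ranks lncRNA nodes (seed nodes are excluded from candidacy) by global
#' score, descending, ties broken by node ID, and returns the top `top_k`.
#'
#' @param result a [rwrm_scores()] result.
#' @param biotypes named character vector (`lncRNA`/`mRNA`) covering the
#'   network nodes.
#' @param top_k number of lncRNAs to return (default 2); values past the
#'   number of candidates return the full ranked list.
#' @return data.frame (node, score, rank).
#' @export
prioritize_lncrnas <- function(result, biotypes, top_k = 2) {
  stopifnot(inherits(result, "rwrm_result"))
  cand <- result$ranking[
    biotypes[result$ranking$node] == "lncRNA" & !result$ranking$is_seed,
    c("node", "score")
  ]
  if (!nrow(cand)) stop("no lncRNA node in the network")
  cand <- cand[order(-cand$score, cand$node), ]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  utils::head(cand, top_k)
}
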