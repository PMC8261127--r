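random_multiplex <- function(n, L = 2, p_edge = 0.1, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n))
  layers <- lapply(seq_len(L), function(l) {
    a <- matrix(rbinom(n * n, 1, p_edge), n)
    a <- pmax(a, t(a))
    diag(a) <- 0
    dimnames(a) <- list(nodes, nodes)
    a
  })
  names(layers) <- paste0("layer", seq_len(L))
  multiplex_graph(layers)
}

test_that("supra-transition matrix is column-stochastic with the block form", {
  # hand-built oracle for n = 2, L = 2, single edge in both layers
  a <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  g <- multiplex_graph(list(l1 = a, l2 = a))
  S <- build_supra_transition(g, delta = 0.5)
  # before normalization: diag blocks 0.5*A, off-diag blocks 0.5*I; every
  # column then sums to 1, so normalization leaves the entries at 0.5
  oracle <- matrix(0, 4, 4)
  oracle[1:2, 1:2] <- 0.5 * a
  oracle[3:4, 3:4] <- 0.5 * a
  oracle[3:4, 1:2] <- diag(0.5, 2)
  oracle[1:2, 3:4] <- diag(0.5, 2)
  expect_equal(unname(S), oracle, tolerance = 1e-12)
  # random multiplexes: columns always sum to one
  for (seed in 1:3) {
    g2 <- random_multiplex(sample(5:30, 1), seed = seed)
    S2 <- build_supra_transition(g2, 0.5)
    expect_equal(unname(colSums(S2)), rep(1, nrow(S2)), tolerance = 1e-12)
  }
  # single layer reduces to the column-normalized adjacency
  g1 <- multiplex_graph(list(only = a))
  expect_equal(unname(build_supra_transition(g1, 0.7)),
               sweep(a, 2, colSums(a), "/"), ignore_attr = TRUE)
  # isolated-everywhere node gets the uniform teleport column
  iso <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  iso["a", "b"] <- iso["b", "a"] <- 1
  gi <- multiplex_graph(list(l1 = iso, l2 = iso))
  Si <- build_supra_transition(gi, 0)
  expect_equal(unname(Si[, 3]), rep(1 / 6, 6))
})

test_that("layer weights follow the two-layer ratio formula", {
  expect_equal(layer_weights(1), c(1, 1))
  expect_equal(layer_weights(3), c(0.5, 1.5))
  for (R in c(0.1, 0.5, 2, 7.3)) {
    expect_equal(sum(layer_weights(R)), 2, tolerance = 1e-12)
  }
  expect_error(layer_weights(0), "positive")
  expect_error(layer_weights(-2), "positive")
})

test_that("restart-only walk returns the restart distribution", {
  g <- random_multiplex(20, seed = 5)
  res <- rwrm_scores(g, seeds = g$nodes[1:3], r = 1, tau = c(1.5, 0.5))
  p_rs <- c(as.numeric(g$nodes %in% g$nodes[1:3]) / 3 * 1.5 / 2,
            as.numeric(g$nodes %in% g$nodes[1:3]) / 3 * 0.5 / 2)
  expect_equal(as.vector(res$probabilities), p_rs, tolerance = 1e-12)
})

test_that("iterative walk matches the direct linear solve", {
  for (case in list(c(50, 6), c(120, 9), c(200, 12))) {
    g <- random_multiplex(case[1], p_edge = 0.07, seed = case[1])
    seeds <- g$nodes[seq_len(case[2])]
    res <- rwrm_scores(g, seeds, delta = 0.5, r = 0.7)
    S <- build_supra_transition(g, 0.5)
    p0 <- rep(as.numeric(g$nodes %in% seeds) / length(seeds), 2)
    p_rs <- p0 * rep(c(1, 1) / 2, each = case[1])
    direct <- 0.7 * solve(diag(2 * case[1]) - 0.3 * S, p_rs)
    expect_lt(max(abs(as.vector(res$probabilities) - direct)), 1e-8)
    expect_equal(sum(res$probabilities), 1, tolerance = 1e-8)
  }
})

test_that("raising the restart probability concentrates mass on seeds", {
  g <- random_multiplex(40, seed = 8)
  seeds <- g$nodes[1:4]
  seed_mass <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(r) {
    res <- rwrm_scores(g, seeds, r = r)
    sum(res$global[seeds])
  }, numeric(1))
  expect_true(all(diff(seed_mass) > 0))
})

test_that("identical decoupled layers reproduce the single-layer walk", {
  # with the inter-layer jump off, the two copies evolve independently and
  # the restart vector splits its unit mass evenly between them, so each
  # node's global score (summed over layers) equals its single-layer
  # probability exactly; with coupling on, column normalization makes the
  # collapsed chain a lazy walk with renormalized degrees, so no exact
  # relation holds
  set.seed(9)
  a <- matrix(rbinom(900, 1, 0.15), 30)
  a <- pmax(a, t(a)); diag(a) <- 0
  dimnames(a) <- list(sprintf("n%02d", 1:30), sprintf("n%02d", 1:30))
  g2 <- multiplex_graph(list(l1 = a, l2 = a))
  g1 <- multiplex_graph(list(l1 = a))
  seeds <- rownames(a)[1:3]
  two <- rwrm_scores(g2, seeds, delta = 0, r = 0.7, tau = c(1, 1))
  one <- rwrm_scores(g1, seeds, r = 0.7)
  expect_equal(two$global, one$global, tolerance = 1e-8)
  # and the per-layer distributions are identical halves
  expect_equal(two$probabilities[, 1], two$probabilities[, 2],
               tolerance = 1e-10)
})

test_that("lncRNA prioritization excludes seeds and breaks ties by ID", {
  a <- matrix(0, 6, 6)
  nodes <- c("lncB", "lncA", "lncC", "m1", "m2", "m3")
  dimnames(a) <- list(nodes, nodes)
  a["lncA", "m1"] <- a["m1", "lncA"] <- 1 # only lncA is wired to the seed
  g <- multiplex_graph(list(l1 = a, l2 = a))
  res <- rwrm_scores(g, seeds = "m1")
  biotypes <- c(lncA = "lncRNA", lncB = "lncRNA", lncC = "lncRNA",
                m1 = "mRNA", m2 = "mRNA", m3 = "mRNA")
  top <- prioritize_lncrnas(res, biotypes, top_k = 10)
  expect_identical(top$node[1], "lncA")
  # the two isolated lncRNAs tie and appear in ID order
  expect_identical(top$node[2:3], c("lncB", "lncC"))
  expect_equal(top$score[2], top$score[3], tolerance = 1e-12)
  expect_identical(top$rank, 1:3)
  expect_identical(nrow(prioritize_lncrnas(res, biotypes, top_k = 2)), 2L)
  expect_error(rwrm_scores(g, seeds = "absent"), "no seed")
})
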