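# Shared fixtures and independent oracles for the test suite.

# -- memoized default-cohort pipeline run (expensive; computed once) ---------
.run_cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.run_cache$report)) {
    dir <- file.path(tempdir(), "afcerna-default-run")
    .run_cache$report <- suppressMessages(
      run_all(default_config(out_dir = dir, rng_seed = 1L))
    )
    .run_cache$dir <- dir
  }
  list(report = .run_cache$report, dir = .run_cache$dir)
}

# -- a fast generator configuration for unit tests ---------------------------
small_config <- function(...) {
  defaults <- list(
    n_samples_per_group = c("SR/SR" = 15, "AF/SR" = 20, "AF/AF" = 25),
    n_genes = 400L, n_lncrna = 40L, n_modules = 3L, module_size = 50L,
    n_planted_per_module = 8L, n_seed_genes = 6L,
    decoy_coverage = c(lncRNA = 2, mRNA = 8), n_mirnas = 300L,
    n_layer2_background = 40L, rng_seed = 11L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# the construction used for classifier sanity checks: a clearly separable
# planted AF signal in the hub's pair genes plus a saturating platform
# confound aligned against the signal in the test cohort
classifier_config <- function() {
  simulation_config(
    n_genes = 800L, n_lncrna = 80L, n_modules = 2L, module_size = 100L,
    trait_module_effects = list(
      "1" = list(contrast = "susceptibility", effect = 3.5),
      "2" = list(contrast = "persistence", effect = 3.5)
    ),
    n_planted_per_module = 12L, decoy_coverage = c(lncRNA = 2, mRNA = 10),
    n_seed_genes = 16L, batch_confound = 2, rng_seed = 777L
  )
}

# -- independent oracles -----------------------------------------------------

# exact upper-tail hypergeometric probability by direct combinatorial
# enumeration over k (plain choose(), no logs)
oracle_hyper <- function(N, M, n, t) {
  if (t == 0) return(1)
  ks <- t:min(n, M)
  sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}

# hand-coded BH step-up formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# brute-force all-pairs AUC (U statistic with half credit for ties)
oracle_auc_allpairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# independent scale-free fit: same equal-width log10 binning, slope and R^2
# via closed-form least squares instead of the package's lm path
oracle_scale_free_scan <- function(expr, candidates, n_breaks = 10) {
  C <- stats::cor(t(expr))
  base <- (1 + C) / 2
  diag(base) <- 0
  vapply(candidates, function(b) {
    k <- rowSums(base^b)
    k <- k[k > 0]
    bins <- cut(log10(k), n_breaks, include.lowest = TRUE)
    freq <- tabulate(bins, nbins = n_breaks)
    mk <- tapply(k, bins, mean)
    ok <- freq > 0
    x <- log10(mk[ok])
    y <- log10(freq[ok])
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - slope * mean(x)
    r2 <- 1 - sum((y - a - slope * x)^2) / sum((y - mean(y))^2)
    -sign(slope) * r2
  }, numeric(1))
}

# expression whose correlation network has hub structure: a few genes
# follow a shared factor with high fidelity and most only weakly, giving a
# heavy-tailed connectivity distribution with a falling degree histogram
hub_structured_expr <- function(n_genes = 100, n_samples = 50, seed = 31) {
  set.seed(seed)
  f <- rnorm(n_samples)
  w <- seq_len(n_genes)^(-0.6)
  x <- outer(w, f) + sqrt(1 - w^2) * matrix(rnorm(n_genes * n_samples), n_genes)
  rownames(x) <- sprintf("g%03d", seq_len(n_genes))
  x
}

# minimal ceRNA network object for tests that only need an edge table
fake_network <- function(edges) {
  structure(list(edges = edges, tested = edges), class = "cerna_network")
}
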