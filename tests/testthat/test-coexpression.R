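test_that("signed adjacency maps correlations as ((1+cor)/2)^beta", {
  x <- c(1, 0, -1, 0)
  y <- c(0, 1, 0, -1) # exactly uncorrelated with x
  expr <- rbind(a = x, b = 2 * x, c = -x, d = y)
  colnames(expr) <- paste0("s", 1:4)
  a12 <- signed_adjacency(expr, 12)
  expect_equal(a12["a", "b"], 1)            # cor +1
  expect_equal(a12["a", "c"], 0)            # cor -1
  expect_equal(a12["a", "d"], 2^-12)        # cor 0 at beta 12
  expect_true(all(a12 >= 0 & a12 <= 1))
  expect_equal(a12, t(a12))
  expect_error(signed_adjacency(rbind(expr, e = rep(1, 4)), 2), "zero-variance")
})

test_that("soft-threshold choice matches an independent regression oracle", {
  expr <- hub_structured_expr()
  candidates <- 1:20
  oracle_fits <- oracle_scale_free_scan(expr, candidates)
  # threshold derived from the oracle scan, not from the implementation
  thr <- 0.8 * max(oracle_fits)
  oracle_choice <- candidates[which(oracle_fits >= thr)[1]]
  b <- pick_beta(expr, candidates, fit_threshold = thr)
  expect_identical(as.integer(b), oracle_choice)
  expect_equal(attr(b, "fit_table")$fit, unname(oracle_fits), tolerance = 1e-8)
  # every smaller candidate fails the threshold under the oracle too
  if (oracle_choice > 1) {
    expect_true(all(oracle_fits[candidates < oracle_choice] < thr))
  }
  # a permissive threshold returns the smallest candidate
  expect_gt(oracle_fits[1], 0) # slope negative at beta = 1 on this data
  expect_identical(as.integer(pick_beta(expr, candidates, fit_threshold = 0)), 1L)
  # unreachable threshold errors and reports the best fit
  expect_error(pick_beta(expr, candidates, fit_threshold = 0.999),
               "best was")
})

test_that("degenerate connectivity is rejected", {
  prof <- rnorm(10)
  expr <- rbind(a = prof, b = 2 * prof, c = 3 * prof) # all cor exactly 1
  colnames(expr) <- paste0("s", 1:10)
  expect_error(pick_beta(expr, 1:5), "degenerate|undefined")
})

test_that("topological overlap matches closed forms", {
  # two-node network: TOM equals the adjacency
  a2 <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(compute_tom(a2)["a", "b"], 0.3)
  # complete unit graph: all overlap 1
  ones <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  expect_true(all(compute_tom(ones) == 1))
  # empty graph: identity pattern
  zero <- diag(5)
  dimnames(zero) <- list(letters[1:5], letters[1:5])
  tz <- compute_tom(zero)
  expect_equal(tz, diag(5), ignore_attr = TRUE)
  expect_error(compute_tom(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("TOM is symmetric and bounded on random adjacencies", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(5:25, 1)
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
    tom <- compute_tom(a)
    expect_lt(max(abs(tom - t(tom))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(all(diag(tom) == 1))
  }
})

test_that("module detection recovers planted blocks under the size rule", {
  block_tom <- function(sizes, within = 0.9, between = 0.01) {
    n <- sum(sizes)
    t <- matrix(between, n, n)
    start <- cumsum(c(1, sizes))
    for (i in seq_along(sizes)) {
      idx <- start[i]:(start[i + 1] - 1)
      t[idx, idx] <- within
    }
    diag(t) <- 1
    dimnames(t) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
    t
  }
  tom <- block_tom(c(40, 50))
  cl <- cluster_modules(tom, min_module_size = 30)
  expect_identical(max(cl$labels), 2L)
  expect_identical(unname(cl$labels[1:40]), rep(2L, 40)) # smaller block -> id 2
  expect_identical(unname(cl$labels[41:90]), rep(1L, 50))
  # blocks below the minimum size are unassigned
  expect_warning(cl2 <- cluster_modules(block_tom(c(10, 15)), min_module_size = 30),
                 "min_module_size")
  expect_true(all(cl2$labels == 0L))
  # a single perfectly duplicated profile forms one module
  ones <- matrix(1, 60, 60, dimnames = list(sprintf("g%02d", 1:60),
                                            sprintf("g%02d", 1:60)))
  cl3 <- cluster_modules(ones, min_module_size = 30)
  expect_identical(max(cl3$labels), 1L)
  expect_true(all(cl3$labels == 1L))
})

test_that("module eigengene equals the first principal component", {
  set.seed(22)
  prof <- rnorm(30)
  # rank-1 module: every gene a copy of one profile
  expr1 <- outer(c(1, 2, 0.5, 3), prof) + 5
  dimnames(expr1) <- list(paste0("g", 1:4), paste0("s", 1:30))
  me <- module_eigengene(expr1, rownames(expr1))
  zs <- (prof - mean(prof)) / sd(prof)
  expect_equal(unname(me), zs / sqrt(sum(zs^2)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(attr(me, "var_explained"), 1, tolerance = 1e-12)
  # two-gene module against a full SVD oracle
  expr2 <- matrix(rnorm(60), 2, 30,
                  dimnames = list(c("a", "b"), paste0("s", 1:30)))
  me2 <- module_eigengene(expr2, c("a", "b"))
  xs <- t(scale(t(expr2)))
  v1 <- svd(xs)$v[, 1]
  expect_equal(abs(unname(me2)), abs(v1), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sqrt(sum(me2^2)), 1, tolerance = 1e-12)
  # sign convention on random modules
  for (i in 1:5) {
    ex <- matrix(rnorm(8 * 20), 8, 20,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:20)))
    m <- module_eigengene(ex, rownames(ex))
    expect_gte(cor(m, colMeans(t(scale(t(ex))))), 0)
  }
  expect_error(module_eigengene(rbind(expr2, c = rep(1, 30)), c("a", "c")),
               "zero-variance")
})

test_that("eigengene merging joins only similar modules", {
  set.seed(23)
  n <- 60
  fA <- rnorm(n)
  fB <- 0.95 * fA + sqrt(1 - 0.95^2) * rnorm(n) # highly correlated factor
  fC <- rnorm(n)                                 # independent factor
  make_genes <- function(f, k, prefix) {
    x <- outer(rep(1, k), f) + matrix(rnorm(k * n, sd = 0.05), k)
    rownames(x) <- paste0(prefix, seq_len(k))
    x
  }
  expr <- rbind(make_genes(fA, 10, "a"), make_genes(fB, 10, "b"),
                make_genes(fC, 10, "c"))
  colnames(expr) <- paste0("s", seq_len(n))
  labels <- setNames(rep(1:3, each = 10), rownames(expr))
  # modules 1 and 2 share a factor: merged; 3 stays
  mg <- merge_modules(labels, expr, cut_height = 0.25)
  expect_identical(max(mg$labels), 2L)
  expect_identical(length(unique(mg$labels[paste0("a", 1:10)])), 1L)
  expect_identical(unique(mg$labels[paste0("a", 1:10)]),
                   unique(mg$labels[paste0("b", 1:10)]))
  expect_identical(nrow(mg$merge_history), 1L)
  # dissimilar modules are untouched
  labels2 <- setNames(rep(c(1L, 3L), each = 10),
                      c(paste0("a", 1:10), paste0("c", 1:10)))
  mg2 <- merge_modules(labels2, expr[names(labels2), ], cut_height = 0.25)
  expect_identical(max(mg2$labels), 2L)
  expect_identical(nrow(mg2$merge_history), 0L)
  # identical eigengenes always merge
  labels3 <- setNames(rep(1:2, each = 5), paste0("a", 1:10))
  mg3 <- merge_modules(labels3, expr[names(labels3), ], cut_height = 0.25)
  expect_identical(max(mg3$labels), 1L)
})

test_that("module-trait correlation uses the right samples and codes", {
  pheno <- data.frame(
    sample_id = sprintf("s%02d", 1:60),
    rhythm = rep(c("SR/SR", "AF/SR", "AF/AF"), each = 20),
    stringsAsFactors = FALSE
  )
  code <- c(rep(0, 20), rep(1, 20)) # susceptibility coding on its subset
  me <- cbind(ME1 = c(code, rnorm(20)), ME2 = rnorm(60))
  rownames(me) <- pheno$sample_id
  res <- module_trait_correlation(me, pheno, "susceptibility")
  expect_equal(res$r[res$module == 1], 1, tolerance = 1e-12)
  expect_identical(unique(res$n), 40L)
  # an eigengene exactly orthogonal to the trait code: r ~ 0, p large
  set.seed(24)
  v <- rnorm(40)
  X <- cbind(1, code)
  v_orth <- v - X %*% qr.coef(qr(X), v)
  me2 <- cbind(ME1 = c(v_orth, rnorm(20)))
  rownames(me2) <- pheno$sample_id
  res2 <- module_trait_correlation(me2, pheno, "susceptibility")
  expect_lt(abs(res2$r), 1e-10)
  expect_gt(res2$p, 0.5)
  # permutation oracle agrees that the correlation is null
  obs <- abs(res2$r)
  perm <- replicate(200, abs(cor(sample(code), v_orth)))
  expect_gt(mean(perm >= obs), 0.5)
  # persistence contrast uses AF/AF vs AF/SR
  me3 <- cbind(ME1 = c(rnorm(20), rep(0, 20), rep(1, 20)))
  rownames(me3) <- pheno$sample_id
  res3 <- module_trait_correlation(me3, pheno, "persistence")
  expect_equal(res3$r, 1, tolerance = 1e-12)
  expect_error(
    module_trait_correlation(me3[1:40, , drop = FALSE], pheno[1:40, ],
                             "persistence"),
    "constant"
  )
})
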