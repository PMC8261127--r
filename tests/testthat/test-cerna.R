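test_that("hypergeometric tail matches hand-derived values", {
  expect_equal(hypergeom_p(10, 5, 4, 0), 1)
  expect_equal(hypergeom_p(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_p(10, 5, 4, 2), 1 - 55 / 210, tolerance = 1e-12)
  # symmetric in the two target-set sizes
  expect_equal(hypergeom_p(100, 20, 7, 3), hypergeom_p(100, 7, 20, 3),
               tolerance = 1e-14)
  expect_error(hypergeom_p(10, 11, 4, 2), "require")
  expect_error(hypergeom_p(10, 5, 4, 5), "require")
})

test_that("hypergeometric tail agrees with enumeration and phyper", {
  set.seed(31)
  for (i in 1:200) {
    N <- sample(2:60, 1)
    M <- sample(0:N, 1)
    n <- sample(0:N, 1)
    t <- sample(0:min(n, M), 1)
    p <- hypergeom_p(N, M, n, t)
    expect_equal(p, oracle_hyper(N, M, n, t), tolerance = 1e-12)
    # independent library cross-check
    expect_equal(p, stats::phyper(t - 1, M, N - M, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(32)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 0)), "TRUE")
})

make_toy_db <- function() {
  # lnc1 shares all 8 of its miRNAs with m1 (M = 10); lnc2 has no targets in
  # the table; filler gene inflates the universe to N = 200
  mir <- sprintf("mir%03d", 1:200)
  lnc_pairs <- data.frame(gene_id = "lnc1", mirna_id = mir[1:8])
  mrna_pairs <- rbind(
    data.frame(gene_id = "m1", mirna_id = mir[c(1:8, 100, 101)]),
    data.frame(gene_id = "m2", mirna_id = mir[150:157]),
    data.frame(gene_id = "filler", mirna_id = mir)
  )
  mirna_target_db(lnc_pairs, mrna_pairs)
}

test_that("module ceRNA networks follow the intramodule p < alpha rule", {
  db <- make_toy_db()
  expect_identical(db$N, 200L)
  biotypes <- c(lnc1 = "lncRNA", lnc2 = "lncRNA", m1 = "mRNA", m2 = "mRNA",
                filler = "mRNA")
  nw <- build_module_cerna(c("lnc1", "lnc2", "m1", "m2"), biotypes, db,
                           module_id = 7)
  # full overlap is significant; the disjoint pair is not even tested
  expect_identical(nw$edges$lncrna, "lnc1")
  expect_identical(nw$edges$mrna, "m1")
  expect_identical(nw$edges$t, 8L)
  expect_equal(nw$edges$p, hypergeom_p(200, 10, 8, 8), tolerance = 1e-12)
  expect_lt(nw$edges$p, 0.05)
  expect_identical(nw$edges$module, 7)
  expect_identical(nw$edges$shared_mirnas,
                   paste(sprintf("mir%03d", 1:8), collapse = ";"))
  # partners in different modules yield no edge
  nw2 <- build_module_cerna(c("lnc1", "m2"), biotypes, db)
  expect_identical(nrow(nw2$edges), 0L)
  # a module without lncRNA targets warns and returns an empty network
  expect_warning(nw3 <- build_module_cerna(c("lnc2", "m1"), biotypes, db),
                 "no lncRNA")
  expect_identical(nrow(nw3$edges), 0L)
})

test_that("lowering alpha never adds edges", {
  ds <- generate_dataset(small_config())
  truth <- ds$truth$modules
  genes <- names(truth)[truth == 1]
  prev <- NULL
  for (alpha in c(0.1, 0.05, 0.01, 0.001)) {
    nw <- build_module_cerna(genes, ds$biotypes, ds$mirna_db, 1, alpha = alpha)
    key <- paste(nw$edges$lncrna, nw$edges$mrna)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("planted pairs dominate decoys and survive BH selection", {
  ds <- generate_dataset(small_config())
  truth <- ds$truth$modules
  build <- function(adjusted) {
    nets <- lapply(1:3, function(m) {
      suppressWarnings(build_module_cerna(names(truth)[truth == m],
                                          ds$biotypes, ds$mirna_db, m,
                                          use_adjusted = adjusted))
    })
    do.call(rbind, lapply(nets, `[[`, "edges"))
  }
  edges <- build(FALSE)
  found <- paste(edges$lncrna, edges$mrna)
  planted <- paste(ds$truth$planted_pairs$lncrna, ds$truth$planted_pairs$mrna)
  # every planted pair is recovered, and decoy edges (if any) are the
  # borderline low-overlap ones: at this miniature database size a two-miRNA
  # chance overlap can cross p < 0.05, which the BH step removes
  expect_identical(mean(planted %in% found), 1)
  expect_true(all(edges$t[found %in% planted] == 8L))
  expect_true(all(edges$t[!(found %in% planted)] <= 3L))
  edges_adj <- build(TRUE)
  found_adj <- paste(edges_adj$lncrna, edges_adj$mrna)
  expect_identical(mean(planted %in% found_adj), 1)
  expect_gte(mean(found_adj %in% planted), 0.9)
})

test_that("network aggregation unions edges and flags disease genes", {
  mk <- function(n, module, prefix) {
    fake_network(data.frame(
      lncrna = paste0(prefix, "L", seq_len(n)),
      mrna = paste0(prefix, "M", seq_len(n)),
      module = module, t = 2L, n = 5L, M = 6L, N = 100L,
      p = 0.01, p_adj = 0.02, shared_mirnas = "mirX",
      stringsAsFactors = FALSE
    ))
  }
  one <- aggregate_networks(list(mk(3, 1, "a")))
  expect_identical(nrow(one$edges), 3L)
  four <- aggregate_networks(list(mk(3, 1, "a"), mk(4, 2, "b"),
                                  mk(5, 3, "c"), mk(6, 4, "d")),
                             seed_genes = c("aM1", "cM2", "zzz"))
  expect_identical(nrow(four$edges), 18L)
  flagged <- four$nodes$gene[four$nodes$is_known_disease_gene]
  expect_setequal(flagged, intersect(c("aM1", "cM2", "zzz"), four$nodes$gene))
  expect_error(aggregate_networks(list(mk(3, 1, "a"), mk(3, 2, "a"))),
               "duplicate")
})

test_that("over-representation test matches the enumeration oracle", {
  universe <- sprintf("g%03d", 1:100)
  sets <- list(hit = universe[1:10], miss = sprintf("x%02d", 1:10))
  gene_list <- universe[c(1:5, 50:54)]
  res <- enrich_ora(gene_list, universe, sets)
  hit <- res[res$set == "hit", ]
  expect_identical(hit$overlap, 5L)
  expect_equal(hit$p, oracle_hyper(100, 10, 10, 5), tolerance = 1e-12)
  expect_equal(res$p[res$set == "miss"], 1)
  # certain events have probability one
  all_res <- enrich_ora(universe, universe, list(everything = universe))
  expect_equal(all_res$p, 1)
  expect_error(enrich_ora("g001", character(0), sets), "empty universe")
  expect_error(enrich_ora("nope", universe, sets), "subset")
})
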