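test_that("identical config and seed reproduce the dataset; seeds differ", {
  cfg <- small_config()
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$train_counts, d2$train_counts)
  expect_identical(d1$mirna_db, d2$mirna_db)
  expect_identical(d1$test_expression, d2$test_expression)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(small_config(rng_seed = 12L))
  expect_false(identical(d1$train_counts, d3$train_counts))
})

test_that("dimensions and phenotype bookkeeping match the configuration", {
  cfg <- simulation_config(
    n_samples_per_group = c("SR/SR" = 20, "AF/SR" = 30, "AF/AF" = 50),
    n_genes = 500L, n_lncrna = 50L, n_modules = 3L, module_size = 60L,
    n_planted_per_module = 8L, n_seed_genes = 6L,
    decoy_coverage = c(lncRNA = 2, mRNA = 8), rng_seed = 3L
  )
  ds <- generate_dataset(cfg)
  expect_identical(dim(ds$train_counts), c(500L, 100L))
  expect_identical(as.integer(table(ds$phenotypes$rhythm)[c("SR/SR", "AF/SR", "AF/AF")]),
                   c(20L, 30L, 50L))
  expect_identical(colnames(ds$train_counts), ds$phenotypes$sample_id)
  # gene universe consistent across components
  genes <- rownames(ds$train_counts)
  expect_identical(rownames(ds$test_expression), genes)
  expect_true(all(ds$mirna_db$lnc_pairs$gene_id %in% genes))
  expect_true(all(unlist(ds$layer2_edges[, 1:2]) %in% genes))
  expect_true(all(ds$seed_genes %in% genes))
  # biotypes partition the genes
  expect_setequal(unique(ds$biotypes), c("lncRNA", "mRNA"))
  expect_identical(sum(ds$biotypes == "lncRNA"), 50L)
})

test_that("within-module correlation exceeds between-module correlation", {
  ds <- generate_dataset(small_config(module_base_cor = 0.6))
  truth <- ds$truth$modules
  m1 <- names(truth)[truth == 1]
  m2 <- names(truth)[truth == 2]
  cors <- stats::cor(t(ds$train_counts[c(m1, m2), ]))
  within <- c(cors[m1, m1][upper.tri(diag(length(m1)))],
              cors[m2, m2][upper.tri(diag(length(m2)))])
  between <- cors[m1, m2]
  expect_gt(mean(within), mean(between))
  expect_gt(mean(within), 0.3)
})

test_that("trait factors shift exactly in the designated contrast only", {
  ds <- generate_dataset(small_config())
  f <- ds$truth$factors
  grp <- ds$phenotypes$rhythm
  gm <- function(m, g) mean(f[m, grp == g])
  eff <- 2.5
  # susceptibility module: AF-history groups shifted, AF/AF == AF/SR
  expect_equal(gm(1, "AF/SR") - gm(1, "SR/SR"), eff, tolerance = 1e-10)
  expect_equal(gm(1, "AF/AF") - gm(1, "AF/SR"), 0, tolerance = 1e-10)
  # persistence module: only AF/AF shifted
  expect_equal(gm(2, "AF/SR") - gm(2, "SR/SR"), 0, tolerance = 1e-10)
  expect_equal(gm(2, "AF/AF") - gm(2, "AF/SR"), eff, tolerance = 1e-10)
  # null module: no shift anywhere
  expect_equal(gm(3, "AF/SR") - gm(3, "SR/SR"), 0, tolerance = 1e-10)
  expect_equal(gm(3, "AF/AF") - gm(3, "AF/SR"), 0, tolerance = 1e-10)
})

test_that("planted ceRNA pairs share exactly the configured miRNA counts", {
  ds <- generate_dataset(small_config())
  db <- ds$mirna_db
  pp <- ds$truth$planted_pairs
  shared <- mapply(function(l, m) {
    length(intersect(db$lnc_targets[[l]], db$mrna_targets[[m]]))
  }, pp$lncrna, pp$mrna)
  expect_identical(unname(shared), pp$shared)
  # hub wiring: connected to every seed gene via layer 1 or layer 2
  hub <- ds$truth$hub_lncrna
  l1 <- pp$mrna[pp$lncrna == hub]
  l2 <- ds$layer2_edges$gene_b[ds$layer2_edges$gene_a == hub]
  expect_true(all(ds$seed_genes %in% c(l1, l2)))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_modules = 100L, module_size = 300L,
                                 n_genes = 5000L),
               "capacity")
  cfg <- small_config(planted_cerna_pairs = data.frame(
    lncrna = "nope", mrna = "pc00001", shared = 3
  ))
  expect_error(generate_dataset(cfg), "unknown genes")
})

test_that("dataset writers emit readable pipeline inputs", {
  ds <- generate_dataset(small_config())
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  back <- read_matrix_tsv(paths[["counts"]])
  expect_equal(back, ds$train_counts)
  db <- read_mirna_targets(paths[["mirna"]])
  expect_identical(db$N, ds$mirna_db$N)
  expect_identical(sort(names(db$lnc_targets)), sort(names(ds$mirna_db$lnc_targets)))
  expect_identical(read_seed_genes(paths[["seeds"]]), ds$seed_genes)
})

test_that("generated gene sets cover modules and write valid GMT", {
  ds <- generate_dataset(small_config())
  sets <- generate_gene_sets(ds, n_sets = 10L, n_module_sets = 3L,
                             rng_seed = 5L)
  expect_length(sets, 10L)
  # module-aligned sets really sit inside their module
  truth <- ds$truth$modules
  expect_true(all(truth[sets[["MODULE1_SET"]]] == 1))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  reread <- load_gmt(path, min_size = 1, max_size = 1000)
  expect_identical(lapply(reread, sort), lapply(sets, sort))
})
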