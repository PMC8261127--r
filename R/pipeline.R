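#' Default end-to-end pipeline configuration
#'
#' All stage parameters default to the study's printed settings: low-count
#' filter (counts < 10 in more than 80% of samples), 2 surrogate variables,
#' top 5,000 variance genes, scale-free fit threshold 0.9 (with a fixed
#' fallback power of 12 when no candidate qualifies on a given dataset),
#' minimum module size 30, eigengene merge cut 0.25, two top modules per
#' contrast, ceRNA alpha 0.05, layer-jump probability 0.5, restart
#' probability 0.7, two top lncRNAs, six CV folds.
#'
#' @param out_dir directory for all written artifacts.
#' @param rng_seed master seed; each stochastic stage consumes a
#'   stage-specific child of it, so changing one stage's seed leaves
#'   upstream outputs unchanged.
#' @param simulation a [simulation_config()] for the synthetic cohort
#'   (seeded from `rng_seed` by default).
#' @param ... overrides for any config entry.
#' @return named list of class `run_config`.
#' @export
default_config <- function(out_dir, rng_seed = 1L,
                           simulation = simulation_config(rng_seed = rng_seed),
                           ...) {
  cfg <- list(
    out_dir = out_dir,
    rng_seed = as.integer(rng_seed),
    simulation = simulation,
    min_count = 10, max_low_fraction = 0.8, n_sv = 2, top_k = 5000,
    beta = "auto", beta_candidates = 1:20, fit_threshold = 0.9,
    beta_fallback = 12,
    min_module_size = 30, deep_split = 2, tree_cut_height = NULL,
    merge_cut_height = 0.25, n_top_modules_per_contrast = 2,
    alpha = 0.05, use_adjusted = FALSE,
    delta = 0.5, r = 0.7, rwr_tolerance = 1e-10, rwr_max_iter = 1e4,
    top_lncrnas = 2,
    gmt_min_size = 10, gmt_max_size = 500, n_gene_sets = 25,
    cv_folds = 6, ntree = 500
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror [default_config()]; unspecified keys keep their defaults.
#'
#' @param path YAML file.
#' @param out_dir output directory (may also be given in the file).
#' @return a `run_config`.
#' @export
read_config <- function(path, out_dir = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files")
  }
  vals <- yaml::read_yaml(path)
  if (!is.null(out_dir)) vals$out_dir <- out_dir
  if (is.null(vals$out_dir)) stop("config must provide out_dir")
  sim_args <- vals$simulation %||% list()
  vals$simulation <- NULL
  seed <- vals$rng_seed %||% 1L
  do.call(default_config, c(
    list(out_dir = vals$out_dir, rng_seed = seed,
         simulation = do.call(simulation_config,
                              c(sim_args, if (is.null(sim_args$rng_seed)) list(rng_seed = seed)))),
    vals[setdiff(names(vals), c("out_dir", "rng_seed"))]
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-cohort simulation, preprocessing (filter,
#' variance stabilization, surrogate variables, residualization, top-variance
#' selection), signed co-expression network and module detection, eigengene
#' merging, module-trait correlation and selection of the top modules per
#' contrast, module-specific ceRNA networks, aggregation, two-layer
#' multiplex random walk with restart seeded with the known disease genes,
#' lncRNA prioritization, pathway association for each top lncRNA, and
#' batch-harmonized random-forest classification (with a batch-retained
#' sensitivity run) for each top lncRNA. All declared artifacts are written
#' under `config$out_dir`; outputs contain no timestamps, so a fixed seed
#' reproduces every file byte for byte.
#'
#' @param config a [default_config()] / [read_config()] result.
#' @return a run report (named list of per-stage summaries), invisibly
#'   written to `run_report.json` as well.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_top_modules_per_contrast < 1) {
    stop("modules stage: n_top_modules_per_contrast must be at least 1")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  report <- list(config = config[setdiff(names(config), "simulation")])
  t0 <- proc.time()[["elapsed"]]

  ## -- simulate -------------------------------------------------------------
  dataset <- generate_dataset(config$simulation)
  write_dataset(dataset, out("data"))
  gene_sets <- generate_gene_sets(dataset, n_sets = config$n_gene_sets,
                                  rng_seed = config$rng_seed + 101L)
  write_gmt(gene_sets, out("data", "gene_sets.gmt"))
  report$simulate <- list(
    n_genes = nrow(dataset$train_counts),
    n_train = ncol(dataset$train_counts),
    n_test = ncol(dataset$test_expression),
    hub_lncrna = dataset$truth$hub_lncrna
  )

  ## -- preprocess -----------------------------------------------------------
  prep <- preprocess_expression(
    dataset$train_counts, dataset$phenotypes,
    min_count = config$min_count, max_low_fraction = config$max_low_fraction,
    n_sv = config$n_sv, top_k = config$top_k
  )
  write_matrix_tsv(round(prep$expr, 6), out("cleaned_expression.tsv"))
  report$preprocess <- list(
    n_filtered = prep$n_filtered, n_selected = nrow(prep$expr),
    n_sv = ncol(prep$svs)
  )

  ## -- co-expression network and modules ------------------------------------
  beta <- config$beta
  if (identical(beta, "auto")) {
    beta <- tryCatch(
      as.integer(pick_beta(prep$expr, config$beta_candidates,
                           config$fit_threshold)),
      error = function(e) {
        message("scale-free fit threshold not reached (", conditionMessage(e),
                "); using fallback power ", config$beta_fallback)
        as.integer(config$beta_fallback)
      }
    )
  }
  adj <- signed_adjacency(prep$expr, beta)
  tom <- compute_tom(adj)
  rm(adj)
  clus <- cluster_modules(tom, min_module_size = config$min_module_size,
                          deep_split = config$deep_split,
                          cut_height = config$tree_cut_height)
  rm(tom)
  merged <- merge_modules(clus$labels, prep$expr,
                          cut_height = config$merge_cut_height)
  labels <- merged$labels
  mes <- module_eigengenes(prep$expr, labels)
  utils::write.table(
    data.frame(gene_id = names(labels), module = labels,
               biotype = dataset$biotypes[names(labels)]),
    out("modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_matrix_tsv(round(t(mes), 6), out("eigengenes.tsv"))

  trait <- lapply(c("susceptibility", "persistence"), function(ct) {
    module_trait_correlation(mes, dataset$phenotypes, ct)
  })
  names(trait) <- c("susceptibility", "persistence")
  n_top <- config$n_top_modules_per_contrast
  selected <- lapply(trait, function(tt) utils::head(tt$module, n_top))
  jsonlite::write_json(trait, out("module_trait.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  report$modules <- list(
    beta = beta, cut_height = clus$cut_height,
    n_modules = max(labels), n_unassigned = sum(labels == 0),
    selected = selected,
    top_trait = lapply(trait, function(tt) tt[seq_len(min(n_top, nrow(tt))), ])
  )

  ## -- module-specific ceRNA networks ---------------------------------------
  sel_modules <- unique(unlist(selected))
  networks <- lapply(sel_modules, function(m) {
    build_module_cerna(names(labels)[labels == m], dataset$biotypes,
                       dataset$mirna_db, module_id = m,
                       alpha = config$alpha, use_adjusted = config$use_adjusted)
  })
  for (i in seq_along(sel_modules)) {
    utils::write.table(networks[[i]]$edges,
                       out(sprintf("cerna_module%d.tsv", sel_modules[i])),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  network <- aggregate_networks(networks, dataset$seed_genes)
  utils::write.table(network$edges, out("cerna_aggregated.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$cerna <- list(
    modules = sel_modules,
    edges_per_module = vapply(networks, function(nw) nrow(nw$edges), integer(1)),
    n_edges = nrow(network$edges),
    n_nodes = nrow(network$nodes),
    n_seed_in_network = sum(network$nodes$is_known_disease_gene)
  )
  if (nrow(network$edges) == 0) stop("cerna stage: aggregated network is empty")

  ## -- two-layer multiplex random walk --------------------------------------
  nodes <- network$nodes$gene
  layer1 <- edges_to_adjacency(network$edges[, c("lncrna", "mrna")], nodes)
  layer2 <- edges_to_adjacency(dataset$layer2_edges, nodes)
  n_l1 <- sum(layer1[upper.tri(layer1)] > 0)
  n_l2 <- sum(layer2[upper.tri(layer2)] > 0)
  if (n_l2 == 0) stop("rwrm stage: no functional edge among network nodes")
  tau <- layer_weights(n_l1 / n_l2)
  graph <- multiplex_graph(list(cerna = layer1, functional = layer2))
  seeds <- intersect(dataset$seed_genes, nodes)
  rwr <- rwrm_scores(graph, seeds, delta = config$delta, r = config$r,
                     tau = tau, tolerance = config$rwr_tolerance,
                     max_iter = config$rwr_max_iter)
  ranking <- rwr$ranking
  ranking$biotype <- dataset$biotypes[ranking$node]
  ranking$score <- signif(ranking$score, 10)
  ranking[, c("cerna", "functional")] <-
    lapply(ranking[, c("cerna", "functional")], signif, 10)
  utils::write.table(ranking, out("rwrm_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  top_lnc <- prioritize_lncrnas(rwr, dataset$biotypes,
                                top_k = config$top_lncrnas)
  jsonlite::write_json(top_lnc, out("top_lncrnas.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  report$rwrm <- list(
    layer_edges = c(cerna = n_l1, functional = n_l2), tau = tau,
    n_seeds = length(seeds), iterations = rwr$iterations,
    top_lncrnas = top_lnc
  )

  ## -- pathway association for the top lncRNAs ------------------------------
  sets <- lapply(gene_sets, intersect, y = rownames(prep$expr))
  sets <- sets[lengths(sets) >= config$gmt_min_size &
                 lengths(sets) <= config$gmt_max_size]
  rhythm_ord <- c("SR/SR" = 0, "AF/SR" = 1, "AF/AF" = 2)[dataset$phenotypes$rhythm]
  report$pathways <- list()
  for (lnc in top_lnc$node) {
    pa <- pathway_association(prep$expr, sets, rhythm_ord, lnc)
    utils::write.table(pa, out(sprintf("pathways_%s.tsv", lnc)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$pathways[[lnc]] <- utils::head(pa[pa$coefficient > 0, ], 10)
  }

  ## -- random-forest classification per top lncRNA --------------------------
  vst <- vst_transform(filter_low_counts(dataset$train_counts,
                                         config$min_count,
                                         config$max_low_fraction))$expr
  train_sel <- dataset$phenotypes$rhythm %in% c("AF/AF", "SR/SR")
  train_labels <- as.integer(dataset$phenotypes$rhythm[train_sel] == "AF/AF")
  report$classifiers <- list()
  for (lnc in top_lnc$node) {
    feats <- extract_pair_features(network, lnc)
    feats <- intersect(feats, intersect(rownames(vst),
                                        rownames(dataset$test_expression)))
    rep_on <- classify_rhythm(
      vst[feats, train_sel, drop = FALSE], train_labels,
      dataset$test_expression[feats, , drop = FALSE], dataset$test_labels,
      train_batch = dataset$phenotypes$batch[train_sel],
      batch_removal = TRUE, k = config$cv_folds,
      seed = config$rng_seed + 211L, ntree = config$ntree
    )
    rep_off <- classify_rhythm(
      vst[feats, train_sel, drop = FALSE], train_labels,
      dataset$test_expression[feats, , drop = FALSE], dataset$test_labels,
      train_batch = dataset$phenotypes$batch[train_sel],
      batch_removal = FALSE, k = config$cv_folds,
      seed = config$rng_seed + 211L, ntree = config$ntree
    )
    report$classifiers[[lnc]] <- list(
      n_features = length(feats), cv_auc = rep_on$cv_auc,
      fold_auc = rep_on$fold_auc, test_auc = rep_on$test_auc,
      test_auc_batch_retained = rep_off$test_auc
    )
  }
  jsonlite::write_json(
    report$classifiers, out("classifier_report.json"),
    auto_unbox = TRUE, digits = NA
  )

  report$truth_check <- list(hub_lncrna = dataset$truth$hub_lncrna)
  report$dataset <- dataset
  file_report <- report[setdiff(names(report), "dataset")]
  file_report$config$out_dir <- NULL # path-independent, byte-reproducible
  jsonlite::write_json(file_report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", force = TRUE)
  report$wall_time_s <- proc.time()[["elapsed"]] - t0
  invisible(report)
}
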