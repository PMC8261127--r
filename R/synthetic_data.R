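#' Simulation configuration for a synthetic atrial-rhythm expression cohort
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the design of the real study system: a training cohort of
#' 235 left-atrial samples split into three rhythm groups (SR/SR n = 43,
#' AF/SR n = 74, AF/AF n = 118), 5,000 network genes of which 460 are
#' lncRNAs, six planted co-expression modules of which two carry trait
#' effects (one for AF susceptibility, one for AF persistence), a
#' miRNA-target database with planted high-overlap ceRNA pairs plus sparse
#' background coverage, a known-disease-gene seed list wired to one hub
#' lncRNA, and a smaller continuous-valued (microarray-like) test cohort of
#' 38 samples (32 AF, 6 SR) with a strong per-gene batch shift.
#'
#' @param n_samples_per_group named integer vector of training-group sizes;
#'   names must be `SR/SR`, `AF/SR`, `AF/AF`.
#' @param n_genes total number of genes.
#' @param n_lncrna number of genes labelled `lncRNA`; the rest are `mRNA`.
#' @param n_modules number of planted co-expression modules.
#' @param module_size genes per planted module (remaining genes are
#'   unstructured background noise).
#' @param module_base_cor target within-module Pearson correlation on the
#'   latent (noise-free) scale, in (0, 1).
#' @param trait_module_effects named list keyed by module index; each element
#'   is `list(contrast =, effect =)` where contrast is `"susceptibility"`
#'   (latent factor shifted in all AF-history samples, i.e. AF/SR and AF/AF)
#'   or `"persistence"` (shifted in AF/AF only) and effect is the mean shift
#'   of the module's latent factor in units of its standard deviation.
#' @param signal_scale log2-expression units per unit of latent signal.
#' @param base_log_expr range (log2 scale) of gene baseline expression.
#' @param dispersion two numbers `c(d0, d1)`; negative-binomial dispersion of
#'   a gene with baseline mean mu is `d0 + d1/mu` (a 1/mean trend, so counts
#'   are overdispersed most strongly at low expression).
#' @param sex_effect log2-scale magnitude of the additive sex effect,
#'   affecting a random 30% of genes.
#' @param batch_effect standard deviation of the per-gene batch
#'   coefficients (log2 scale, all genes affected); the batch contrast is a
#'   dominant direction of unwanted variation, as surrogate-variable
#'   analysis assumes.
#' @param quality_effect standard deviation of the per-gene loadings on a
#'   continuous per-sample technical factor (library quality / depth
#'   residual); the second dominant unwanted direction.
#' @param depth_sd standard deviation of log-normal per-sample depth factors.
#' @param n_mirnas size of the miRNA universe.
#' @param planted_cerna_pairs optional data.frame with columns `lncrna`,
#'   `mrna`, `shared` overriding the default planting scheme. `NULL` (the
#'   default) plants `n_planted_per_module` pairs inside each trait module,
#'   including hub-to-seed pairs (see Details).
#' @param n_planted_per_module planted ceRNA pairs per trait module.
#' @param planted_shared shared-miRNA count of every planted pair.
#' @param planted_lnc_targets,planted_mrna_targets target-set sizes of
#'   planted lncRNAs and mRNAs.
#' @param decoy_lnc_targets,decoy_mrna_targets target-set sizes of decoy
#'   (background-coverage) genes.
#' @param decoy_coverage named vector `c(lncRNA =, mRNA =)`; number of decoy
#'   genes of each biotype given random target sets in every module.
#' @param n_seed_genes number of known-disease seed genes (mRNAs planted in
#'   the trait modules, half in each).
#' @param n_test_per_group named integer vector `c(SR =, AF =)` of test-set
#'   sizes.
#' @param batch_shift named vector `c(location =, scale =)`: per-gene batch
#'   perturbation of the test cohort; each gene g gets
#'   `a_g + b_g * x` with `a_g ~ N(0, location^2)` and
#'   `b_g = exp(N(0, scale^2))`.
#' @param batch_confound magnitude of a platform shift aligned against the
#'   trait signal: every test sample's expression of a trait-module gene is
#'   shifted by `-batch_confound` times the gene's expected AF-vs-SR log2
#'   difference. This is the designed stress that makes batch retention
#'   degrade held-out discrimination; 0 disables it.
#' @param test_noise_sd residual noise (log2 scale) of the continuous test
#'   expression values.
#' @param n_layer2_background number of random functional (layer-2) edges
#'   drawn among the miRNA-covered module genes, in addition to the planted
#'   hub-to-seed edges.
#' @param rng_seed integer seed; identical configurations with the same seed
#'   reproduce the dataset bit for bit.
#'
#' @details The default planting scheme designates one hub lncRNA in the
#' susceptibility module. The hub forms high-overlap ceRNA pairs with all
#' seed genes of its own module and functional (layer-2) edges with all seed
#' genes of the persistence module, so that it is connected to every seed
#' gene across the two layers and should be recovered as the top-ranked
#' lncRNA by the multiplex random walk. Planted lncRNA target sets within a
#' module are mutually disjoint and planted mRNA filler miRNAs avoid all
#' planted lncRNA targets of the module, so each planted pair shares exactly
#' `planted_shared` miRNAs and cross pairs among planted genes share none.
#'
#' @return an object of class `simulation_config` (a validated list).
#' @seealso [generate_dataset()]
#' @export
simulation_config <- function(n_samples_per_group = c("SR/SR" = 43, "AF/SR" = 74, "AF/AF" = 118),
                              n_genes = 5000L,
                              n_lncrna = 460L,
                              n_modules = 6L,
                              module_size = 300L,
                              module_base_cor = 0.6,
                              trait_module_effects = list(
                                "1" = list(contrast = "susceptibility", effect = 2.5),
                                "2" = list(contrast = "persistence", effect = 2.5)
                              ),
                              signal_scale = 2,
                              base_log_expr = c(3, 8),
                              dispersion = c(0.1, 2),
                              sex_effect = 0.2,
                              batch_effect = 1.0,
                              quality_effect = 0.7,
                              depth_sd = 0.2,
                              n_mirnas = 923L,
                              planted_cerna_pairs = NULL,
                              n_planted_per_module = 30L,
                              planted_shared = 8L,
                              planted_lnc_targets = 10L,
                              planted_mrna_targets = 15L,
                              decoy_lnc_targets = 6L,
                              decoy_mrna_targets = 8L,
                              decoy_coverage = c(lncRNA = 4, mRNA = 20),
                              n_seed_genes = 20L,
                              n_test_per_group = c(SR = 6, AF = 32),
                              batch_shift = c(location = 2, scale = 0.3),
                              batch_confound = 1,
                              test_noise_sd = 0.6,
                              n_layer2_background = 150L,
                              rng_seed = 1L) {
  cfg <- list(
    n_samples_per_group = n_samples_per_group, n_genes = as.integer(n_genes),
    n_lncrna = as.integer(n_lncrna), n_modules = as.integer(n_modules),
    module_size = as.integer(module_size), module_base_cor = module_base_cor,
    trait_module_effects = trait_module_effects, signal_scale = signal_scale,
    base_log_expr = base_log_expr, dispersion = dispersion,
    sex_effect = sex_effect, batch_effect = batch_effect,
    quality_effect = quality_effect, depth_sd = depth_sd,
    n_mirnas = as.integer(n_mirnas), planted_cerna_pairs = planted_cerna_pairs,
    n_planted_per_module = as.integer(n_planted_per_module),
    planted_shared = as.integer(planted_shared),
    planted_lnc_targets = as.integer(planted_lnc_targets),
    planted_mrna_targets = as.integer(planted_mrna_targets),
    decoy_lnc_targets = as.integer(decoy_lnc_targets),
    decoy_mrna_targets = as.integer(decoy_mrna_targets),
    decoy_coverage = decoy_coverage, n_seed_genes = as.integer(n_seed_genes),
    n_test_per_group = n_test_per_group, batch_shift = batch_shift,
    batch_confound = batch_confound, test_noise_sd = test_noise_sd,
    n_layer2_background = as.integer(n_layer2_background),
    rng_seed = as.integer(rng_seed)
  )
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(
    identical(sort(names(cfg$n_samples_per_group)), sort(c("SR/SR", "AF/SR", "AF/AF"))),
    all(cfg$n_samples_per_group > 0),
    cfg$n_genes > 0, cfg$n_lncrna > 0, cfg$n_lncrna < cfg$n_genes,
    cfg$n_modules > 0, cfg$module_size > 0,
    cfg$module_base_cor > 0, cfg$module_base_cor < 1,
    is.finite(cfg$signal_scale), cfg$n_mirnas >= 1,
    cfg$planted_shared <= cfg$planted_lnc_targets,
    cfg$planted_shared <= cfg$planted_mrna_targets,
    all(cfg$n_test_per_group > 0), cfg$n_seed_genes >= 2,
    all(c("location", "scale") %in% names(cfg$batch_shift)),
    length(cfg$rng_seed) == 1
  )
  if (cfg$n_modules * cfg$module_size > cfg$n_genes) {
    stop("module count/size exceeds gene capacity: ",
         cfg$n_modules, " x ", cfg$module_size, " > ", cfg$n_genes)
  }
  for (m in names(cfg$trait_module_effects)) {
    eff <- cfg$trait_module_effects[[m]]
    if (as.integer(m) > cfg$n_modules) {
      stop("trait effect assigned to nonexistent module ", m)
    }
    if (!eff$contrast %in% c("susceptibility", "persistence")) {
      stop("unknown contrast '", eff$contrast, "' for module ", m)
    }
    if (!is.finite(eff$effect)) stop("non-finite effect size for module ", m)
  }
  invisible(cfg)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws every input the pipeline consumes: negative-binomial RNA-seq counts
#' for the three-group training cohort, per-sample phenotypes (rhythm, sex,
#' batch), a miRNA-target database with planted ceRNA pairs, a second-layer
#' functional edge list, a seed gene list, a continuous batch-shifted test
#' cohort, and the `truth` record used by the tests.
#'
#' Per sample, one latent factor is drawn for each module; trait modules
#' shift the factor mean in the configured contrast groups only. A module
#' gene's latent value is `sqrt(rho) * factor + sqrt(1-rho) * noise`, so two
#' genes of a module correlate at `rho = module_base_cor` before counting
#' noise. Latent values are mapped to a log2 mean (baseline + signal scale x
#' latent + nuisance effects), multiplied by a per-sample depth factor, and
#' counts are drawn negative-binomially with a 1/mean dispersion trend.
#'
#' @param config a [simulation_config()].
#' @return an object of class `synthetic_dataset`: a list with elements
#'   `train_counts`, `phenotypes`, `mirna_db` (see [mirna_target_db()]),
#'   `layer2_edges`, `seed_genes`, `test_expression`, `test_labels`,
#'   `biotypes`, `gene_sets` and `truth`.
#' @export
generate_dataset <- function(config) {
  validate_simulation_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$rng_seed)

  ## ---- gene universe and module memberships -------------------------------
  n_lnc <- config$n_lncrna
  n_mrna <- config$n_genes - n_lnc
  lnc_ids <- sprintf("lnc%04d", seq_len(n_lnc))
  mrna_ids <- sprintf("pc%05d", seq_len(n_mrna))
  biotypes <- c(
    stats::setNames(rep("lncRNA", n_lnc), lnc_ids),
    stats::setNames(rep("mRNA", n_mrna), mrna_ids)
  )
  # per-module lncRNA share proportional to the global lncRNA fraction
  lnc_per_mod <- max(1L, round(config$module_size * n_lnc / config$n_genes))
  mrna_per_mod <- config$module_size - lnc_per_mod
  if (lnc_per_mod * config$n_modules > n_lnc ||
      mrna_per_mod * config$n_modules > n_mrna) {
    stop("module count exceeds gene capacity for one biotype")
  }
  modules <- stats::setNames(integer(config$n_genes), c(lnc_ids, mrna_ids))
  for (m in seq_len(config$n_modules)) {
    modules[lnc_ids[seq_len(lnc_per_mod) + (m - 1L) * lnc_per_mod]] <- m
    modules[mrna_ids[seq_len(mrna_per_mod) + (m - 1L) * mrna_per_mod]] <- m
  }
  gene_ids <- names(modules)

  ## ---- training phenotypes ------------------------------------------------
  grp_sizes <- config$n_samples_per_group[c("SR/SR", "AF/SR", "AF/AF")]
  n_train <- sum(grp_sizes)
  rhythm <- factor(rep(names(grp_sizes), grp_sizes),
                   levels = c("SR/SR", "AF/SR", "AF/AF"))
  sample_ids <- sprintf("S%03d", seq_len(n_train))
  sex <- stats::rbinom(n_train, 1, 0.5)
  batch <- rep_len(c("b1", "b2"), n_train)[sample(n_train)]
  phenotypes <- data.frame(
    sample_id = sample_ids, rhythm = as.character(rhythm),
    sex = ifelse(sex == 1, "male", "female"), batch = batch,
    stringsAsFactors = FALSE
  )

  ## ---- latent module factors ----------------------------------------------
  factor_shift <- function(rhythm_chr) {
    shifts <- matrix(0, config$n_modules, length(rhythm_chr))
    for (m in names(config$trait_module_effects)) {
      eff <- config$trait_module_effects[[m]]
      hit <- if (eff$contrast == "susceptibility") {
        rhythm_chr %in% c("AF/SR", "AF/AF") # any AF history
      } else {
        rhythm_chr == "AF/AF" # in AF at surgery
      }
      shifts[as.integer(m), hit] <- eff$effect
    }
    shifts
  }
  # factors are drawn with their group means fixed exactly at the planted
  # values (each group's empirical mean is centred away), so contrast
  # specificity is a property of the construction, not of a lucky draw
  centre_by_group <- function(x, groups) {
    for (g in unique(groups)) {
      cols <- groups == g
      x[, cols] <- x[, cols, drop = FALSE] - rowMeans(x[, cols, drop = FALSE])
    }
    x
  }
  factors <- factor_shift(as.character(rhythm)) + centre_by_group(
    matrix(stats::rnorm(config$n_modules * n_train), config$n_modules, n_train),
    as.character(rhythm)
  )
  rownames(factors) <- paste0("M", seq_len(config$n_modules))
  colnames(factors) <- sample_ids

  ## ---- gene-level latent signal and counts --------------------------------
  rho <- config$module_base_cor
  latent <- matrix(stats::rnorm(config$n_genes * n_train), config$n_genes, n_train,
                   dimnames = list(gene_ids, sample_ids))
  in_mod <- modules > 0
  latent[in_mod, ] <- sqrt(rho) * factors[modules[in_mod], , drop = FALSE] +
    sqrt(1 - rho) * latent[in_mod, , drop = FALSE]

  base_log <- stats::runif(config$n_genes, config$base_log_expr[1], config$base_log_expr[2])
  sex_coef <- ifelse(stats::runif(config$n_genes) < 0.3,
                     sample(c(-1, 1), config$n_genes, TRUE) * config$sex_effect, 0)
  batch_coef <- stats::rnorm(config$n_genes, 0, config$batch_effect)
  quality <- stats::rnorm(n_train)
  quality_coef <- stats::rnorm(config$n_genes, 0, config$quality_effect)
  log_mu <- base_log + config$signal_scale * latent +
    outer(sex_coef, sex) + outer(batch_coef, as.numeric(batch == "b2")) +
    outer(quality_coef, quality)
  depth <- exp(stats::rnorm(n_train, 0, config$depth_sd))
  mu <- 2^log_mu * rep(depth, each = config$n_genes)
  disp <- config$dispersion[1] + config$dispersion[2] / 2^base_log
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = rep(1 / disp, n_train)),
    config$n_genes, n_train, dimnames = list(gene_ids, sample_ids)
  )

  ## ---- miRNA-target database with planted ceRNA structure -----------------
  mirnas <- sprintf("mir%04d", seq_len(config$n_mirnas))
  trait_mods <- as.integer(names(config$trait_module_effects))
  planted <- plant_cerna_structure(config, modules, biotypes, mirnas, trait_mods)
  mirna_db <- mirna_target_db(planted$lnc_pairs, planted$mrna_pairs)

  ## ---- layer-2 functional edges -------------------------------------------
  covered <- unique(c(planted$lnc_pairs$gene_id, planted$mrna_pairs$gene_id))
  hub_edges <- if (length(planted$seed_genes_by_module) >= 2) {
    # functional edges wiring the hub to the other trait module's seeds
    data.frame(
      gene_a = planted$hub, gene_b = planted$seed_genes_by_module[[2]],
      weight = round(stats::runif(length(planted$seed_genes_by_module[[2]]), 0.8, 1), 4),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(gene_a = character(0), gene_b = character(0), weight = numeric(0))
  }
  n_bg <- config$n_layer2_background
  bg_a <- sample(covered, n_bg, replace = TRUE)
  bg_b <- sample(covered, n_bg, replace = TRUE)
  keep <- bg_a != bg_b
  bg_edges <- data.frame(
    gene_a = pmin(bg_a[keep], bg_b[keep]), gene_b = pmax(bg_a[keep], bg_b[keep]),
    weight = round(stats::runif(sum(keep), 0.5, 1), 4), stringsAsFactors = FALSE
  )
  layer2 <- rbind(hub_edges, bg_edges)
  layer2 <- layer2[!duplicated(layer2[, c("gene_a", "gene_b")]), ]

  ## ---- independent test cohort (continuous, batch-shifted) ----------------
  n_test <- sum(config$n_test_per_group[c("SR", "AF")])
  test_labels <- rep(c(0L, 1L), config$n_test_per_group[c("SR", "AF")])
  test_ids <- sprintf("T%03d", seq_len(n_test))
  # AF test samples follow the AF/AF generative settings, SR samples SR/SR
  test_rhythm <- ifelse(test_labels == 1L, "AF/AF", "SR/SR")
  test_factors <- factor_shift(test_rhythm) + centre_by_group(
    matrix(stats::rnorm(config$n_modules * n_test), config$n_modules, n_test),
    test_rhythm
  )
  test_latent <- matrix(stats::rnorm(config$n_genes * n_test), config$n_genes, n_test,
                        dimnames = list(gene_ids, test_ids))
  test_latent[in_mod, ] <- sqrt(rho) * test_factors[modules[in_mod], , drop = FALSE] +
    sqrt(1 - rho) * test_latent[in_mod, , drop = FALSE]
  shift_loc <- stats::rnorm(config$n_genes, 0, config$batch_shift[["location"]])
  shift_scale <- exp(stats::rnorm(config$n_genes, 0, config$batch_shift[["scale"]]))
  # expected AF-vs-SR log2 signal per gene; the batch confound opposes it
  af_diff <- (factor_shift("AF/AF") - factor_shift("SR/SR"))[, 1]
  signal_diff <- config$signal_scale * sqrt(rho) *
    ifelse(in_mod, af_diff[pmax(modules, 1L)], 0)
  test_expr <- base_log + config$signal_scale * test_latent +
    matrix(stats::rnorm(config$n_genes * n_test, 0, config$test_noise_sd),
           config$n_genes, n_test) -
    config$batch_confound * signal_diff
  test_expr <- shift_loc + shift_scale * test_expr
  dimnames(test_expr) <- list(gene_ids, test_ids)

  structure(list(
    train_counts = counts,
    phenotypes = phenotypes,
    biotypes = biotypes,
    mirna_db = mirna_db,
    layer2_edges = layer2,
    seed_genes = planted$seed_genes,
    test_expression = test_expr,
    test_labels = stats::setNames(test_labels, test_ids),
    truth = list(
      modules = modules,
      factors = factors,
      test_factors = structure(test_factors,
                               dimnames = list(rownames(factors), test_ids)),
      trait_modules = lapply(config$trait_module_effects, `[[`, "contrast"),
      planted_pairs = planted$pairs,
      hub_lncrna = planted$hub,
      seed_genes = planted$seed_genes,
      sex = stats::setNames(sex, sample_ids),
      batch = stats::setNames(batch, sample_ids),
      batch_coef = stats::setNames(batch_coef, gene_ids),
      quality = stats::setNames(quality, sample_ids)
    ),
    config = config
  ), class = "synthetic_dataset")
}

# Plant the miRNA-target tables. Planted lncRNA target sets within a module
# are disjoint, and planted mRNA filler miRNAs avoid every planted lncRNA
# target of the module, so each planted pair shares exactly `planted_shared`
# miRNAs and planted cross pairs share none. Decoy genes draw independent
# random sets from the full universe, giving background-level overlap.
plant_cerna_structure <- function(config, modules, biotypes, mirnas, trait_mods) {
  lnc_pairs <- list()
  mrna_pairs <- list()
  pairs <- list()
  seed_by_mod <- list()
  hub <- NA_character_

  add_targets <- function(store, gene, set) {
    store[[gene]] <- data.frame(gene_id = gene, mirna_id = set,
                                stringsAsFactors = FALSE)
    store
  }

  if (!is.null(config$planted_cerna_pairs)) {
    pp <- config$planted_cerna_pairs
    stopifnot(all(c("lncrna", "mrna", "shared") %in% names(pp)))
    unknown <- setdiff(c(pp$lncrna, pp$mrna), names(modules))
    if (length(unknown)) {
      stop("planted pairs reference unknown genes: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    for (i in seq_len(nrow(pp))) {
      lnc <- pp$lncrna[i]; mr <- pp$mrna[i]; t <- pp$shared[i]
      if (is.null(lnc_pairs[[lnc]])) {
        lnc_pairs <- add_targets(lnc_pairs, lnc,
                                 sample(mirnas, config$planted_lnc_targets))
      }
      own <- lnc_pairs[[lnc]]$mirna_id
      shared <- sample(own, t)
      filler <- sample(setdiff(mirnas, own), config$planted_mrna_targets - t)
      mrna_pairs <- add_targets(mrna_pairs, mr, c(shared, filler))
      pairs[[i]] <- data.frame(lncrna = lnc, mrna = mr, shared = t,
                               module = modules[[lnc]], stringsAsFactors = FALSE)
    }
    hub <- pp$lncrna[1]
    seed_genes <- character(0)
  } else {
    n_half_seed <- config$n_seed_genes %/% 2L
    for (k in seq_along(trait_mods)) {
      m <- trait_mods[k]
      mod_lnc <- names(modules)[modules == m & biotypes == "lncRNA"]
      mod_mrna <- names(modules)[modules == m & biotypes == "mRNA"]
      n_seed_m <- if (k <= 2) n_half_seed else 0L
      # planted lncRNAs for this module: the hub (module 1 of the trait list)
      # plus enough others to carry the planted pairs
      n_other_pairs <- config$n_planted_per_module - n_seed_m
      n_lnc_planted <- max(1L, ceiling(n_other_pairs / 4))
      planted_lnc <- mod_lnc[seq_len(min(length(mod_lnc), 1L + n_lnc_planted))]
      if (k == 1) hub <- planted_lnc[1]
      # disjoint target sets for the module's planted lncRNAs
      pool <- mirnas
      hub_extra <- if (k == 1) 2L else 0L
      for (ln in planted_lnc) {
        sz <- config$planted_lnc_targets + if (ln == hub) hub_extra else 0L
        set <- sample(pool, sz)
        pool <- setdiff(pool, set)
        lnc_pairs <- add_targets(lnc_pairs, ln, set)
      }
      taken <- setdiff(mirnas, pool) # all planted lncRNA targets in module
      seeds_m <- mod_mrna[seq_len(n_seed_m)]
      seed_by_mod[[k]] <- seeds_m
      other_mrna <- setdiff(mod_mrna, seeds_m)[seq_len(n_other_pairs)]
      if (anyNA(c(seeds_m, other_mrna))) {
        stop("module ", m, " too small for the requested planted ceRNA pairs")
      }
      # hub (or first lncRNA) pairs with every seed mRNA of the module;
      # remaining planted mRNAs are spread over the other planted lncRNAs
      pair_lnc <- c(
        rep(planted_lnc[1], n_seed_m),
        rep_len(planted_lnc[-1], length(other_mrna))
      )
      pair_mrna <- c(seeds_m, other_mrna)
      for (i in seq_along(pair_mrna)) {
        lnc <- pair_lnc[i]
        own <- lnc_pairs[[lnc]]$mirna_id
        shared <- sample(own, config$planted_shared)
        filler <- sample(setdiff(mirnas, taken),
                         config$planted_mrna_targets - config$planted_shared)
        mrna_pairs <- add_targets(mrna_pairs, pair_mrna[i], c(shared, filler))
        pairs[[length(pairs) + 1L]] <- data.frame(
          lncrna = lnc, mrna = pair_mrna[i], shared = config$planted_shared,
          module = m, stringsAsFactors = FALSE
        )
      }
    }
    seed_genes <- unlist(seed_by_mod, use.names = FALSE)
    # decoy coverage: sparse random target sets in every module
    for (m in seq_len(config$n_modules)) {
      mod_lnc <- names(modules)[modules == m & biotypes == "lncRNA"]
      mod_mrna <- names(modules)[modules == m & biotypes == "mRNA"]
      free_lnc <- setdiff(mod_lnc, names(lnc_pairs))
      free_mrna <- setdiff(mod_mrna, names(mrna_pairs))
      for (ln in utils::head(free_lnc, config$decoy_coverage[["lncRNA"]])) {
        lnc_pairs <- add_targets(lnc_pairs, ln, sample(mirnas, config$decoy_lnc_targets))
      }
      for (mr in utils::head(free_mrna, config$decoy_coverage[["mRNA"]])) {
        mrna_pairs <- add_targets(mrna_pairs, mr, sample(mirnas, config$decoy_mrna_targets))
      }
    }
  }

  list(
    lnc_pairs = do.call(rbind, c(lnc_pairs, list(make.row.names = FALSE))),
    mrna_pairs = do.call(rbind, c(mrna_pairs, list(make.row.names = FALSE))),
    pairs = do.call(rbind, c(pairs, list(make.row.names = FALSE))),
    hub = hub,
    seed_genes = if (exists("seed_genes")) seed_genes else character(0),
    seed_genes_by_module = seed_by_mod
  )
}

#' Generate synthetic gene sets (GMT-style) aligned with the cohort
#'
#' Builds a small gene-set collection over the dataset's gene universe for
#' the pathway-association stage: a few sets drawn from within planted
#' modules (so that their activity scores track the module factors) and the
#' rest drawn at random.
#'
#' @param dataset a [generate_dataset()] result.
#' @param n_sets total number of sets.
#' @param n_module_sets how many sets are sampled from within planted
#'   modules (cycled over modules).
#' @param size_range inclusive range of set sizes.
#' @param rng_seed seed for the set sampling (independent of the dataset).
#' @return named list of character vectors of gene IDs.
#' @export
generate_gene_sets <- function(dataset, n_sets = 25L, n_module_sets = 6L,
                               size_range = c(15, 60), rng_seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(rng_seed)
  modules <- dataset$truth$modules
  genes <- names(modules)
  sets <- vector("list", n_sets)
  mods <- rep_len(seq_len(max(modules)), n_module_sets)
  for (i in seq_len(n_sets)) {
    sz <- sample(seq(size_range[1], size_range[2]), 1)
    sets[[i]] <- if (i <= n_module_sets) {
      sample(genes[modules == mods[i]], min(sz, sum(modules == mods[i])))
    } else {
      sample(genes, sz)
    }
  }
  names(sets) <- c(
    sprintf("MODULE%d_SET", mods),
    sprintf("RANDOM_SET_%02d", seq_len(n_sets - n_module_sets))
  )
  sets
}

#' Write a synthetic dataset to plain-text pipeline inputs
#'
#' Emits the file formats the pipeline reads: expression TSV (genes as rows,
#' header = sample IDs), phenotype TSV, miRNA-target TSV (gene_id, biotype,
#' mirna_id), layer-2 edge TSV, seed-gene TXT (one symbol per line), test
#' expression TSV and label TSV, and the ground truth as JSON.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "train_counts.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    mirna = file.path(dir, "mirna_targets.tsv"),
    layer2 = file.path(dir, "layer2_edges.tsv"),
    seeds = file.path(dir, "seed_genes.txt"),
    test = file.path(dir, "test_expression.tsv"),
    test_labels = file.path(dir, "test_labels.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_matrix_tsv(dataset$train_counts, paths["counts"])
  utils::write.table(dataset$phenotypes, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  db <- dataset$mirna_db
  tg <- rbind(
    data.frame(gene_id = db$lnc_pairs$gene_id, biotype = "lncRNA",
               mirna_id = db$lnc_pairs$mirna_id, stringsAsFactors = FALSE),
    data.frame(gene_id = db$mrna_pairs$gene_id, biotype = "mRNA",
               mirna_id = db$mrna_pairs$mirna_id, stringsAsFactors = FALSE)
  )
  utils::write.table(tg, paths["mirna"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$layer2_edges, paths["layer2"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(dataset$seed_genes, paths["seeds"])
  write_matrix_tsv(dataset$test_expression, paths["test"])
  utils::write.table(
    data.frame(sample_id = names(dataset$test_labels), label = dataset$test_labels),
    paths["test_labels"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  truth <- dataset$truth
  truth$factors <- NULL # large matrices stay in the R object
  truth$test_factors <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
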