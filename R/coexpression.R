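#' Signed weighted adjacency
#'
#' Maps Pearson correlation to edge weight by `((1 + cor) / 2)^beta`, so
#' perfectly anti-correlated genes receive weight 0, uncorrelated genes
#' `2^-beta`, and perfectly correlated genes 1. Only positive co-expression
#' builds strong edges, which is the point of the signed construction.
#'
#' @param expr gene x sample matrix (>= 3 samples).
#' @param beta positive integer soft-thresholding power.
#' @return symmetric gene x gene adjacency in \[0, 1\] (diagonal 1).
#' @export
signed_adjacency <- function(expr, beta) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3, beta >= 1)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "))
  }
  ((1 + stats::cor(t(expr))) / 2)^beta
}

#' Scale-free topology fit of a connectivity vector
#'
#' Bins `log10(k)` into `n_breaks` equal-width bins (empty bins dropped),
#' regresses log10 bin frequency on log10 mean bin connectivity, and returns
#' the signed fit `-sign(slope) * R^2`: high positive values mean the degree
#' distribution falls off as a power law.
#'
#' @param k positive connectivity values.
#' @param n_breaks number of bins (default 10).
#' @return list with `fit` (signed R^2), `slope` and `r_squared`.
#' @export
scale_free_fit <- function(k, n_breaks = 10) {
  k <- k[k > 0]
  lk <- log10(k)
  if (length(unique(lk)) < 2 || diff(range(lk)) == 0) {
    stop("degenerate connectivity: all values equal, scale-free fit undefined")
  }
  bins <- cut(lk, n_breaks, include.lowest = TRUE)
  freq <- tabulate(bins, nbins = n_breaks)
  mean_k <- tapply(k, bins, mean)
  nonempty <- freq > 0
  if (sum(nonempty) < 2) {
    stop("fewer than two occupied connectivity bins; fit undefined")
  }
  x <- log10(mean_k[nonempty])
  y <- log10(freq[nonempty])
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[["x"]]
  r2 <- summary(fit)$r.squared
  list(fit = -sign(slope) * r2, slope = slope, r_squared = r2)
}

#' Choose the soft threshold achieving scale-free topology
#'
#' For each candidate power, builds the signed adjacency, computes each
#' gene's connectivity (sum of off-diagonal adjacency), and evaluates the
#' scale-free fit. Returns the smallest candidate whose signed fit reaches
#' `fit_threshold` (the "degree of independence"); errors (reporting the
#' best fit achieved) when none qualifies.
#'
#' @param expr gene x sample matrix.
#' @param candidates integer powers to scan (default 1..20).
#' @param fit_threshold required signed R^2 (default 0.9).
#' @param n_breaks bins for [scale_free_fit()].
#' @return the chosen power, with the full scan as attribute `"fit_table"`.
#' @export
pick_beta <- function(expr, candidates = 1:20, fit_threshold = 0.9,
                      n_breaks = 10) {
  stopifnot(length(candidates) >= 1)
  candidates <- sort(unique(as.integer(candidates)))
  base <- (1 + stats::cor(t(expr))) / 2
  diag(base) <- 0 # connectivity excludes the diagonal
  fits <- vapply(candidates, function(b) {
    k <- rowSums(base^b)
    scale_free_fit(k, n_breaks)$fit
  }, numeric(1))
  tab <- data.frame(beta = candidates, fit = fits)
  ok <- which(fits >= fit_threshold)
  if (!length(ok)) {
    stop(sprintf(
      "no candidate power reaches scale-free fit %.3f; best was %.3f at beta = %d",
      fit_threshold, max(fits), candidates[which.max(fits)]
    ))
  }
  structure(candidates[ok[1]], fit_table = tab)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j` with `TOM_ii = 1`, where `k` is off-diagonal connectivity. Two
#' genes overlap strongly when they share neighbours even if their direct
#' edge is modest, which damps spurious single edges.
#'
#' @param adjacency symmetric matrix in \[0, 1\]; the diagonal is ignored.
#' @return symmetric TOM matrix in \[0, 1\].
#' @export
compute_tom <- function(adjacency) {
  stopifnot(is.matrix(adjacency))
  if (max(abs(adjacency - t(adjacency))) > 1e-12) {
    stop("adjacency must be symmetric")
  }
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect modules by hierarchical clustering of topological overlap
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a static height; clusters smaller than `min_module_size` are
#' assigned the unassigned label 0 and surviving modules are relabelled
#' 1, 2, ... by decreasing size. When `cut_height` is `NULL` the cut is
#' placed at 0.99 of the maximum merge height: the loosest merges join the
#' unstructured background and the well-separated module subtrees, so a cut
#' just below the dendrogram top isolates the tight modules while the
#' background falls apart into sub-threshold fragments.
#'
#' @param tom topological overlap matrix.
#' @param min_module_size smallest cluster kept as a module (default 30).
#' @param deep_split accepted for interface compatibility with dynamic tree
#'   cutting and recorded, but not used by the static cut.
#' @param cut_height static cut height in \[0, 1\], or `NULL` for the
#'   largest-gap heuristic.
#' @return list with `labels` (named integer vector, 0 = unassigned),
#'   `tree` (the hclust object), `cut_height` used and `deep_split`.
#' @export
cluster_modules <- function(tom, min_module_size = 30, deep_split = 2,
                            cut_height = NULL) {
  stopifnot(is.matrix(tom))
  genes <- rownames(tom)
  n <- nrow(tom)
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    return(list(labels = stats::setNames(integer(n), genes), tree = NULL,
                cut_height = NA_real_, deep_split = deep_split))
  }
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  # average linkage on tied dissimilarities can leave merge heights
  # non-monotone by rounding error, which cutree rejects; repair minimally
  if (is.unsorted(tree$height)) {
    if (max(tree$height - cummax(tree$height)) > 1e-8) {
      stop("merge heights decrease by more than rounding error")
    }
    tree$height <- cummax(tree$height)
  }
  if (is.null(cut_height)) {
    cut_height <- 0.99 * max(tree$height)
  }
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- stats::setNames(integer(n), genes)
  if (length(keep)) {
    kept_sizes <- sizes[as.character(keep)]
    new_id <- stats::setNames(seq_along(keep),
                              keep[order(-kept_sizes, keep)])
    hit <- raw %in% keep
    labels[hit] <- new_id[as.character(raw[hit])]
  } else {
    warning("no cluster reached min_module_size; all genes unassigned")
  }
  list(labels = labels, tree = tree, cut_height = cut_height,
       deep_split = deep_split)
}

#' Module eigengene
#'
#' First principal component of the module's standardized expression: genes
#' are centred and scaled across samples and the eigengene is the first
#' right-singular vector of the member submatrix, sign-aligned so that it
#' correlates nonnegatively with the mean standardized member profile, and
#' unit-norm.
#'
#' @param expr gene x sample matrix.
#' @param member_genes character vector of module members (rownames of
#'   `expr`).
#' @return named per-sample numeric vector with attribute `var_explained`.
#' @export
module_eigengene <- function(expr, member_genes) {
  stopifnot(length(member_genes) >= 1, all(member_genes %in% rownames(expr)))
  x <- expr[member_genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) stop("zero-variance member gene in module")
  xs <- (x - rowMeans(x)) / sds
  sv <- svd(xs)
  me <- sv$v[, 1]
  mean_profile <- colMeans(xs)
  if (sum(me * mean_profile) < 0) me <- -me
  structure(stats::setNames(me, colnames(expr)),
            var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigengenes for every module in an assignment
#'
#' @param expr gene x sample matrix.
#' @param labels named integer module labels (0 = unassigned, skipped).
#' @return sample x module matrix with columns `ME<id>`.
#' @export
module_eigengenes <- function(expr, labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no assigned module")
  mes <- vapply(mods, function(m) {
    module_eigengene(expr, names(labels)[labels == m])
  }, numeric(ncol(expr)))
  dimnames(mes) <- list(colnames(expr), paste0("ME", mods))
  mes
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest module pair whose eigengene dissimilarity
#' `1 - cor(ME_a, ME_b)` falls below `cut_height`, recomputing eigengenes
#' after each merge, until no pair qualifies. The merged pair keeps the
#' lower module id.
#'
#' @param labels named integer module labels (0 = unassigned).
#' @param expr gene x sample matrix.
#' @param cut_height eigengene dissimilarity threshold (default 0.25).
#' @return list with `labels` (relabelled 1..K by decreasing size) and
#'   `merge_history` (data.frame from, into, dissimilarity).
#' @export
merge_modules <- function(labels, expr, cut_height = 0.25) {
  stopifnot(any(labels > 0))
  history <- data.frame(from = integer(0), into = integer(0),
                        dissimilarity = numeric(0))
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    mes <- module_eigengenes(expr, labels)
    d <- 1 - stats::cor(mes)
    diag(d) <- Inf
    i <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[i[1], i[2]] >= cut_height) break
    pair <- sort(mods[c(i[1], i[2])])
    labels[labels == pair[2]] <- pair[1]
    history <- rbind(history, data.frame(
      from = pair[2], into = pair[1], dissimilarity = d[i[1], i[2]]
    ))
  }
  # relabel by decreasing size, keeping 0 for unassigned
  mods <- sort(unique(labels[labels > 0]))
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  remap <- stats::setNames(seq_along(mods), mods[order(-sizes, mods)])
  out <- labels
  out[labels > 0] <- remap[as.character(labels[labels > 0])]
  list(labels = out, merge_history = history)
}

#' Correlate module eigengenes with an atrial-rhythm trait contrast
#'
#' The susceptibility contrast compares AF/SR (coded 1) with SR/SR (coded
#' 0); the persistence contrast compares AF/AF (coded 1) with AF/SR (coded
#' 0). Pearson correlation of each eigengene with the binary code is tested
#' two-sidedly via `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param eigengenes sample x module matrix (from [module_eigengenes()]).
#' @param phenotypes data.frame with `sample_id` and `rhythm`, rows aligned
#'   with the eigengene rows.
#' @param contrast `"susceptibility"` or `"persistence"`.
#' @return data.frame (module, contrast, r, p, n) sorted by p.
#' @export
module_trait_correlation <- function(eigengenes, phenotypes,
                                     contrast = c("susceptibility", "persistence")) {
  contrast <- match.arg(contrast)
  stopifnot(identical(rownames(eigengenes), phenotypes$sample_id))
  codes <- if (contrast == "susceptibility") {
    c("SR/SR" = 0, "AF/SR" = 1)
  } else {
    c("AF/SR" = 0, "AF/AF" = 1)
  }
  sel <- phenotypes$rhythm %in% names(codes)
  y <- codes[phenotypes$rhythm[sel]]
  if (length(unique(y)) < 2) stop("trait constant in the ", contrast, " subset")
  n <- length(y)
  r <- as.numeric(stats::cor(eigengenes[sel, , drop = FALSE], y))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- data.frame(
    module = as.integer(sub("^ME", "", colnames(eigengenes))),
    contrast = contrast, r = r, p = p, n = n, stringsAsFactors = FALSE
  )
  out[order(out$p), ]
}
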