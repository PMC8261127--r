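#' Load gene sets from a GMT file
#'
#' Each line holds a set name, a description and the member genes,
#' tab-separated. Sets are optionally intersected with an expression gene
#' universe first and then filtered to sizes within `[min_size, max_size]`
#' (both bounds inclusive).
#'
#' @param path GMT file path.
#' @param min_size,max_size inclusive set-size bounds (defaults 10 and 500).
#' @param universe optional character vector; sets are intersected with it
#'   before size filtering.
#' @return named list of character vectors with attribute `descriptions`.
#' @export
load_gmt <- function(path, min_size = 10, max_size = 500, universe = NULL) {
  lines <- readLines(path)
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": expected name, description and genes")
    }
    nms[i] <- fields[1]
    desc[i] <- fields[2]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(nms)) stop("duplicate set names in GMT file")
  names(sets) <- nms
  names(desc) <- nms
  if (!is.null(universe)) sets <- lapply(sets, intersect, y = universe)
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  structure(sets[keep], descriptions = desc[keep])
}

#' Single-sample gene-set activity score
#'
#' Standardizes each gene across samples (z-score) and returns, per sample,
#' the mean z of the set genes: a transparent single-sample enrichment
#' score whose sign tracks coordinated up- or down-regulation of the set.
#' Zero-variance genes are skipped with a warning.
#'
#' @param expr gene x sample matrix.
#' @param gene_set character vector of gene IDs (at least one must be in
#'   `expr`).
#' @return named per-sample numeric vector.
#' @export
sample_set_score <- function(expr, gene_set) {
  genes <- intersect(gene_set, rownames(expr))
  if (!length(genes)) stop("no set gene present in the expression matrix")
  x <- expr[genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) skipped in set scoring")
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (!nrow(x)) stop("all set genes have zero variance")
  }
  z <- (x - rowMeans(x)) / sds
  colMeans(z)
}

#' Association of a pathway score with lncRNA expression, adjusting for
#' rhythm
#'
#' Ordinary least squares of the per-sample set score on an intercept, the
#' atrial-rhythm covariate and the lncRNA expression; returns the lncRNA
#' coefficient and its two-sided t-test p-value. Rhythm may enter as a
#' single ordinal covariate (SR/SR = 0, AF/SR = 1, AF/AF = 2) or dummy
#' coded, which is the caller's choice of `rhythm` encoding (numeric vector
#' or factor).
#'
#' @param score per-sample numeric response.
#' @param rhythm numeric vector (ordinal coding) or factor (dummy coding).
#' @param lnc_expr per-sample lncRNA expression.
#' @return list with `coefficient`, `p`, `n`.
#' @export
lncrna_pathway_lm <- function(score, rhythm, lnc_expr) {
  stopifnot(length(score) == length(lnc_expr),
            length(score) == length(rhythm))
  fit <- stats::lm(score ~ rhythm + lnc_expr)
  if (anyNA(stats::coef(fit))) {
    stop("collinear design: rhythm and lncRNA expression are aliased")
  }
  s <- summary(fit)$coefficients
  list(coefficient = s["lnc_expr", "Estimate"],
       p = s["lnc_expr", "Pr(>|t|)"],
       n = length(score))
}

#' Pathway association screen for one lncRNA
#'
#' Scores every gene set with [sample_set_score()] and fits
#' [lncrna_pathway_lm()] per set.
#'
#' @param expr gene x sample matrix.
#' @param gene_sets named list of gene sets.
#' @param rhythm rhythm covariate (see [lncrna_pathway_lm()]).
#' @param lncrna lncRNA gene ID (row of `expr`).
#' @return data.frame (set, coefficient, p, n) sorted by coefficient,
#'   descending.
#' @export
pathway_association <- function(expr, gene_sets, rhythm, lncrna) {
  stopifnot(lncrna %in% rownames(expr))
  lnc <- expr[lncrna, ]
  res <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    set <- setdiff(gene_sets[[nm]], lncrna)
    sc <- sample_set_score(expr, set)
    fit <- lncrna_pathway_lm(sc, rhythm, lnc)
    data.frame(set = nm, coefficient = fit$coefficient, p = fit$p, n = fit$n,
               stringsAsFactors = FALSE)
  }))
  res[order(-res$coefficient), ]
}
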