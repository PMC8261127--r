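#' Filter genes expressed too rarely
#'
#' Removes a gene when its count falls below `min_count` in more than
#' `max_low_fraction` of samples. The boundary is strict: a gene low in
#' exactly 80% of samples is retained under the defaults.
#'
#' @param counts nonnegative integer gene x sample matrix.
#' @param min_count counts below this value are considered "low".
#' @param max_low_fraction maximum tolerated fraction of low samples.
#' @return the retained rows of `counts`.
#' @export
filter_low_counts <- function(counts, min_count = 10, max_low_fraction = 0.8) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  low_frac <- rowMeans(counts < min_count)
  keep <- low_frac <= max_low_fraction
  if (!any(keep)) stop("all genes filtered out; thresholds too aggressive")
  counts[keep, , drop = FALSE]
}

#' Variance-stabilizing transform via median-of-ratios normalization
#'
#' Per-sample size factors are computed by the median-of-ratios rule
#' (median over genes of count / geometric-mean count, using genes with all
#' counts positive) and the transform is `log2(count / size_factor + 1)`.
#' The map is monotone in counts within a sample and two samples that are
#' exact scalar multiples of each other transform to identical columns.
#'
#' @param counts filtered count matrix.
#' @return list with `expr` (transformed matrix) and `size_factors`.
#' @export
vst_transform <- function(counts) {
  stopifnot(is.matrix(counts))
  if (any(colSums(counts) == 0)) stop("all-zero sample in count matrix")
  positive <- rowSums(counts == 0) == 0
  if (!any(positive)) stop("no gene with all-positive counts; cannot form size factors")
  logc <- log(counts[positive, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- exp(apply(logc - loggeo, 2, stats::median))
  expr <- log2(sweep(counts, 2, sf, "/") + 1)
  list(expr = expr, size_factors = sf)
}

#' Estimate surrogate variables by residual principal components
#'
#' Regresses every gene on the protected design (the phenotype of interest)
#' plus the adjustment design (known covariates) and takes the top principal
#' components of the residual matrix as surrogate variables: sample-level
#' directions of systematic variation not explained by the modelled
#' covariates (batch, depth, hidden structure).
#'
#' @param expr gene x sample numeric matrix.
#' @param protected sample x p design matrix of protected covariates
#'   (e.g. rhythm coding); may be NULL.
#' @param adjustment sample x q design matrix of known adjustment covariates
#'   (e.g. sex); may be NULL.
#' @param n_sv number of surrogate variables to return.
#' @return sample x `n_sv` matrix (0 columns when `n_sv = 0`).
#' @export
estimate_svs <- function(expr, protected = NULL, adjustment = NULL, n_sv = 2) {
  stopifnot(is.matrix(expr), n_sv >= 0)
  n <- ncol(expr)
  if (n_sv >= n) stop("n_sv must be smaller than the sample count")
  if (n_sv == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(colnames(expr), NULL)))
  }
  design <- cbind(`(Intercept)` = rep(1, n), protected, adjustment)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) stop("rank-deficient design in SV estimation")
  resid <- t(qr.resid(qrd, t(expr)))
  if (sum(resid^2) < 1e-12 * max(1, sum(expr^2))) {
    stop("residual matrix is numerically zero; surrogate variables undefined")
  }
  sv <- svd(resid, nu = 0, nv = n_sv)$v
  dimnames(sv) <- list(colnames(expr), paste0("SV", seq_len(n_sv)))
  sv
}

#' Remove unwanted covariates while protecting the trait design
#'
#' Fits, per gene, ordinary least squares on the combined design
#' `[intercept | keep | remove]` and subtracts only the fitted contribution
#' of the `remove` columns, so trait-linked variation captured by `keep`
#' survives while the removed component is orthogonal to the `remove`
#' columns (after accounting for `keep`). Applying the operation twice with
#' the same designs is a no-op.
#'
#' @param expr gene x sample matrix.
#' @param keep sample x p design of protected covariates (may be NULL).
#' @param remove sample x q design of covariates to regress out (may be
#'   NULL, in which case `expr` is returned unchanged).
#' @return cleaned gene x sample matrix.
#' @export
residualize <- function(expr, keep = NULL, remove = NULL) {
  stopifnot(is.matrix(expr))
  if (is.null(remove) || ncol(as.matrix(remove)) == 0) return(expr)
  keep <- if (is.null(keep)) NULL else as.matrix(keep)
  remove <- as.matrix(remove)
  design <- cbind(`(Intercept)` = rep(1, ncol(expr)), keep, remove)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) stop("rank-deficient combined design")
  beta <- qr.coef(qrd, t(expr)) # p x genes
  rm_idx <- seq.int(ncol(design) - ncol(remove) + 1L, ncol(design))
  cleaned <- expr - t(remove %*% beta[rm_idx, , drop = FALSE])
  dimnames(cleaned) <- dimnames(expr)
  cleaned
}

#' Select the most variable genes
#'
#' Ranks genes by sample variance (ties broken by gene ID, lexicographically,
#' for determinism) and keeps the top `k`.
#'
#' @param expr gene x sample matrix with rownames.
#' @param k number of genes to keep (default 5000).
#' @return the selected rows of `expr`.
#' @export
select_top_variance <- function(expr, k = 5000) {
  stopifnot(is.matrix(expr), k >= 2)
  if (k > nrow(expr)) {
    warning("k exceeds the number of genes; returning all ", nrow(expr), " genes")
    k <- nrow(expr)
  }
  v <- apply(expr, 1, stats::var)
  ord <- order(-v, rownames(expr))
  expr[sort(ord[seq_len(k)]), , drop = FALSE]
}

#' Full expression preprocessing: filter, transform, adjust, select
#'
#' Applies the stages in their fixed order: low-count filter, variance
#' stabilization, surrogate-variable estimation (protecting the rhythm
#' design, adjusting for sex), residualization of sex + SVs, and top-variance
#' gene selection.
#'
#' @param counts raw gene x sample counts.
#' @param phenotypes data.frame with columns `sample_id`, `rhythm`
#'   (`SR/SR`/`AF/SR`/`AF/AF`) and `sex`, rows aligned with `colnames(counts)`.
#' @param min_count,max_low_fraction see [filter_low_counts()].
#' @param n_sv number of surrogate variables (default 2).
#' @param top_k number of high-variance genes to keep (default 5000).
#' @return list with `expr` (cleaned, selected matrix), `svs`,
#'   `size_factors` and `n_filtered`.
#' @export
preprocess_expression <- function(counts, phenotypes, min_count = 10,
                                  max_low_fraction = 0.8, n_sv = 2,
                                  top_k = 5000) {
  stopifnot(identical(colnames(counts), phenotypes$sample_id))
  if (anyDuplicated(rownames(counts))) stop("duplicate gene IDs in count matrix")
  filtered <- filter_low_counts(counts, min_count, max_low_fraction)
  vst <- vst_transform(filtered)
  rhythm <- factor(phenotypes$rhythm, levels = c("SR/SR", "AF/SR", "AF/AF"))
  protected <- stats::model.matrix(~rhythm)[, -1, drop = FALSE]
  sex <- stats::model.matrix(~ factor(phenotypes$sex))[, -1, drop = FALSE]
  colnames(sex) <- "sex"
  svs <- estimate_svs(vst$expr, protected, sex, n_sv = n_sv)
  cleaned <- residualize(vst$expr, keep = protected, remove = cbind(sex, svs))
  list(
    expr = select_top_variance(cleaned, k = top_k),
    svs = svs,
    size_factors = vst$size_factors,
    n_filtered = nrow(counts) - nrow(filtered)
  )
}
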