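#' Read and write the pipeline's tab-separated tables
#'
#' All matrices travel as TSV with genes as rows, a `gene_id` first column
#' and sample IDs in the header; all tables are tab-separated with a header
#' row.
#'
#' @param mat numeric matrix with row and column names.
#' @param path file path.
#' @return `write_matrix_tsv` invisibly returns `path`; `read_matrix_tsv`
#'   returns a numeric matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Read a miRNA-target table into a target database
#'
#' The table must have columns `gene_id`, `biotype` (`lncRNA`/`mRNA`) and
#' `mirna_id`, one row per target pair.
#'
#' @param path TSV path.
#' @return a [mirna_target_db()].
#' @export
read_mirna_targets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "biotype", "mirna_id") %in% names(df)))
  mirna_target_db(
    lnc_pairs = df[df$biotype == "lncRNA", c("gene_id", "mirna_id")],
    mrna_pairs = df[df$biotype == "mRNA", c("gene_id", "mirna_id")]
  )
}

#' Read a seed-gene list (one gene symbol per line)
#'
#' @param path text file path.
#' @return character vector of gene IDs.
#' @export
read_seed_genes <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write gene sets in GMT format
#'
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to the set names).
#' @return invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path, descriptions = names(gene_sets)) {
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(gene_sets), descriptions, gene_sets)
  writeLines(lines, path)
  invisible(path)
}
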