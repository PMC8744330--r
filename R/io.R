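#' Read and write GMT gene-set files
#'
#' GMT is one gene set per line: name, description, then member symbols, all
#' tab-separated.
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @param descriptions Optional character vector (recycled) for column 2.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' Read and write gene x sample count matrices as TSV
#'
#' Genes in rows (first column `gene`), samples in columns.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path File path.
#' @return `read_counts_tsv` returns a numeric matrix.
#' @export
write_counts_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read and write sparse counts as MatrixMarket MTX with sidecar TSVs
#'
#' Writes `<stem>.mtx`, `<stem>.genes.tsv`, `<stem>.barcodes.tsv`.
#'
#' @param mat Gene x cell matrix (dense or `Matrix` sparse).
#' @param stem Path stem (no extension).
#' @return `read_counts_mtx` returns a dense matrix with dimnames.
#' @export
write_counts_mtx <- function(mat, stem) {
  sp <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sp, paste0(stem, ".mtx"))
  writeLines(rownames(mat), paste0(stem, ".genes.tsv"))
  writeLines(colnames(mat), paste0(stem, ".barcodes.tsv"))
  invisible(stem)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(stem) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  rownames(m) <- readLines(paste0(stem, ".genes.tsv"))
  colnames(m) <- readLines(paste0(stem, ".barcodes.tsv"))
  m
}

#' Read and write a two-column ligand-receptor table as TSV
#'
#' @param lr Tibble/data.frame with columns `ligand`, `receptor`.
#' @param path File path.
#' @return `read_lr_tsv` returns a tibble.
#' @export
write_lr_tsv <- function(lr, path) {
  write.table(lr[, c("ligand", "receptor")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_lr_tsv
#' @export
read_lr_tsv <- function(path) {
  tibble::as_tibble(read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE))
}
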