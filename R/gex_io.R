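## Expression-matrix IO. Counts live in a Matrix::dgCMatrix, genes in rows
## and cell barcodes in columns, matching the cellranger MTX triplet.

#' Read a cellranger-style MTX triplet
#'
#' Reads `matrix.mtx`, `features.tsv` (or `genes.tsv`; first column gene id,
#' second, if present, gene symbol — the symbol is used as row name) and
#' `barcodes.tsv` from a directory.
#'
#' @param dir Directory containing the three files.
#' @return A sparse genes x cells count matrix (`dgCMatrix`).
#' @export
read_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  feat <- file.path(dir, c("features.tsv", "genes.tsv"))
  feat <- feat[file.exists(feat)][1]
  bc <- file.path(dir, "barcodes.tsv")
  if (!file.exists(mtx) || is.na(feat) || !file.exists(bc)) {
    stop("expected matrix.mtx, features.tsv/genes.tsv and barcodes.tsv in ", dir)
  }
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- read.delim(feat, header = FALSE, stringsAsFactors = FALSE)
  symbols <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  barcodes <- readLines(bc)
  if (nrow(m) != length(symbols) || ncol(m) != length(barcodes)) {
    stop("matrix dimensions do not match features/barcodes")
  }
  dimnames(m) <- list(symbols, barcodes)
  m
}

#' Write counts as an MTX triplet
#'
#' @param counts Genes x cells matrix (dense or sparse).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  write.table(data.frame(id = rownames(counts), symbol = rownames(counts)),
              file.path(dir, "features.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a dense CSV count matrix (genes in rows, cells in columns)
#'
#' @param path CSV path; first column gene symbols, header row barcodes.
#' @return A sparse genes x cells count matrix.
#' @export
read_counts_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  methods::as(Matrix::Matrix(as.matrix(df), sparse = TRUE), "CsparseMatrix")
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene symbols,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (set name -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  sets
}
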