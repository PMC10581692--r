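# Count-matrix I/O: 10x-style Matrix-Market triplet directories
# (matrix.mtx + genes.tsv + barcodes.tsv [+ metadata.csv]) and single-file
# delimited dumps for small fixtures.

#' Validate a genes-by-cells count matrix
#'
#' Checks the count-matrix contract: integral non-negative values, unique
#' gene and cell identifiers on the dimnames.
#'
#' @param m Numeric matrix, genes in rows, cells in columns.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_counts <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("counts must be a numeric matrix (genes x cells)", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("counts must carry gene ids (rownames) and cell ids (colnames)",
         call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate cell identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(m) || any(m < 0) || any(m != floor(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  invisible(m)
}

#' Flag mitochondrial genes by name
#'
#' Mouse/10x convention: gene symbols prefixed `mt-` (case-insensitive).
#'
#' @param gene_ids Character vector of gene identifiers.
#' @return Logical vector, `TRUE` for mitochondrial genes.
#' @export
is_mito <- function(gene_ids) grepl("^mt-", gene_ids, ignore.case = TRUE)

#' Write a count matrix (and optional metadata) to a 10x-style directory
#'
#' Writes `matrix.mtx` (Matrix-Market triplet), `genes.tsv`,
#' `barcodes.tsv`, and, when metadata is supplied, `metadata.csv` with
#' columns `cell_id, group, cd133_status, ccnd1_status, cluster`.
#'
#' @param m Genes-by-cells integer count matrix with dimnames.
#' @param dir Output directory (created if absent).
#' @param metadata Optional per-cell `data.frame` with a `cell_id` column.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(m, dir, metadata = NULL) {
  validate_counts(m)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "TsparseMatrix")
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(gene = rownames(m), symbol = rownames(m)),
    file.path(dir, "genes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  if (!is.null(metadata)) {
    if (!"cell_id" %in% names(metadata))
      stop("metadata must have a `cell_id` column", call. = FALSE)
    utils::write.csv(metadata, file.path(dir, "metadata.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a count matrix from a 10x-style directory or delimited file
#'
#' A directory is expected to hold `matrix.mtx`, `genes.tsv`,
#' `barcodes.tsv`; a file is read as a delimited matrix (comma or tab,
#' decided by extension) with gene ids in the first column and cell ids as
#' the header. Round-trips with [write_counts()].
#'
#' @param path Directory or file path.
#' @return Integer matrix, genes x cells, with dimnames.
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) return(.read_counts_mtx(path))
  if (!file.exists(path))
    stop("no such file or directory: ", path, call. = FALSE)
  .read_counts_delim(path)
}

.read_counts_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  genes_f <- file.path(dir, "genes.tsv")
  bc_f <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, genes_f, bc_f))
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  if (file.size(mtx) == 0)
    stop("empty input file: ", mtx, call. = FALSE)
  sm <- tryCatch(Matrix::readMM(mtx), error = function(e)
    stop("malformed Matrix-Market triplet in ", mtx, ": ",
         conditionMessage(e), call. = FALSE))
  genes <- utils::read.table(genes_f, sep = "\t", header = FALSE,
                             colClasses = "character")[[1L]]
  cells <- readLines(bc_f)
  if (nrow(sm) != length(genes))
    stop("dimension mismatch in ", dir, ": matrix.mtx declares ", nrow(sm),
         " genes but genes.tsv has ", length(genes), " lines", call. = FALSE)
  if (ncol(sm) != length(cells))
    stop("dimension mismatch in ", dir, ": matrix.mtx declares ", ncol(sm),
         " cells but barcodes.tsv has ", length(cells), " lines",
         call. = FALSE)
  m <- as.matrix(sm)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes, cells)
  validate_counts(m)
  m
}

.read_counts_delim <- function(path) {
  if (file.size(path) == 0)
    stop("empty input file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  validate_counts(m)
  m
}

#' Write a count matrix as a single delimited file
#'
#' @param m Count matrix.
#' @param path Output `.csv` or `.tsv` file.
#' @return `path`, invisibly.
#' @export
write_counts_delim <- function(m, path) {
  validate_counts(m)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-cell metadata
#'
#' @param path `metadata.csv` file or a directory containing one.
#' @return `data.frame` with at least a `cell_id` column.
#' @export
read_metadata <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "metadata.csv")
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(md))
    stop("metadata file ", path, " lacks a `cell_id` column", call. = FALSE)
  md
}
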