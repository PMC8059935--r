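#' Spatial count matrix container
#'
#' Lightweight container for a cells x genes sparse UMI count matrix with
#' per-cell and per-gene annotations. Cells are keyed by the combinatorial
#' barcode (spatial barcode, PCR index) and carry their well of origin;
#' genes carry a species assignment inferred from the reference-namespace
#' prefix of the gene id (a joint human/mouse reference yields ids such as
#' `GRCh38_...` and `mm10_...`).
#'
#' @param counts cells x genes matrix (coerced to `dgCMatrix`), non-negative
#'   integers; rows named by cell id, columns by gene id.
#' @param cell_meta data.frame, one row per cell (row order = matrix rows).
#' @param gene_meta data.frame, one row per gene (row order = matrix columns).
#' @return An object of class `spatial_counts`.
#' @export
spatial_counts <- function(counts, cell_meta, gene_meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  stopifnot(nrow(cell_meta) == nrow(counts), nrow(gene_meta) == ncol(counts))
  cell_meta <- as.data.frame(cell_meta)
  gene_meta <- as.data.frame(gene_meta)
  if (is.null(rownames(counts))) rownames(counts) <- cell_meta$cell_id
  if (is.null(colnames(counts))) colnames(counts) <- gene_meta$gene_id
  cell_meta$total_umis <- Matrix::rowSums(counts)
  cell_meta$genes_detected <- Matrix::rowSums(counts > 0)
  rownames(cell_meta) <- rownames(counts)
  rownames(gene_meta) <- colnames(counts)
  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "spatial_counts")
}

#' @export
dim.spatial_counts <- function(x) dim(x$counts)

#' @export
print.spatial_counts <- function(x, ...) {
  cat(sprintf("spatial_counts: %d cells x %d genes, %d UMIs\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Subset a spatial count matrix
#'
#' @param x a `spatial_counts`.
#' @param cells,genes index vectors (logical, integer or names); missing
#'   keeps everything.
#' @return A `spatial_counts` restricted to the selection.
#' @export
subset_counts <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "spatial_counts"))
  if (is.null(cells)) cells <- seq_len(nrow(x$counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$counts))
  spatial_counts(x$counts[cells, genes, drop = FALSE],
                 x$cell_meta[cells, , drop = FALSE],
                 x$gene_meta[genes, , drop = FALSE])
}

#' Write / read counts as Matrix Market with TSV sidecars
#'
#' Writes `matrix.mtx` (genes x cells, the conventional orientation for
#' exchange), `barcodes.tsv` (the cell metadata) and `features.tsv` (the
#' gene metadata) into `dir`. `read_counts` reverses the operation.
#'
#' @param x a `spatial_counts`.
#' @param dir output (input) directory.
#' @return `write_counts` invisibly returns `dir`; `read_counts` returns a
#'   `spatial_counts`.
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "spatial_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  write_tsv(x$cell_meta, file.path(dir, "barcodes.tsv"))
  write_tsv(x$gene_meta, file.path(dir, "features.tsv"))
  invisible(dir)
}

#' @rdname write_counts
#' @export
read_counts <- function(dir) {
  m <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  cells <- read_tsv(file.path(dir, "barcodes.tsv"))
  genes <- read_tsv(file.path(dir, "features.tsv"))
  rownames(m) <- cells$cell_id
  colnames(m) <- genes$gene_id
  spatial_counts(m, cells, genes)
}
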