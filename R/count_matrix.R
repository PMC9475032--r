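#' UMI count matrix with cell metadata
#'
#' A light container for an integer gene x cell UMI count matrix together
#' with gene identifiers, cell identifiers, and a per-cell metadata table
#' (patient, tissue, platform). The matrix is stored sparse.
#'
#' @param values non-negative integer matrix (genes x cells); dense or
#'   `Matrix` sparse.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell identifiers (columns).
#' @param cell_meta data.frame with one row per cell; expected columns
#'   `patient`, `tissue` (one of tumor/normal/lymph_node), `platform`.
#'   May be `NULL`.
#' @return an object of class `count_matrix`.
#' @importFrom methods as
#' @export
count_matrix <- function(values, gene_ids, cell_ids, cell_meta = NULL) {
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(values) != length(gene_ids))
    stopf("gene_ids length (%d) does not match matrix rows (%d)",
          length(gene_ids), nrow(values))
  if (ncol(values) != length(cell_ids))
    stopf("cell_ids length (%d) does not match matrix columns (%d)",
          length(cell_ids), ncol(values))
  if (anyDuplicated(gene_ids)) stopf("duplicate gene ids")
  if (anyDuplicated(cell_ids)) stopf("duplicate cell ids")
  v <- values@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stopf("counts must be non-negative integers")
  if (!is.null(cell_meta)) {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != length(cell_ids))
      stopf("cell_meta has %d rows for %d cells", nrow(cell_meta),
            length(cell_ids))
    rownames(cell_meta) <- cell_ids
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$cell_meta))
    cat("  metadata:", paste(colnames(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

# Subset a count_matrix by cell index/ids, keeping metadata aligned.
subset_cells <- function(counts, cells) {
  count_matrix(counts$values[, cells, drop = FALSE],
               counts$gene_ids,
               counts$cell_ids[if (is.character(cells))
                 match(cells, counts$cell_ids) else cells],
               if (is.null(counts$cell_meta)) NULL
               else counts$cell_meta[cells, , drop = FALSE])
}
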