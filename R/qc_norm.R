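# Reading, QC filtering, log normalization and the clustering contract.

#' QC thresholds
#'
#' Presets follow the two platforms' filters: cells are kept with *more
#' than* `min_genes` detected genes, *more than* `min_transcripts` UMIs and
#' *lower than* `max_mito_fraction` mitochondrial counts (all strict
#' inequalities). `"strt"` = (1000, 10000, 0.20); `"tenx"` = (500, 1000,
#' 0.50).
#'
#' @param min_genes minimum detected genes (exclusive).
#' @param min_transcripts minimum total UMIs (exclusive).
#' @param max_mito_fraction maximum mitochondrial count fraction
#'   (exclusive), in `[0, 1]`.
#' @param preset `"strt"` or `"tenx"`; overrides the three values.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 500, min_transcripts = 1000,
                          max_mito_fraction = 0.5, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("strt", "tenx"))
    vals <- switch(preset,
                   strt = c(1000, 10000, 0.20),
                   tenx = c(500, 1000, 0.50))
    min_genes <- vals[1]; min_transcripts <- vals[2]; max_mito_fraction <- vals[3]
  }
  assert_scalar_num(min_genes, "min_genes", 0)
  assert_scalar_num(min_transcripts, "min_transcripts", 0)
  assert_scalar_num(max_mito_fraction, "max_mito_fraction", 0, 1)
  structure(list(min_genes = min_genes, min_transcripts = min_transcripts,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Read a UMI count matrix from Matrix Market files
#'
#' Expects `matrix.mtx` plus `genes.tsv` and `barcodes.tsv` sidecars (one
#' id per line) and, optionally, `cell_meta.tsv` as written by
#' [write_fixture()].
#'
#' @param directory directory holding the files.
#' @return a [count_matrix()].
#' @export
read_counts <- function(directory) {
  p <- function(f) file.path(directory, f)
  for (f in c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
    if (!file.exists(p(f))) stopf("missing file '%s' in '%s'", f, directory)
  m <- Matrix::readMM(p("matrix.mtx"))
  genes <- readLines(p("genes.tsv"))
  cells <- readLines(p("barcodes.tsv"))
  if (nrow(m) != length(genes))
    stopf("genes.tsv has %d entries for %d matrix rows", length(genes), nrow(m))
  if (ncol(m) != length(cells))
    stopf("barcodes.tsv has %d entries for %d matrix columns",
          length(cells), ncol(m))
  meta <- NULL
  if (file.exists(p("cell_meta.tsv"))) {
    meta <- utils::read.delim(p("cell_meta.tsv"), stringsAsFactors = FALSE)
    if (!identical(meta$cell_id, cells))
      stopf("cell_meta.tsv cell ids do not match barcodes.tsv")
    meta$cell_id <- NULL
  }
  count_matrix(m, genes, cells, meta)
}

# Per-cell QC statistics used by the filter.
qc_stats <- function(counts, mito_prefix = "MT-") {
  v <- counts$values
  total <- Matrix::colSums(v)
  detected <- Matrix::colSums(v > 0)
  mito <- is_mito_gene(counts$gene_ids, mito_prefix)
  mito_frac <- if (any(mito))
    Matrix::colSums(v[mito, , drop = FALSE]) / pmax(total, 1) else
      rep(0, ncol(v))
  data.frame(cell_id = counts$cell_ids, total = total, detected = detected,
             mito_fraction = mito_frac, row.names = NULL)
}

#' Filter cells by QC thresholds
#'
#' Keeps exactly the cells with detected genes > `min_genes`, total UMIs >
#' `min_transcripts` and mitochondrial fraction < `max_mito_fraction`
#' (strict inequalities). Genes and cell order are preserved.
#'
#' @param counts a [count_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return the filtered [count_matrix()].
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds(),
                      mito_prefix = "MT-") {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(thresholds, "qc_thresholds"))
  st <- qc_stats(counts, mito_prefix)
  keep <- st$detected > thresholds$min_genes &
    st$total > thresholds$min_transcripts &
    st$mito_fraction < thresholds$max_mito_fraction
  if (!any(keep))
    stopf("QC removed all %d cells; check thresholds against the data",
          ncol(counts$values))
  subset_cells(counts, which(keep))
}

#' Log-normalize a count matrix
#'
#' `value(g, c) = log(1 + scale_factor * count(g, c) / total(c))` (natural
#' log). Per cell, `sum(exp(value) - 1)` equals `scale_factor`.
#'
#' @param counts a [count_matrix()].
#' @param scale_factor positive scale, default `1e4`.
#' @return an `expression_matrix`: list with dense `values` (genes x
#'   cells), ids, `scale_factor` and the cell metadata carried over.
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  stopifnot(inherits(counts, "count_matrix"))
  assert_scalar_num(scale_factor, "scale_factor", min = .Machine$double.eps)
  total <- Matrix::colSums(counts$values)
  if (any(total == 0))
    stopf("%d cell(s) have zero total counts; filter before normalizing",
          sum(total == 0))
  vals <- log1p(sweep(as.matrix(counts$values), 2L, total, "/") * scale_factor)
  structure(list(values = vals, gene_ids = counts$gene_ids,
                 cell_ids = counts$cell_ids, cell_meta = counts$cell_meta,
                 scale_factor = scale_factor),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells (scale %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

# Top principal components of cells (cells x n_pcs score matrix).
cell_pcs <- function(expr, n_pcs = 20L) {
  x <- t(expr$values)
  x <- x[, apply(x, 2L, stats::var) > 0, drop = FALSE]
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1L)
  if (n_pcs < 1L) return(matrix(0, nrow(t(expr$values)), 1L))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  pc$x
}

#' Graph-based cell clustering
#'
#' Builds a k-nearest-neighbor graph (Euclidean distance on the top
#' principal components) and partitions it with Louvain modularity
#' communities. The algorithmic choice is a contract, not a claim: the
#' malignant caller needs stable labels, not a specific community
#' structure.
#'
#' @param expr an `expression_matrix`.
#' @param n_neighbors neighbors per cell in the kNN graph.
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed (community detection breaks ties randomly).
#' @param n_pcs number of principal components.
#' @return named integer vector of cluster labels (1-based), one per cell.
#' @export
cluster_cells <- function(expr, n_neighbors = 15L, resolution = 1,
                          seed = 1L, n_pcs = 20L) {
  stopifnot(inherits(expr, "expression_matrix"))
  n_cells <- ncol(expr$values)
  n_neighbors <- assert_count(n_neighbors, "n_neighbors", 1L)
  if (n_cells < n_neighbors + 1L)
    stopf("need at least n_neighbors + 1 = %d cells, have %d",
          n_neighbors + 1L, n_cells)
  pcs <- cell_pcs(expr, n_pcs)
  d <- as.matrix(stats::dist(pcs))
  if (max(d) == 0)  # degenerate geometry: identical cells, one community
    return(stats::setNames(rep(1L, n_cells), expr$cell_ids))
  edges <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    nn <- order(d[i, ])[2:(n_neighbors + 1L)]
    cbind(i, nn)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- with_seed_(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  stats::setNames(as.integer(igraph::membership(comm)), expr$cell_ids)
}
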