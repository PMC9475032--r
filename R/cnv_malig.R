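# Copy-number inference from expression and malignant-cell calling.
#
# The smoother follows the moving-average recipe popularized by inferCNV:
# per-gene reference centering in log space, residual clamping, a centered
# moving average along each chromosome, per-cell median centering, and a
# final reference re-centering before exponentiating to ratio space
# (baseline 1 = copy neutral).

# Centered moving average with a symmetric window that shrinks near the
# ends: at position i the half-width is min(h, i - 1, n - i).
moving_average_shrink <- function(x, window_size) {
  n <- length(x)
  h <- (window_size - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1L, n - i)
    out[i] <- (cs[i + hi + 1L] - cs[i - hi]) / (2L * hi + 1L)
  }
  out
}

#' Infer smoothed relative copy number from expression
#'
#' @param expr an `expression_matrix` (log-normalized).
#' @param positions gene position data.frame (gene, chromosome, start);
#'   chromosomes with fewer than `window_size` genes after intersection
#'   with `expr` are dropped with a warning.
#' @param reference_cells cell ids whose mean defines the copy-neutral
#'   baseline (e.g. normal epithelium from adjacent tissue).
#' @param window_size odd moving-average width in genes (default 101, the
#'   convention this class of smoother ships with).
#' @param cap residual clamp in log space (default 3).
#' @return a `cnv_matrix`: list with `values` (cells x genome-ordered
#'   genes, ratio space, baseline 1), `gene_order` data.frame, and
#'   `reference_cells`.
#' @export
infer_cnv <- function(expr, positions, reference_cells,
                      window_size = 101L, cap = 3) {
  stopifnot(inherits(expr, "expression_matrix"))
  window_size <- assert_count(window_size, "window_size", 3L)
  if (window_size %% 2L == 0L) stopf("window_size must be odd")
  assert_scalar_num(cap, "cap", min = .Machine$double.eps)
  if (length(reference_cells) == 0L) stopf("empty reference cell set")
  if (!all(reference_cells %in% expr$cell_ids))
    stopf("reference cells missing from the expression matrix")

  pos <- positions[positions$gene %in% expr$gene_ids, , drop = FALSE]
  if (nrow(pos) == 0L) stopf("no genes with positions in the expression matrix")
  keep_chrom <- names(which(table(pos$chromosome) >= window_size))
  dropped <- setdiff(unique(pos$chromosome), keep_chrom)
  if (length(dropped))
    warnf("dropping chromosome(s) with < %d positioned genes: %s",
          window_size, paste(dropped, collapse = ", "))
  pos <- pos[pos$chromosome %in% keep_chrom, , drop = FALSE]
  if (nrow(pos) == 0L) stopf("no chromosome has >= window_size genes")
  pos <- pos[order(pos$chromosome, pos$start), , drop = FALSE]

  x <- t(expr$values[match(pos$gene, expr$gene_ids), , drop = FALSE])
  ref_idx <- match(reference_cells, expr$cell_ids)

  # (1) reference centering, (2) clamp, (3) per-chromosome smoothing
  res <- sweep(x, 2L, colMeans(x[ref_idx, , drop = FALSE]), "-")
  res[res > cap] <- cap
  res[res < -cap] <- -cap
  for (ch in unique(pos$chromosome)) {
    j <- which(pos$chromosome == ch)
    res[, j] <- t(apply(res[, j, drop = FALSE], 1L,
                        moving_average_shrink, window_size))
  }
  # (4) per-cell median centering, (5) reference re-centering
  res <- sweep(res, 1L, apply(res, 1L, stats::median), "-")
  res <- sweep(res, 2L, colMeans(res[ref_idx, , drop = FALSE]), "-")
  structure(list(values = exp(res), gene_order = pos,
                 reference_cells = reference_cells),
            class = "cnv_matrix")
}

#' Mean-of-squared-deviation malignancy score
#'
#' `score(c) = mean over genes of (value(c, g) - baseline)^2`, the
#' measurement used to rank cells by the magnitude of their inferred
#' copy-number aberrations. Baseline 1 scores deviation from copy-neutral
#' in ratio space; `space = "log"` scores `log(value)` around 0.
#'
#' @param cnv a `cnv_matrix` (or bare cells x genes matrix, baseline 1).
#' @param space `"ratio"` (default) or `"log"`.
#' @return named non-negative numeric vector, one score per cell.
#' @export
msd_score <- function(cnv, space = c("ratio", "log")) {
  space <- match.arg(space)
  v <- if (inherits(cnv, "cnv_matrix")) cnv$values else as.matrix(cnv)
  if (length(v) == 0L) stopf("empty CNV matrix")
  dev <- if (space == "ratio") v - 1 else log(v)
  rowMeans(dev^2)
}

#' Percentile threshold from reference scores
#'
#' The threshold is the stated percentile of the reference (normal
#' epithelial) score distribution, computed by linear interpolation between
#' order statistics (R quantile type 7).
#'
#' @param normal_scores numeric scores of reference cells (>= 2 values).
#' @param percentile percentile in (0, 100], default 90.
#' @return scalar threshold.
#' @export
malignancy_threshold <- function(normal_scores, percentile = 90) {
  if (length(normal_scores) < 2L) stopf("need at least 2 reference scores")
  assert_scalar_num(percentile, "percentile")
  if (percentile <= 0 || percentile > 100)
    stopf("'percentile' must be in (0, 100]")
  unname(stats::quantile(normal_scores, percentile / 100, type = 7))
}

#' Call malignant cells by threshold plus cluster majority
#'
#' A cell is flagged high-CNV when its score strictly exceeds the
#' threshold; a cluster is called malignant when the fraction of high-CNV
#' cells in it exceeds `dominance` (default 0.5, a deterministic proxy for
#' the "high-CNV cells dominant" curation step); every cell inherits its
#' cluster's call.
#'
#' @param scores named per-cell MSD scores.
#' @param threshold scalar from [malignancy_threshold()].
#' @param clusters named cluster labels covering the scored cells.
#' @param dominance fraction of high-CNV cells above which a cluster is
#'   malignant (exclusive).
#' @return data.frame (cell_id, msd_score, high_cnv, cluster, final_call).
#' @export
call_malignant <- function(scores, threshold, clusters, dominance = 0.5) {
  if (is.null(names(scores)) || is.null(names(clusters)))
    stopf("scores and clusters must be named by cell id")
  missing <- setdiff(names(scores), names(clusters))
  if (length(missing))
    stopf("%d scored cell(s) have no cluster label", length(missing))
  assert_scalar_num(dominance, "dominance", 0, 1)
  cl <- clusters[names(scores)]
  high <- scores > threshold
  frac <- tapply(high, cl, mean)
  malignant_clusters <- names(frac)[frac > dominance]
  call <- ifelse(as.character(cl) %in% malignant_clusters,
                 "malignant", "normal")
  data.frame(cell_id = names(scores), msd_score = unname(scores),
             high_cnv = unname(high), cluster = unname(cl),
             final_call = call, stringsAsFactors = FALSE)
}
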