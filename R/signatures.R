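# Gene-set scoring, differential expression and score stratification.

#' Control-bin module score
#'
#' Re-implementation of the control-gene signature score used throughout
#' single-cell work: all genes are binned into `n_bins` groups by average
#' expression across cells; for each signature gene, `n_ctrl` control genes
#' are sampled with replacement from its bin; the score of a cell is the
#' mean expression of the signature genes minus the mean expression of the
#' pooled control draw. The expected score of a random gene set is 0.
#'
#' @param expr an `expression_matrix`, or a bare genes x cells matrix with
#'   rownames.
#' @param gene_set character vector of signature genes; genes missing from
#'   `expr` are dropped with a warning.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes sampled per signature gene (default 100).
#' @param seed integer seed for the control draw.
#' @return named numeric score per cell.
#' @export
module_score <- function(expr, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else
    as.matrix(expr)
  if (is.null(rownames(vals))) stopf("expression matrix must have gene names")
  n_bins <- assert_count(n_bins, "n_bins", 1L)
  n_ctrl <- assert_count(n_ctrl, "n_ctrl", 1L)
  sig <- intersect(gene_set, rownames(vals))
  if (length(sig) == 0L)
    stopf("gene set has no genes in common with the expression matrix")
  if (length(sig) < length(gene_set))
    warnf("dropping %d signature gene(s) absent from the matrix",
          length(gene_set) - length(sig))

  avg <- rowMeans(vals)
  n_bins_eff <- min(n_bins, length(unique(avg)))
  # equal-frequency bins on the rank of average expression; a constant
  # matrix collapses to a single bin
  bin <- if (n_bins_eff < 2L) rep(1L, nrow(vals)) else
    as.integer(cut(rank(avg, ties.method = "first"),
                   breaks = n_bins_eff, labels = FALSE,
                   include.lowest = TRUE))
  names(bin) <- rownames(vals)

  ctrl <- with_seed_(seed, {
    unlist(lapply(sig, function(g) {
      pool <- names(bin)[bin == bin[[g]]]
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }))
  })
  colMeans(vals[sig, , drop = FALSE]) -
    colMeans(vals[ctrl, , drop = FALSE])
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based enrichment per cell: genes are ranked by expression within
#' the cell; the score is the running-sum difference between the weighted
#' in-set empirical CDF (weights `rank^alpha`) and the unweighted out-set
#' CDF, summed over all positions. Depends on ranks only, so any strictly
#' increasing per-cell transform leaves it unchanged.
#'
#' @param expr an `expression_matrix` or bare matrix with rownames.
#' @param gene_set character vector; must not cover the whole gene
#'   universe (the out-set CDF would be undefined).
#' @param alpha rank-weighting exponent (default 0.25).
#' @return named numeric enrichment score per cell.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else
    as.matrix(expr)
  if (is.null(rownames(vals))) stopf("expression matrix must have gene names")
  assert_scalar_num(alpha, "alpha", 0)
  sig <- intersect(gene_set, rownames(vals))
  if (length(sig) == 0L)
    stopf("gene set has no genes in common with the expression matrix")
  n <- nrow(vals)
  if (length(sig) >= n)
    stopf("gene set equals the full gene universe; out-set is empty")
  in_set <- rownames(vals) %in% sig

  apply(vals, 2L, function(x) {
    # descending expression; ties broken by row order for determinism
    ord <- order(-x, seq_along(x))
    inset_ord <- in_set[ord]
    r <- rank(x, ties.method = "first")  # higher expression, higher rank
    w <- r[ord]^alpha
    w[!inset_ord] <- 0
    cdf_in <- cumsum(w) / sum(w)
    cdf_out <- cumsum(!inset_ord) / (n - length(sig))
    sum(cdf_in - cdf_out)
  })
}

#' Wilcoxon differential expression with detection and fold-change filters
#'
#' Genes are pre-filtered to those expressed (value > 0) in at least
#' `min_pct` of either group and with absolute log fold change at least
#' `logfc_threshold`; each surviving gene gets a two-sided Wilcoxon
#' rank-sum test, corrected across tested genes. The log fold change uses
#' the pseudo-count convention
#' `log(mean(expm1(x_a)) + 1) - log(mean(expm1(x_b)) + 1)` (natural log).
#'
#' @param expr an `expression_matrix` or bare matrix with gene rownames and
#'   cell colnames.
#' @param group_a,group_b cell ids of the two groups (>= 3 cells each).
#' @param min_pct minimum detection fraction in either group (default
#'   0.25).
#' @param logfc_threshold minimum |log fold change| (default `log(2)`).
#' @param correction `"bonferroni"` or `"bh"`.
#' @param alpha significance level on the adjusted p (default 0.01).
#' @return data.frame (gene, avg_logfc, fold_change, pct_a, pct_b, p,
#'   p_adj, direction, significant), ordered by p.
#' @export
deg_test <- function(expr, group_a, group_b, min_pct = 0.25,
                     logfc_threshold = log(2),
                     correction = c("bonferroni", "bh"), alpha = 0.01) {
  correction <- match.arg(correction)
  vals <- if (inherits(expr, "expression_matrix")) expr$values else
    as.matrix(expr)
  if (is.null(colnames(vals))) stopf("expression matrix must have cell names")
  a <- match(group_a, colnames(vals))
  b <- match(group_b, colnames(vals))
  if (anyNA(a) || anyNA(b)) stopf("group cells missing from the matrix")
  if (length(a) < 3L || length(b) < 3L)
    stopf("both groups need at least 3 cells")
  assert_scalar_num(min_pct, "min_pct", 0, 1)

  xa <- vals[, a, drop = FALSE]
  xb <- vals[, b, drop = FALSE]
  pct_a <- rowMeans(xa > 0)
  pct_b <- rowMeans(xb > 0)
  lfc <- log(rowMeans(expm1(xa)) + 1) - log(rowMeans(expm1(xb)) + 1)
  tested <- (pmax(pct_a, pct_b) >= min_pct) & (abs(lfc) >= logfc_threshold)
  genes <- rownames(vals)[tested]
  if (length(genes) == 0L)
    return(data.frame(gene = character(), avg_logfc = numeric(),
                      fold_change = numeric(), pct_a = numeric(),
                      pct_b = numeric(), p = numeric(), p_adj = numeric(),
                      direction = character(), significant = logical()))
  p <- vapply(genes, function(g)
    suppressWarnings(stats::wilcox.test(xa[g, ], xb[g, ])$p.value),
    numeric(1))
  p_adj <- stats::p.adjust(p, method = if (correction == "bh") "BH"
                           else "bonferroni")
  out <- data.frame(
    gene = genes, avg_logfc = lfc[tested], fold_change = exp(lfc[tested]),
    pct_a = pct_a[tested], pct_b = pct_b[tested], p = p, p_adj = p_adj,
    direction = ifelse(lfc[tested] > 0, "up", "down"),
    significant = p_adj < alpha, stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p), , drop = FALSE]
}

#' Split cells into high/low groups by a score
#'
#' Default rule is a median split with ties going to the low group
#' (`score <= median` is low); alternatively a fixed threshold can be
#' supplied, in which case `score > threshold` is high.
#'
#' @param scores named numeric scores (>= 2 cells).
#' @param rule `"median"` or a single numeric threshold.
#' @return named factor with levels `low`, `high`.
#' @export
stratify_by_score <- function(scores, rule = "median") {
  if (length(scores) < 2L) stopf("need at least 2 scores")
  if (identical(rule, "median")) {
    if (length(unique(scores)) == 1L)
      stopf("all scores equal; median split undefined (use a threshold rule)")
    thr <- stats::median(scores)
    high <- scores > thr
  } else {
    assert_scalar_num(rule, "rule")
    high <- scores > rule
  }
  stats::setNames(factor(ifelse(high, "high", "low"),
                         levels = c("low", "high")), names(scores))
}
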