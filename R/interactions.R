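# Ligand-receptor edge scoring between cell-type pairs and differential
# edges across ordered conditions.

#' Score ligand-receptor edges between cell types
#'
#' For every ligand-receptor pair and ordered (sender, receiver) cell-type
#' pair: `weight` = mean ligand expression in the sender type times mean
#' receptor expression in the receiver type; the edge is `detected` only
#' when the fraction of sender cells expressing the ligand (value > 0) and
#' the fraction of receiver cells expressing the receptor both reach
#' `detection_threshold`; `specificity` is the product of the sender's
#' share of the ligand mean across all types and the receiver's share of
#' the receptor mean, so it sums to 1 over all type pairs of a
#' ligand-receptor pair whenever any edge is nonzero.
#'
#' @param expr an `expression_matrix` or bare genes x cells matrix with
#'   dimnames.
#' @param cell_types named character vector assigning every cell to a
#'   type (a partition of the cells).
#' @param lr_pairs data.frame with columns ligand, receptor; pairs whose
#'   genes are absent from `expr` are dropped with a warning.
#' @param detection_threshold detection fraction required on both ends
#'   (default 0.2).
#' @return data.frame (ligand, receptor, sender, receiver, weight,
#'   specificity, detected).
#' @export
extract_edges <- function(expr, cell_types, lr_pairs,
                          detection_threshold = 0.2) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else
    as.matrix(expr)
  assert_scalar_num(detection_threshold, "detection_threshold", 0, 1)
  if (is.null(names(cell_types))) stopf("cell_types must be named by cell id")
  if (!setequal(names(cell_types), colnames(vals)))
    stopf("cell_types must partition exactly the cells of the matrix")
  cell_types <- cell_types[colnames(vals)]
  types <- sort(unique(as.character(cell_types)))
  if (any(table(cell_types) == 0L)) stopf("empty cell type")

  genes <- unique(c(lr_pairs$ligand, lr_pairs$receptor))
  missing <- setdiff(genes, rownames(vals))
  if (length(missing))
    warnf("dropping %d pair gene(s) absent from the matrix", length(missing))
  keep <- lr_pairs$ligand %in% rownames(vals) &
    lr_pairs$receptor %in% rownames(vals)
  lr_pairs <- lr_pairs[keep, , drop = FALSE]
  if (nrow(lr_pairs) == 0L)
    return(data.frame(ligand = character(), receptor = character(),
                      sender = character(), receiver = character(),
                      weight = numeric(), specificity = numeric(),
                      detected = logical()))

  genes <- unique(c(lr_pairs$ligand, lr_pairs$receptor))
  # per-type mean expression and detection fraction for the pair genes
  mean_t <- vapply(types, function(ty)
    rowMeans(vals[genes, cell_types == ty, drop = FALSE]), numeric(length(genes)))
  frac_t <- vapply(types, function(ty)
    rowMeans(vals[genes, cell_types == ty, drop = FALSE] > 0),
    numeric(length(genes)))
  if (length(genes) == 1L) {  # vapply drops to vector
    mean_t <- matrix(mean_t, 1L, dimnames = list(genes, types))
    frac_t <- matrix(frac_t, 1L, dimnames = list(genes, types))
  } else {
    rownames(mean_t) <- rownames(frac_t) <- genes
  }

  grid <- expand.grid(sender = types, receiver = types,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(lr_pairs)), function(i) {
    lg <- lr_pairs$ligand[i]; rc <- lr_pairs$receptor[i]
    lsum <- sum(mean_t[lg, ]); rsum <- sum(mean_t[rc, ])
    w <- mean_t[lg, grid$sender] * mean_t[rc, grid$receiver]
    spec <- if (lsum > 0 && rsum > 0)
      (mean_t[lg, grid$sender] / lsum) * (mean_t[rc, grid$receiver] / rsum)
    else rep(0, nrow(grid))
    det <- frac_t[lg, grid$sender] >= detection_threshold &
      frac_t[rc, grid$receiver] >= detection_threshold
    data.frame(ligand = lg, receptor = rc, sender = grid$sender,
               receiver = grid$receiver, weight = unname(w),
               specificity = unname(spec), detected = unname(det),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Differential edges across ordered conditions
#'
#' Compares edge weights across two or more ordered conditions (e.g.
#' normal, primary tumor, metastasis). Zero weights are replaced by a
#' pseudo-weight (smallest nonzero weight across conditions times 1e-3)
#' before taking log ratios. With three or more conditions, an edge is
#' `continuously_up` when its weight strictly increases at every step and
#' `continuously_down` when it strictly decreases at every step.
#'
#' @param edge_tables named list (in condition order) of edge tables from
#'   [extract_edges()] over the same pair/type universe.
#' @return data.frame keyed by (ligand, receptor, sender, receiver) with
#'   per-condition weights, stepwise `log_ratio_*` columns, and a
#'   `change` classification (`continuously_up`, `continuously_down`,
#'   `none`).
#' @export
diff_edges <- function(edge_tables) {
  if (length(edge_tables) < 2L) stopf("need at least 2 conditions")
  key_of <- function(e) paste(e$ligand, e$receptor, e$sender, e$receiver,
                              sep = "|")
  keys <- lapply(edge_tables, key_of)
  for (i in seq_along(keys)[-1])
    if (!setequal(keys[[1]], keys[[i]]))
      stopf("edge tables have mismatched pair universes")
  cond <- names(edge_tables) %||% sprintf("cond%d", seq_along(edge_tables))
  base <- edge_tables[[1]][order(keys[[1]]),
                           c("ligand", "receptor", "sender", "receiver")]
  w <- vapply(seq_along(edge_tables), function(i) {
    e <- edge_tables[[i]]
    e$weight[order(keys[[i]])]
  }, numeric(nrow(base)))
  colnames(w) <- paste0("weight_", cond)

  nz <- w[w > 0]
  eps <- if (length(nz)) min(nz) * 1e-3 else 1e-12
  wp <- pmax(w, eps)
  lr <- log(wp[, -1, drop = FALSE]) - log(wp[, -ncol(wp), drop = FALSE])
  colnames(lr) <- paste0("log_ratio_", cond[-1], "_vs_", cond[-length(cond)])

  up <- apply(w, 1L, function(r) all(diff(r) > 0))
  down <- apply(w, 1L, function(r) all(diff(r) < 0))
  change <- ifelse(up, "continuously_up",
                   ifelse(down, "continuously_down", "none"))
  out <- cbind(base, as.data.frame(w), as.data.frame(lr),
               data.frame(change = change, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
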