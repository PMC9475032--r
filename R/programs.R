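# Intra-tumor expression programs: per-patient signatures from PCA poles
# and NMF factors, clustered across patients into shared meta-programs.

new_signature <- function(patient, source, component, genes) {
  structure(list(patient = patient, source = source,
                 component = as.integer(component),
                 genes = as.character(genes)),
            class = "program_signature")
}

#' @export
print.program_signature <- function(x, ...) {
  cat(sprintf("<program_signature> %s %s%d: %d genes\n", x$patient,
              x$source, x$component, length(x$genes)))
  invisible(x)
}

#' PCA pole signatures for one patient's malignant cells
#'
#' Runs PCA on the centered expression of one patient's malignant cells
#' and, for each of the top components, takes the genes with the most
#' positive and the most negative loadings as two candidate program
#' signatures (the "poles" of the component).
#'
#' @param expr `expression_matrix` restricted to one patient's malignant
#'   cells (or bare genes x cells matrix with dimnames).
#' @param patient patient id recorded in the signatures.
#' @param n_components top principal components to use (default 6).
#' @param n_genes_per_pole genes per pole signature (default 50).
#' @return list of `program_signature` (2 per component, positive pole
#'   first).
#' @export
pca_pole_signatures <- function(expr, patient = "P", n_components = 6L,
                                n_genes_per_pole = 50L) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else
    as.matrix(expr)
  n_components <- assert_count(n_components, "n_components", 0L)
  n_genes_per_pole <- assert_count(n_genes_per_pole, "n_genes_per_pole", 1L)
  if (n_components == 0L) return(list())
  if (ncol(vals) < n_components + 1L)
    stopf("need at least n_components + 1 = %d cells", n_components + 1L)
  keep <- apply(vals, 1L, stats::var) > 0
  if (!any(keep)) stopf("expression is degenerate (no gene varies)")
  x <- t(vals[keep, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE,
                      rank. = min(n_components, ncol(x), nrow(x) - 1L))
  load <- pc$rotation
  out <- list()
  for (k in seq_len(ncol(load))) {
    lk <- load[, k]
    pos <- names(sort(lk, decreasing = TRUE))[seq_len(min(n_genes_per_pole,
                                                          length(lk)))]
    neg <- names(sort(lk))[seq_len(min(n_genes_per_pole, length(lk)))]
    out[[length(out) + 1L]] <- new_signature(patient, "pc_pos", k, pos)
    out[[length(out) + 1L]] <- new_signature(patient, "pc_neg", k, neg)
  }
  out
}

# NNDSVD initialization (non-negative double SVD): deterministic and far
# less prone to poor local optima than random starts. Zeros are replaced
# by the matrix mean ("NNDSVDa" variant) so multiplicative updates can
# move every entry.
nndsvd_init <- function(x, k) {
  sv <- svd(x, nu = k, nv = k)
  w <- matrix(0, nrow(x), k); h <- matrix(0, k, ncol(x))
  w[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  h[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  for (j in seq_len(k)[-1]) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npos >= nneg && npos > 0) {
      w[, j] <- sqrt(sv$d[j] * npos) * up / sqrt(sum(up^2))
      h[j, ] <- sqrt(sv$d[j] * npos) * vp / sqrt(sum(vp^2))
    } else if (nneg > 0) {
      w[, j] <- sqrt(sv$d[j] * nneg) * un / sqrt(sum(un^2))
      h[j, ] <- sqrt(sv$d[j] * nneg) * vn / sqrt(sum(vn^2))
    }
  }
  m <- mean(x)
  w[w == 0] <- m; h[h == 0] <- m
  list(w = w, h = h)
}

# Multiplicative-update NMF (Frobenius loss), deterministic under seed.
nmf_factorize <- function(x, k, seed = 1L, max_iter = 200L, tol = 1e-6,
                          init = c("nndsvd", "random")) {
  init <- match.arg(init)
  eps <- 1e-10
  with_seed_(seed, {
    if (init == "nndsvd" && min(dim(x)) > k) {
      ini <- nndsvd_init(x, k)
      w <- ini$w; h <- ini$h
    } else {
      w <- matrix(stats::runif(nrow(x) * k, 0, 1), nrow(x), k)
      h <- matrix(stats::runif(k * ncol(x), 0, 1), k, ncol(x))
    }
    prev <- Inf
    for (it in seq_len(max_iter)) {
      h <- h * (crossprod(w, x) + eps) / (crossprod(w) %*% h + eps)
      w <- w * (x %*% t(h) + eps) / (w %*% tcrossprod(h) + eps)
      if (it %% 10L == 0L) {
        err <- sum((x - w %*% h)^2)
        if (is.finite(prev) && abs(prev - err) < tol * max(prev, eps)) break
        prev <- err
      }
    }
    # scale factors to unit column norm in W for comparability
    s <- sqrt(colSums(w^2))
    s[s == 0] <- 1
    list(w = sweep(w, 2L, s, "/"), h = sweep(h, 1L, s, "*"))
  })
}

#' NMF program signatures for one patient's malignant cells
#'
#' Factorizes the non-negative (log-normalized) expression of one
#' patient's malignant cells with multiplicative-update NMF and takes the
#' top-loading genes of each factor as a candidate program signature. By
#' default the expression is first converted to relative expression
#' (per-gene centering with negatives clipped to zero), the standard
#' device for intra-tumor program NMF: without it the leading factors
#' just reproduce the mean expression profile.
#'
#' @param expr `expression_matrix` (non-negative values) restricted to one
#'   patient's malignant cells, or a bare non-negative matrix.
#' @param patient patient id recorded in the signatures.
#' @param n_factors number of factors (default 6).
#' @param n_genes genes per factor signature (default 50).
#' @param seed integer seed (used by the `"random"` init).
#' @param max_iter maximum multiplicative-update iterations.
#' @param center centre each gene and clip negatives before factorizing
#'   (default `TRUE`); set `FALSE` to factorize the raw values.
#' @param init `"nndsvd"` (deterministic SVD-based, default) or
#'   `"random"`.
#' @return list of `program_signature`, one per factor, plus the fitted
#'   factor matrices in `attr(, "fit")`.
#' @export
nmf_programs <- function(expr, patient = "P", n_factors = 6L, n_genes = 50L,
                         seed = 1L, max_iter = 200L, center = TRUE,
                         init = "nndsvd") {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else
    as.matrix(expr)
  if (any(vals < 0)) stopf("NMF requires non-negative input")
  n_factors <- assert_count(n_factors, "n_factors", 1L)
  n_genes <- assert_count(n_genes, "n_genes", 1L)
  if (center) {
    vals <- vals - rowMeans(vals)
    vals[vals < 0] <- 0
  }
  fit <- nmf_factorize(vals, n_factors, seed = seed, max_iter = max_iter,
                       init = init)
  sigs <- lapply(seq_len(n_factors), function(k) {
    top <- order(fit$w[, k], decreasing = TRUE)[seq_len(min(n_genes,
                                                            nrow(vals)))]
    new_signature(patient, "nmf_factor", k, rownames(vals)[top])
  })
  attr(sigs, "fit") <- fit
  sigs
}

#' Cluster per-patient signatures into shared meta-programs
#'
#' Scores every signature on all malignant cells (control-bin module
#' score), computes pairwise Pearson correlations of the score vectors,
#' and hierarchically clusters the signatures with distance
#' `1 - correlation`. Clusters containing signatures from at least two
#' patients are "shared" meta-programs; their consensus gene list is the
#' set of genes appearing in at least `min_support` member signatures.
#'
#' @param signatures list of `program_signature` from >= 2 patients.
#' @param expr `expression_matrix` over all malignant cells.
#' @param k number of signature clusters to cut (default 12; deep enough
#'   that noise signatures separate into their own clusters instead of
#'   being absorbed into program clusters).
#' @param linkage hierarchical linkage method (default `"average"`).
#' @param min_support minimum member signatures a consensus gene must
#'   appear in (default 2).
#' @param consensus_size cap on the consensus gene list; genes are ranked
#'   by member support (ties alphabetical). Default: the largest member
#'   signature size, so the consensus stays comparable to its members.
#' @param seed seed for the module-score control draw.
#' @return list of meta-programs (class `meta_program`): name, members,
#'   patients, consensus genes, shared flag, per-cell score.
#' @export
cluster_signatures <- function(signatures, expr, k = 12L,
                               linkage = "average", min_support = 2L,
                               consensus_size = NULL, seed = 1L) {
  if (length(signatures) < 2L) stopf("need at least 2 signatures")
  k <- min(assert_count(k, "k", 1L), length(signatures))
  scores <- vapply(seq_along(signatures), function(i)
    module_score(expr, signatures[[i]]$genes,
                 seed = derive_seed(seed, i)),
    numeric(ncol(if (inherits(expr, "expression_matrix")) expr$values
                 else expr)))
  cors <- suppressWarnings(stats::cor(scores))
  cors[!is.finite(cors)] <- 0
  diag(cors) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cors), method = linkage)
  cl <- stats::cutree(hc, k = k)

  out <- list()
  for (g in sort(unique(cl))) {
    members <- signatures[cl == g]
    pats <- unique(vapply(members, function(s) s$patient, character(1)))
    genes <- unlist(lapply(members, function(s) s$genes))
    tab <- table(genes)
    tab <- tab[tab >= min(min_support, length(members))]
    tab <- tab[order(-as.integer(tab), names(tab))]
    cap <- consensus_size %||% max(vapply(members, function(s)
      length(s$genes), integer(1)))
    consensus <- names(tab)[seq_len(min(cap, length(tab)))]
    mp <- structure(list(
      name = sprintf("MP%d", g), members = members, patients = pats,
      consensus_genes = consensus, shared = length(pats) >= 2L,
      score = rowMeans(scores[, cl == g, drop = FALSE])),
      class = "meta_program")
    out[[length(out) + 1L]] <- mp
  }
  out
}

#' @export
print.meta_program <- function(x, ...) {
  cat(sprintf("<meta_program> %s: %d members from %d patient(s), %d consensus genes%s\n",
              x$name, length(x$members), length(x$patients),
              length(x$consensus_genes), if (x$shared) " [shared]" else ""))
  invisible(x)
}

#' Assign each malignant cell to its best-scoring meta-program
#'
#' Scores every meta-program's consensus gene list per cell (control-bin
#' module score) and labels the cell with the argmax; exact ties are
#' broken by meta-program order (first wins) and all-zero score rows fall
#' back to the first program with a message.
#'
#' @param meta_programs list of `meta_program`.
#' @param expr `expression_matrix` over the malignant cells.
#' @param seed seed for the module-score control draws.
#' @return list with `labels` (named character) and `scores` (cells x
#'   programs matrix).
#' @export
assign_programs <- function(meta_programs, expr, seed = 1L) {
  if (length(meta_programs) == 0L) stopf("no meta-programs to assign")
  scores <- vapply(seq_along(meta_programs), function(i)
    module_score(expr, meta_programs[[i]]$consensus_genes,
                 seed = derive_seed(seed, 100L + i)),
    numeric(ncol(if (inherits(expr, "expression_matrix")) expr$values
                 else expr)))
  colnames(scores) <- vapply(meta_programs, function(m) m$name, character(1))
  if (any(rowSums(scores != 0) == 0))
    message("cells with all-zero program scores assigned to the first program")
  labels <- colnames(scores)[max.col(scores, ties.method = "first")]
  list(labels = stats::setNames(labels, rownames(scores)), scores = scores)
}
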