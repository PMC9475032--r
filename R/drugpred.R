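# Ridge-regression drug-response prediction on pseudo-bulk groups with the
# three-criterion candidate filter.

#' Random pseudo-bulk groups per class
#'
#' Within each class (tumor = malignant cells, normal = normal epithelial
#' cells), cells are randomly partitioned into `n_groups_per_class`
#' near-equal groups and each group's profile is the per-gene mean of the
#' log-normalized expression.
#'
#' @param expr an `expression_matrix` or bare genes x cells matrix.
#' @param classes named character vector (`"malignant"`/`"normal"`) over
#'   the cells of `expr`.
#' @param n_groups_per_class groups per class (default 50).
#' @param seed integer seed for the random partition.
#' @return list with `profiles` (genes x groups matrix), `group_class`
#'   (named `"tumor"`/`"normal"`), and `membership` (cell -> group).
#' @export
pseudobulk_groups <- function(expr, classes, n_groups_per_class = 50L,
                              seed = 1L) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else
    as.matrix(expr)
  n_groups_per_class <- assert_count(n_groups_per_class,
                                     "n_groups_per_class", 1L)
  if (is.null(names(classes))) stopf("classes must be named by cell id")
  classes <- classes[colnames(vals)]
  if (anyNA(classes)) stopf("every cell needs a class label")
  class_map <- c(malignant = "tumor", normal = "normal")
  if (!all(classes %in% names(class_map)))
    stopf("classes must be 'malignant' or 'normal'")

  membership <- character(ncol(vals))
  names(membership) <- colnames(vals)
  profiles <- list(); group_class <- character()
  with_seed_(seed, {
    for (cl in c("malignant", "normal")) {
      cells <- which(classes == cl)
      if (length(cells) < n_groups_per_class)
        stopf("class '%s' has %d cells for %d groups", cl, length(cells),
              n_groups_per_class)
      perm <- sample(cells)
      # near-equal group sizes: earlier groups get the remainder cells
      grp <- sort(rep_len(seq_len(n_groups_per_class), length(perm)))
      for (g in seq_len(n_groups_per_class)) {
        gc <- perm[grp == g]
        gid <- sprintf("%s_G%02d", class_map[[cl]], g)
        profiles[[gid]] <- rowMeans(vals[, gc, drop = FALSE])
        group_class[[gid]] <- class_map[[cl]]
        membership[gc] <- gid
      }
    }
  })
  list(profiles = do.call(cbind, profiles), group_class = group_class,
       membership = membership)
}

#' Tumor score of pseudo-bulk groups
#'
#' Control-bin module score of a malignant signature (typically the
#' malignant-vs-normal differential expression gene list) evaluated on the
#' pseudo-bulk profiles. Used as the correlation covariate in the
#' candidate filter.
#'
#' @param pseudobulks result of [pseudobulk_groups()].
#' @param malignant_signature character vector of signature genes.
#' @param seed seed for the module-score control draw.
#' @return named numeric score per group.
#' @export
tumor_score <- function(pseudobulks, malignant_signature, seed = 1L) {
  if (length(malignant_signature) == 0L) stopf("empty malignant signature")
  module_score(pseudobulks$profiles, malignant_signature, seed = seed)
}

#' Ridge regression drug-response prediction
#'
#' Per drug: the panel and the pseudo-bulk profiles are restricted to
#' their common genes and harmonized per gene before fitting. The default
#' `"double"` harmonization standardizes the training lines by their own
#' per-gene mean/sd and the pseudo-bulk profiles by *their* own per-gene
#' mean/sd, mapping the two clouds onto a common location and scale (a
#' deterministic stand-in for the quantile homogenization used by
#' cell-line transfer tools; single-cell platform shifts otherwise put
#' pseudo-bulks far outside the training distribution and predictions
#' extrapolate wildly). `"train"` applies the training transform to both
#' sides, with pseudo-bulk z-values clipped to `[-z_clip, z_clip]`. A
#' ridge regression (unpenalized intercept) is then fit on the training
#' lines with the penalty chosen by k-fold cross-validation, and the
#' group responses are predicted.
#'
#' @param panel list with `line_expression` (genes x lines) and `response`
#'   (long data.frame drug/line/auc), as from [generate_drug_panel()] or
#'   [read_drug_panel()].
#' @param pseudobulks result of [pseudobulk_groups()].
#' @param lambda_rule `"lambda.min"` or `"lambda.1se"` (cross-validated
#'   penalty choice).
#' @param min_lines minimum measured lines per drug (default 20); drugs
#'   below it are skipped with a warning.
#' @param min_genes minimum common genes required (default 50).
#' @param nfolds cross-validation folds (default 5).
#' @param harmonize `"double"` (default) or `"train"`; see Details.
#' @param z_clip harmonized-value clip in training standard deviations
#'   for the `"train"` method (default 3; `Inf` disables).
#' @param seed seed controlling the fold assignment.
#' @return matrix of predicted AUC, drugs x groups.
#' @export
ridge_fit_predict <- function(panel, pseudobulks,
                              lambda_rule = c("lambda.min", "lambda.1se"),
                              min_lines = 20L, min_genes = 50L,
                              nfolds = 5L, harmonize = c("double", "train"),
                              z_clip = 3, seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  harmonize <- match.arg(harmonize)
  expr <- panel$line_expression
  common <- intersect(rownames(expr), rownames(pseudobulks$profiles))
  if (length(common) < min_genes)
    stopf("only %d common genes between panel and pseudobulks (need >= %d)",
          length(common), min_genes)
  xt <- t(expr[common, , drop = FALSE])            # lines x genes
  xp <- t(pseudobulks$profiles[common, , drop = FALSE])  # groups x genes
  mu <- colMeans(xt)
  sd <- apply(xt, 2L, stats::sd)
  keep <- sd > 0
  xt <- sweep(sweep(xt[, keep, drop = FALSE], 2L, mu[keep], "-"),
              2L, sd[keep], "/")
  if (harmonize == "double") {
    mp <- colMeans(xp[, keep, drop = FALSE])
    sp <- apply(xp[, keep, drop = FALSE], 2L, stats::sd)
    sp[sp == 0] <- 1  # constant gene in pseudobulks: center only
    xp <- sweep(sweep(xp[, keep, drop = FALSE], 2L, mp, "-"), 2L, sp, "/")
  } else {
    xp <- sweep(sweep(xp[, keep, drop = FALSE], 2L, mu[keep], "-"),
                2L, sd[keep], "/")
    xp[xp > z_clip] <- z_clip
    xp[xp < -z_clip] <- -z_clip
  }

  drugs <- unique(panel$response$drug)
  preds <- matrix(NA_real_, length(drugs), nrow(xp),
                  dimnames = list(drugs, rownames(xp)))
  for (d in drugs) {
    resp <- panel$response[panel$response$drug == d, ]
    lines <- intersect(resp$line, rownames(xt))
    if (length(lines) < min_lines) {
      warnf("drug '%s' has %d measured lines (< %d); skipped", d,
            length(lines), min_lines)
      next
    }
    y <- resp$auc[match(lines, resp$line)]
    # explicit broad penalty grid: glmnet's automatic ridge path stops
    # early once deviance saturates, stranding lambda.min at the path
    # edge on strong-signal panels (features are standardized and y is
    # O(1), so a fixed grid is adequate)
    lambda_grid <- exp(seq(log(1e3), log(1e-6), length.out = 100))
    fit <- with_seed_(derive_seed(seed, match(d, drugs)),
      glmnet::cv.glmnet(xt[lines, , drop = FALSE], y, alpha = 0,
                        nfolds = nfolds, standardize = FALSE,
                        lambda = lambda_grid))
    preds[d, ] <- as.vector(stats::predict(fit, newx = xp, s = lambda_rule))
  }
  preds[!apply(preds, 1L, function(r) all(is.na(r))), , drop = FALSE]
}

#' Filter candidate drugs by the three stated criteria
#'
#' Per drug: a two-sample t-test of the predicted AUC between tumor and
#' normal pseudo-bulk groups (corrected across drugs), the log2 fold
#' change of the tumor mean over the normal mean, and the Pearson
#' correlation of the predicted AUC with the tumor score across all
#' groups. A drug is a candidate when `adjusted p < p_cut`, `log2fc <
#' log2fc_cut` and `correlation < cor_cut` (defaults 0.05, -0.1, -0.5:
#' predicted more sensitive in tumor groups, tracking malignancy).
#'
#' @param predictions drugs x groups matrix from [ridge_fit_predict()].
#' @param group_class named `"tumor"`/`"normal"` vector over the groups.
#' @param tumor_scores named numeric tumor score per group.
#' @param p_cut,log2fc_cut,cor_cut the three thresholds.
#' @param correction `"bh"` (default) or `"bonferroni"`.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return data.frame (drug, mean_tumor, mean_normal, log2fc, p, p_adj,
#'   tumor_score_correlation, candidate), ordered by p.
#' @export
filter_candidates <- function(predictions, group_class, tumor_scores,
                              p_cut = 0.05, log2fc_cut = -0.1,
                              cor_cut = -0.5,
                              correction = c("bh", "bonferroni"),
                              cor_method = c("pearson", "spearman")) {
  correction <- match.arg(correction)
  cor_method <- match.arg(cor_method)
  groups <- colnames(predictions)
  gc <- group_class[groups]
  if (anyNA(gc)) stopf("group_class missing for some groups")
  if (sum(gc == "tumor") < 2L || sum(gc == "normal") < 2L)
    stopf("need at least 2 groups per class")
  ts <- tumor_scores[groups]

  rows <- lapply(rownames(predictions), function(d) {
    pr <- predictions[d, ]
    mt <- mean(pr[gc == "tumor"]); mn <- mean(pr[gc == "normal"])
    if (mt <= 0 || mn <= 0) {
      warnf("drug '%s' has non-positive mean predicted AUC; excluded", d)
      return(NULL)
    }
    # near-constant predictions (infinite shrinkage) carry no evidence
    pval <- tryCatch(stats::t.test(pr[gc == "tumor"],
                                   pr[gc == "normal"])$p.value,
                     error = function(e) 1)
    data.frame(drug = d, mean_tumor = mt, mean_normal = mn,
               log2fc = log2(mt / mn), p = pval,
               tumor_score_correlation =
                 suppressWarnings(stats::cor(pr, ts, method = cor_method)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no drug with positive mean predicted AUC")
  out$p_adj <- stats::p.adjust(out$p, method = if (correction == "bh") "BH"
                               else "bonferroni")
  out$candidate <- out$p_adj < p_cut & out$log2fc < log2fc_cut &
    !is.na(out$tumor_score_correlation) &
    out$tumor_score_correlation < cor_cut
  out <- out[order(out$p), c("drug", "mean_tumor", "mean_normal", "log2fc",
                             "p", "p_adj", "tumor_score_correlation",
                             "candidate")]
  rownames(out) <- NULL
  out
}
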