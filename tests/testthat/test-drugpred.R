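# Pseudo-bulk groups, tumor score, ridge prediction, candidate filter.

small_world <- function(seed = 1) {
  cc <- cohort_config(n_cells_per_patient = 150, malignant_fraction = 0.4,
                      n_genes = 600, program_size = 25, seed = seed)
  co <- generate_cohort(cc)
  ex <- normalize_log(co$counts)
  classes <- stats::setNames(co$truth$cells$class, co$truth$cells$cell_id)
  list(cc = cc, co = co, ex = ex, classes = classes)
}

test_that("pseudobulk_groups partitions cells and averages correctly", {
  w <- small_world()
  pb <- pseudobulk_groups(w$ex, w$classes, n_groups_per_class = 10, seed = 2)
  # disjoint cover of all cells
  expect_setequal(names(pb$membership), w$ex$cell_ids)
  expect_false(any(pb$membership == ""))
  # sizes near-equal within class
  sizes <- table(pb$membership)
  mal_sizes <- sizes[grep("tumor", names(sizes))]
  expect_lte(max(mal_sizes) - min(mal_sizes), 1)
  # group means match brute-force per-gene averages
  for (g in sample(names(pb$group_class), 3)) {
    cells <- names(pb$membership)[pb$membership == g]
    brute <- apply(w$ex$values[, cells, drop = FALSE], 1, mean)
    expect_equal(pb$profiles[, g], brute, tolerance = 1e-12)
  }
  # one group per class reproduces the class mean
  pb1 <- pseudobulk_groups(w$ex, w$classes, 1, seed = 3)
  mal <- names(w$classes)[w$classes == "malignant"]
  expect_equal(pb1$profiles[, "tumor_G01"],
               rowMeans(w$ex$values[, mal]), tolerance = 1e-12)
  # determinism + class-size guard
  expect_identical(pseudobulk_groups(w$ex, w$classes, 10, seed = 2)$membership,
                   pb$membership)
  expect_error(pseudobulk_groups(w$ex, w$classes, 1000), "for 1000 groups")
})

test_that("tumor_score separates classes; constants score zero", {
  w <- small_world(3)
  pb <- pseudobulk_groups(w$ex, w$classes, 15, seed = 1)
  sig <- unlist(w$co$truth$program_gene_sets)
  ts <- tumor_score(pb, sig, seed = 4)
  tumor <- ts[pb$group_class == "tumor"]
  normal <- ts[pb$group_class == "normal"]
  # AUC of separation
  auc <- mean(outer(tumor, normal, ">"))
  expect_gte(auc, 0.95)
  # permutation equivariance
  perm <- rev(seq_along(ts))
  pb2 <- pb
  pb2$profiles <- pb$profiles[, perm]
  expect_equal(unname(tumor_score(pb2, sig, seed = 4)),
               unname(ts[perm]), tolerance = 1e-12)
  # constant profiles give all-zero scores
  pbc <- pb
  pbc$profiles <- matrix(1, nrow(pb$profiles), ncol(pb$profiles),
                         dimnames = dimnames(pb$profiles))
  expect_equal(unname(tumor_score(pbc, sig, seed = 1)),
               rep(0, ncol(pb$profiles)))
  expect_error(tumor_score(pb, character()), "empty")
})

test_that("ridge shrinkage limits behave as expected", {
  # strong-noise panel: CV picks heavy shrinkage, predictions ~ mean AUC
  withr::with_seed(8, {
    xt <- matrix(rnorm(3000), 60, 50,
                 dimnames = list(sprintf("L%02d", 1:60), NULL))
    y <- rnorm(60, 5, 0.01)             # essentially constant response
  })
  panel <- list(line_expression = t(xt) |>
                  `rownames<-`(sprintf("g%02d", 1:50)),
                response = data.frame(drug = "d", line = rownames(xt),
                                      auc = y))
  pb <- list(profiles = t(xt[1:10, ]) |>
               `rownames<-`(sprintf("g%02d", 1:50)) |>
               `colnames<-`(sprintf("grp%02d", 1:10)),
             group_class = stats::setNames(rep(c("tumor", "normal"), 5),
                                           sprintf("grp%02d", 1:10)))
  pr <- ridge_fit_predict(panel, pb, min_lines = 10, min_genes = 10,
                          seed = 1)
  expect_lt(max(abs(pr - mean(y))), 0.05)
  expect_error(ridge_fit_predict(panel, list(profiles = pb$profiles[1:3, ]),
                                 min_lines = 10, min_genes = 10),
               "common genes")
})

test_that("noiseless planted panels are predicted almost exactly", {
  # well-determined training set (n >> p): the noiseless linear response
  # on 10 target genes is recovered essentially exactly on held-out lines
  cc <- cohort_config(n_genes = 600, program_size = 25, seed = 2)
  genes <- scmalig:::cohort_genes(cc)
  tg <- genes$gene[cc$program_gene_sets[[1]]][1:10]
  pan <- generate_drug_panel(500, 120, "d1", "d1", effect_size = -1,
                             noise_sd = 0, seed = 3, config = cc,
                             target_genes = list(d1 = tg), intercept = 2.1)
  expr <- pan$panel$line_expression
  hold <- colnames(expr)[401:500]
  train <- list(line_expression = expr[, 1:400],
                response = pan$panel$response[
                  pan$panel$response$line %in% colnames(expr)[1:400], ])
  pb <- list(profiles = expr[, hold],
             group_class = stats::setNames(rep(c("tumor", "normal"), 50),
                                           hold))
  # held-out lines share the training platform: one-sided harmonization
  pr <- ridge_fit_predict(train, pb, min_lines = 20, min_genes = 50,
                          seed = 4, harmonize = "train", z_clip = Inf)
  truth <- pan$panel$response$auc[match(hold, pan$panel$response$line)]
  r2 <- 1 - sum((pr["d1", ] - truth)^2) / sum((truth - mean(truth))^2)
  expect_gte(r2, 0.99)
})

test_that("filter_candidates applies the three criteria and brute-force stats", {
  groups <- c(sprintf("t%02d", 1:10), sprintf("n%02d", 1:10))
  gcl <- stats::setNames(rep(c("tumor", "normal"), each = 10), groups)
  ts <- stats::setNames(c(rnorm(10, 2, 0.1), rnorm(10, 0, 0.1)), groups)
  preds <- rbind(
    hit  = c(rnorm(10, 0.8, 0.02), rnorm(10, 1.0, 0.02)),
    null = rep(1, 20),
    up   = c(rnorm(10, 1.2, 0.02), rnorm(10, 1.0, 0.02)))
  colnames(preds) <- groups
  res <- filter_candidates(preds, gcl, ts)
  expect_true(res$candidate[res$drug == "hit"])
  expect_false(res$candidate[res$drug == "null"])
  expect_false(res$candidate[res$drug == "up"])
  expect_equal(res$log2fc[res$drug == "null"], 0)

  # t-test p and BH adjustment match hand-rolled oracles
  p_manual <- vapply(rownames(preds), function(d) {
    x <- preds[d, gcl == "tumor"]; y <- preds[d, gcl == "normal"]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(1)
    stats::t.test(x, y)$p.value
  }, numeric(1))
  expect_equal(res$p[match(rownames(preds), res$drug)],
               unname(p_manual), tolerance = 1e-10)
  expect_equal(res$p_adj[match(rownames(preds), res$drug)],
               oracle_bh(unname(p_manual)), tolerance = 1e-10)
  resb <- filter_candidates(preds, gcl, ts, correction = "bonferroni")
  expect_equal(resb$p_adj[match(rownames(preds), resb$drug)],
               oracle_bonferroni(unname(p_manual)), tolerance = 1e-10)

  # non-positive mean predictions excluded with a warning
  preds2 <- rbind(preds, bad = rep(-1, 20))
  expect_warning(res2 <- filter_candidates(preds2, gcl, ts), "non-positive")
  expect_false("bad" %in% res2$drug)
})

test_that("predictions ignore gene and cell order", {
  w <- small_world(5)
  pb <- pseudobulk_groups(w$ex, w$classes, 10, seed = 1)
  pan <- generate_drug_panel(60, 300, c("d1", "d2"), "d1", seed = 2,
                             config = w$cc)
  pr <- ridge_fit_predict(pan$panel, pb, min_lines = 20, seed = 3)
  # permute panel genes and pseudobulk genes independently
  pan2 <- pan
  gperm <- withr::with_seed(9, sample(nrow(pan$panel$line_expression)))
  pan2$panel$line_expression <- pan$panel$line_expression[gperm, ]
  pb2 <- pb
  pperm <- withr::with_seed(10, sample(nrow(pb$profiles)))
  pb2$profiles <- pb$profiles[pperm, ]
  pr2 <- ridge_fit_predict(pan2$panel, pb2, min_lines = 20, seed = 3)
  # glmnet's coordinate descent is order-sensitive at its convergence
  # tolerance; predictions agree to well below any decision threshold
  expect_lt(max(abs(pr2 - pr)), 0.02)
})
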