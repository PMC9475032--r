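# Readers, QC filtering, log normalization, clustering contract.

make_counts <- function(m, meta = NULL) {
  count_matrix(m, rownames(m), colnames(m), meta)
}

test_that("read_counts detects dimension mismatches and explicit zeros", {
  m <- withr::with_seed(1, matrix(rpois(60, 2), 10, 6))
  dimnames(m) <- list(c(sprintf("G%02d", 1:8), "MT-1", "MT-2"),
                      sprintf("c%d", 1:6))
  dir <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  back <- read_counts(dir)
  expect_equal(as.matrix(back$values), m, ignore_attr = FALSE,
               tolerance = 0)  # readMM yields doubles; values must agree

  writeLines(rownames(m)[-1], file.path(dir, "genes.tsv"))
  expect_error(read_counts(dir), "genes.tsv has 9")
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  file.remove(file.path(dir, "barcodes.tsv"))
  expect_error(read_counts(dir), "missing file")

  # explicit zero entries parse to the same dense matrix
  dir2 <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 3", "1 1 5", "2 1 0", "2 2 7"),
             file.path(dir2, "matrix.mtx"))
  writeLines(c("a", "b"), file.path(dir2, "genes.tsv"))
  writeLines(c("x", "y"), file.path(dir2, "barcodes.tsv"))
  expect_identical(as.matrix(read_counts(dir2)$values),
                   matrix(c(5, 0, 0, 7), 2, dimnames = list(c("a", "b"),
                                                            c("x", "y"))))
})

test_that("qc_filter applies the platform thresholds with strict bounds", {
  # cells engineered against the STRT preset (1000, 10000, 0.20)
  n_genes <- 1500
  gene_ids <- c(sprintf("G%04d", seq_len(n_genes - 1)), "MT-1")
  build_cell <- function(detected, total, mito_frac) {
    v <- numeric(n_genes)
    mito <- round(total * mito_frac)
    body <- total - mito
    v[seq_len(detected - 1)] <- c(rep(1, detected - 2),
                                  body - (detected - 2))
    v[n_genes] <- mito
    v
  }
  m <- cbind(keep = build_cell(1200, 12000, 0.15),
             low_umi = build_cell(1200, 9999, 0.15),
             low_genes = build_cell(900, 12000, 0.15),
             high_mito = build_cell(1200, 12000, 0.25))
  rownames(m) <- gene_ids
  cm <- make_counts(m)
  kept <- qc_filter(cm, qc_thresholds(preset = "strt"))
  expect_identical(kept$cell_ids, "keep")

  # boundary: exactly 10,000 transcripts is excluded ("more than")
  m2 <- cbind(at = build_cell(1200, 10000, 0.15),
              above = build_cell(1200, 10001, 0.15))
  rownames(m2) <- gene_ids
  expect_identical(qc_filter(make_counts(m2),
                             qc_thresholds(preset = "strt"))$cell_ids,
                   "above")

  # 10x preset boundary case: 501 genes, 1001 UMIs, 49% mito retained
  m3 <- cbind(edge = build_cell(501, 1001, 0.49))
  rownames(m3) <- gene_ids
  expect_identical(qc_filter(make_counts(m3),
                             qc_thresholds(preset = "tenx"))$cell_ids, "edge")

  # identity thresholds keep everything, order preserved
  all_kept <- qc_filter(cm, qc_thresholds(0, 0, 1))
  expect_identical(all_kept$cell_ids, colnames(m))
  expect_error(qc_filter(cm, qc_thresholds(1e6, 0, 1)), "all")
})

test_that("qc_filter is idempotent and matches the brute-force predicate", {
  co <- generate_cohort(cohort_config(n_cells_per_patient = 80,
                                      n_genes = 600, program_size = 20,
                                      library_size_mean = 5000, seed = 5))
  thr <- qc_thresholds(preset = "tenx")
  once <- qc_filter(co$counts, thr)
  twice <- qc_filter(once, thr)
  expect_identical(twice$cell_ids, once$cell_ids)

  m <- as.matrix(co$counts$values)
  mito <- startsWith(rownames(m), "MT-")
  brute <- sum(vapply(seq_len(ncol(m)), function(j) {
    sum(m[, j] > 0) > 500 && sum(m[, j]) > 1000 &&
      sum(m[mito, j]) / sum(m[, j]) < 0.5
  }, logical(1)))
  expect_identical(ncol(once$values), brute)
})

test_that("normalize_log matches direct arithmetic and conserves totals", {
  m <- matrix(c(1, 2, 7,
                0, 5, 0), 3, 2,
              dimnames = list(c("a", "b", "c"), c("c1", "c2")))
  ex <- normalize_log(make_counts(m), scale_factor = 100)
  expect_equal(ex$values[, "c1"], log(c(a = 11, b = 21, c = 71)))
  # single expressed gene at scale 1e4
  ex2 <- normalize_log(make_counts(m), scale_factor = 1e4)
  expect_equal(unname(ex2$values["b", "c2"]), log(1 + 1e4))
  expect_equal(unname(ex2$values[c("a", "c"), "c2"]), c(0, 0))
  # scale invariance: doubling counts leaves the normalized vector fixed
  ex3 <- normalize_log(make_counts(2 * m), scale_factor = 100)
  expect_equal(ex3$values, ex$values)
  # conservation: sum(expm1(values)) per cell equals the scale factor
  co <- generate_cohort(cohort_config(n_cells_per_patient = 40,
                                      n_genes = 300, program_size = 10,
                                      seed = 2))
  exb <- normalize_log(co$counts)
  expect_equal(colSums(expm1(exb$values)),
               rep(1e4, ncol(exb$values)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # zero-total cell errors
  mz <- m; mz[, 2] <- 0
  expect_error(normalize_log(make_counts(mz)), "zero total")
})

test_that("cluster_cells recovers planted blobs and degenerates safely", {
  blob <- function(center, n, seed) withr::with_seed(seed,
    matrix(rnorm(50 * n, center, 0.2), 50, n))
  m <- cbind(blob(0, 100, 1), blob(5, 100, 2))
  dimnames(m) <- list(sprintf("g%02d", 1:50), sprintf("c%03d", 1:200))
  ex <- as_expr(m)
  cl <- cluster_cells(ex, n_neighbors = 10, seed = 4)
  expect_identical(length(cl), 200L)
  expect_equal(adjusted_rand(cl, rep(1:2, each = 100)), 1)
  # determinism
  expect_identical(cl, cluster_cells(ex, n_neighbors = 10, seed = 4))
  # identical cells collapse to one community
  flat <- as_expr(matrix(1, 20, 30,
                         dimnames = list(sprintf("g%d", 1:20),
                                         sprintf("c%d", 1:30))))
  expect_identical(unname(unique(cluster_cells(flat, n_neighbors = 5))), 1L)
  expect_error(cluster_cells(flat, n_neighbors = 50), "at least")
})
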