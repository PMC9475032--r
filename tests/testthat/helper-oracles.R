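# Independent brute-force oracles used to check the package's
# implementations. Written as plain loops on purpose: they must stay
# independent of the vectorized code paths they verify.

oracle_msd <- function(m, baseline = 1) {
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    s <- 0
    for (j in seq_len(ncol(m))) s <- s + (m[i, j] - baseline)^2
    out[i] <- s / ncol(m)
  }
  out
}

oracle_moving_average <- function(x, window) {
  n <- length(x)
  h <- (window - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1, n - i)
    out[i] <- mean(x[(i - hi):(i + hi)])
  }
  out
}

# linear interpolation between order statistics (R type-7 definition,
# written out by hand)
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Wilcoxon rank-sum statistic by pair counting (W as reported by
# wilcox.test: number of (a, b) pairs with a > b, ties counted 1/2)
oracle_rank_sum <- function(a, b) {
  w <- 0
  for (x in a) for (y in b) w <- w + (x > y) + 0.5 * (x == y)
  w
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    v <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- v
    prev <- v
  }
  adj
}

oracle_bonferroni <- function(p) pmin(1, p * length(p))

# control-bin module score, re-derived step by step with loops
oracle_module_score <- function(vals, gene_set, n_bins, n_ctrl, seed) {
  sig <- intersect(gene_set, rownames(vals))
  avg <- apply(vals, 1, mean)
  nb <- min(n_bins, length(unique(avg)))
  bin <- if (nb < 2) rep(1L, nrow(vals)) else
    as.integer(cut(rank(avg, ties.method = "first"), breaks = nb,
                   labels = FALSE, include.lowest = TRUE))
  names(bin) <- rownames(vals)
  ctrl <- withr::with_seed(as.integer(seed), {
    drawn <- character(0)
    for (g in sig) {
      pool <- names(bin)[bin == bin[[g]]]
      drawn <- c(drawn, pool[sample.int(length(pool), n_ctrl, replace = TRUE)])
    }
    drawn
  })
  out <- numeric(ncol(vals))
  for (cidx in seq_len(ncol(vals))) {
    out[cidx] <- mean(vals[sig, cidx]) - mean(vals[ctrl, cidx])
  }
  names(out) <- colnames(vals)
  out
}

# weighted-ECDF single-sample enrichment for one cell, by hand
oracle_ssgsea_cell <- function(x, in_set, alpha) {
  n <- length(x)
  ord <- order(-x, seq_along(x))
  r <- rank(x, ties.method = "first")
  w <- ifelse(in_set[ord], r[ord]^alpha, 0)
  cdf_in <- cumsum(w) / sum(w)
  cdf_out <- cumsum(!in_set[ord]) / sum(!in_set)
  sum(cdf_in - cdf_out)
}

# adjusted Rand index for partition comparison
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_i * sum_j / n
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# greedy one-to-one matching of meta-programs to planted gene sets
match_programs <- function(meta_programs, truth_sets) {
  jmat <- sapply(truth_sets, function(gs)
    sapply(meta_programs, function(m) jaccard(m$consensus_genes, gs)))
  jmat <- matrix(jmat, nrow = length(meta_programs))
  colnames(jmat) <- names(truth_sets)
  res <- rep(NA_real_, length(truth_sets))
  names(res) <- names(truth_sets)
  used <- rep(FALSE, nrow(jmat))
  for (it in seq_along(truth_sets)) {
    j2 <- jmat
    j2[used, ] <- -1
    j2[, !is.na(res)] <- -1
    idx <- which(j2 == max(j2), arr.ind = TRUE)[1, ]
    res[idx[2]] <- jmat[idx[1], idx[2]]
    used[idx[1]] <- TRUE
  }
  res
}

# small expression_matrix from a bare matrix, for unit tests
as_expr <- function(m, meta = NULL, scale_factor = 1e4) {
  structure(list(values = m, gene_ids = rownames(m), cell_ids = colnames(m),
                 cell_meta = meta, scale_factor = scale_factor),
            class = "expression_matrix")
}

# named matrix with reproducible random values
rmat <- function(nr, nc, seed = 1, gen = function(n) runif(n)) {
  withr::with_seed(seed, {
    m <- matrix(gen(nr * nc), nr, nc)
    dimnames(m) <- list(sprintf("g%03d", seq_len(nr)),
                        sprintf("c%03d", seq_len(nc)))
    m
  })
}
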