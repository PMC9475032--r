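# Synthetic cohorts and cell-line drug panels with planted ground truth.
#
# The generator emulates the statistical structure the downstream stages
# assume: multi-patient UMI counts with cell-type marker blocks,
# mitochondrial genes (prefix "MT-"), chromosome-level copy-number gains in
# malignant cells, four overlapping malignant expression programs laid out
# along a one-dimensional progression axis, and a cell-line panel whose
# drug response depends linearly on planted target-gene expression.

PROGRAM_NAMES <- c("cell_cycle", "mitochondria", "metabolism", "EMT")

#' Configuration for a synthetic cohort
#'
#' Defaults describe a small two-patient desk-scale cohort: 300 cells per
#' patient, 2,000 genes on 10 autosome-like chromosomes, 10% malignant
#' cells, and two 1.5x chromosome gains planted in every patient's
#' malignant cells.
#'
#' @param n_patients number of patients.
#' @param n_cells_per_patient cells per patient.
#' @param n_genes total genes (including mitochondrial genes).
#' @param n_chromosomes number of nuclear chromosomes genes are spread over.
#' @param malignant_fraction fraction of each patient's cells that are
#'   malignant, in `[0, 1]`.
#' @param cnv_events data.frame with columns `patient`, `chromosome`,
#'   `multiplier` (> 0); each row multiplies the expression rates of all
#'   genes on that chromosome in that patient's malignant cells. `NULL`
#'   plants two 1.5x gains (chr1 and chr2) per patient; use a zero-row
#'   data.frame for a copy-neutral null cohort.
#' @param program_gene_sets named list of four pairwise-disjoint gene-index
#'   or gene-name vectors (cell_cycle, mitochondria, metabolism, EMT);
#'   `NULL` assigns four disjoint blocks of `program_size` genes.
#' @param program_size genes per planted program when defaults are used.
#' @param program_loading log-scale effect size applied as
#'   `exp(weight * loading)` to a malignant cell's program genes. 0 gives a
#'   programme-free null.
#' @param library_size_mean mean UMI count per cell.
#' @param dispersion negative-binomial dispersion (1/size); gamma-Poisson
#'   overdispersion shared by all genes.
#' @param mito_gene_fraction fraction of genes that are mitochondrial
#'   ("MT-" prefix, chromosome "MT").
#' @param mito_expr_fraction fraction of the expression budget carried by
#'   mitochondrial genes (sets the typical mito percentage seen in QC).
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the config.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 2L,
                          n_cells_per_patient = 300L,
                          n_genes = 2000L,
                          n_chromosomes = 10L,
                          malignant_fraction = 0.1,
                          cnv_events = NULL,
                          program_gene_sets = NULL,
                          program_size = 50L,
                          program_loading = 0.8,
                          library_size_mean = 20000L,
                          dispersion = 0.3,
                          mito_gene_fraction = 0.01,
                          mito_expr_fraction = 0.08,
                          seed = 1L) {
  n_patients <- assert_count(n_patients, "n_patients", 1L)
  n_cells_per_patient <- assert_count(n_cells_per_patient,
                                      "n_cells_per_patient", 2L)
  n_genes <- assert_count(n_genes, "n_genes", 10L)
  n_chromosomes <- assert_count(n_chromosomes, "n_chromosomes", 1L)
  assert_scalar_num(malignant_fraction, "malignant_fraction", 0, 1)
  assert_scalar_num(program_loading, "program_loading", 0)
  assert_scalar_num(library_size_mean, "library_size_mean", 1)
  assert_scalar_num(dispersion, "dispersion")
  if (dispersion <= 0) stopf("'dispersion' must be positive")
  assert_scalar_num(mito_gene_fraction, "mito_gene_fraction", 0, 1)
  assert_scalar_num(mito_expr_fraction, "mito_expr_fraction", 0, 1)
  program_size <- assert_count(program_size, "program_size", 1L)

  n_mito <- max(1L, round(mito_gene_fraction * n_genes))
  n_nuclear <- n_genes - n_mito
  if (n_nuclear < 2L * n_chromosomes)
    stopf("chromosomes would have < 2 genes: %d nuclear genes over %d chromosomes",
          n_nuclear, n_chromosomes)

  patients <- sprintf("P%d", seq_len(n_patients))
  if (is.null(cnv_events)) {
    cnv_events <- data.frame(
      patient = rep(patients, each = 2L),
      chromosome = rep(c("chr1", "chr2"), n_patients),
      multiplier = 1.5)
  }
  cnv_events <- as.data.frame(cnv_events)
  if (nrow(cnv_events)) {
    if (!all(c("patient", "chromosome", "multiplier") %in%
             colnames(cnv_events)))
      stopf("cnv_events needs columns patient, chromosome, multiplier")
    if (any(cnv_events$multiplier <= 0))
      stopf("CNV multipliers must be positive")
    if (!all(cnv_events$patient %in% patients))
      stopf("cnv_events reference unknown patients")
  }

  if (is.null(program_gene_sets)) {
    if (4L * program_size > n_nuclear)
      stopf("program gene sets (%d genes) exceed available genes (%d)",
            4L * program_size, n_nuclear)
    # spread programs over different chromosomes so a program is not
    # confounded with a single CNV block
    idx <- seq(1L, n_nuclear, length.out = 4L * program_size)
    idx <- unique(round(idx))
    while (length(idx) < 4L * program_size)
      idx <- sort(unique(c(idx, sample.int(n_nuclear, 1L))))
    program_gene_sets <- split(idx, rep(PROGRAM_NAMES, length.out = length(idx)))
    program_gene_sets <- program_gene_sets[PROGRAM_NAMES]
  }
  if (length(program_gene_sets) != 4L)
    stopf("exactly four program gene sets are required")
  if (is.null(names(program_gene_sets)) ||
      any(!nzchar(names(program_gene_sets))))
    names(program_gene_sets) <- PROGRAM_NAMES
  all_pg <- unlist(program_gene_sets)
  if (anyDuplicated(all_pg))
    stopf("program gene sets must be pairwise disjoint")
  if (length(all_pg) > n_genes)
    stopf("program gene sets exceed n_genes")

  structure(list(
    n_patients = n_patients, n_cells_per_patient = n_cells_per_patient,
    n_genes = n_genes, n_chromosomes = n_chromosomes,
    malignant_fraction = malignant_fraction, cnv_events = cnv_events,
    program_gene_sets = program_gene_sets, program_loading = program_loading,
    library_size_mean = library_size_mean, dispersion = dispersion,
    mito_gene_fraction = mito_gene_fraction,
    mito_expr_fraction = mito_expr_fraction,
    n_mito = n_mito, patients = patients, seed = as.integer(seed)),
    class = "cohort_config")
}

# Gene universe for a config: nuclear genes G0001.. on chr1..chrN (block
# layout, increasing 1-based starts) followed by MT- genes on chromosome MT.
cohort_genes <- function(config) {
  n_nuclear <- config$n_genes - config$n_mito
  chrom <- sprintf("chr%d",
                   sort(rep_len(seq_len(config$n_chromosomes), n_nuclear)))
  start <- integer(n_nuclear)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- seq_along(i) * 100000L
  }
  data.frame(
    gene = c(sprintf("G%04d", seq_len(n_nuclear)),
             sprintf("MT-%d", seq_len(config$n_mito))),
    chromosome = c(chrom, rep("MT", config$n_mito)),
    start = c(start, seq_len(config$n_mito) * 1000L),
    stringsAsFactors = FALSE)
}

# Baseline relative expression of the config's gene universe: lognormal
# abundances with the mitochondrial budget pinned. A deterministic
# function of the config, shared by the cohort and any cell-line panel
# generated from the same config (relative gene abundance is a property
# of the transcriptome, not of one dataset).
cohort_base_rates <- function(config) {
  genes <- cohort_genes(config)
  mito <- genes$chromosome == "MT"
  with_seed_(derive_seed(config$seed, 17L), {
    base <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1)
    if (any(mito) && config$mito_expr_fraction > 0) {
      base[mito] <- base[mito] / sum(base[mito]) *
        config$mito_expr_fraction / (1 - config$mito_expr_fraction) *
        sum(base[!mito])
    }
    stats::setNames(base, genes$gene)
  })
}

# Piecewise-linear simplex path along latent progression t in [0,1]:
# pure cell-cycle at t=0, pure mitochondria at t=1/3, then a branch into
# metabolism or EMT reaching purity at t=1.
program_weights_on_path <- function(t, branch) {
  w <- matrix(0, length(t), 4L, dimnames = list(NULL, PROGRAM_NAMES))
  early <- t <= 1 / 3
  w[early, "cell_cycle"] <- 1 - 3 * t[early]
  w[early, "mitochondria"] <- 3 * t[early]
  s <- (t[!early] - 1 / 3) / (2 / 3)
  w[!early, "mitochondria"] <- 1 - s
  w[cbind(which(!early), 2L + branch[!early])] <- s
  w
}

# Gamma-Poisson (negative binomial) draw around a genes x cells rate matrix.
draw_nb_counts <- function(mu, dispersion) {
  n <- length(mu)
  counts <- stats::rnbinom(n, mu = as.vector(mu), size = 1 / dispersion)
  matrix(counts, nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Generate a synthetic multi-patient cohort
#'
#' Draws UMI counts from a gamma-Poisson model around cell-type x gene base
#' rates. Malignant cells additionally carry their patient's planted
#' chromosome-level copy-number multipliers and program-weighted
#' `exp(weight * loading)` boosts on the four planted program gene sets,
#' with weights following a latent progression path
#' (cell cycle -> mitochondria -> metabolism | EMT).
#'
#' @param config a [cohort_config()].
#' @return list with elements `counts` ([count_matrix()]), `positions`
#'   (data.frame gene/chromosome/start) and `truth` (per-cell class, cell
#'   type, tissue, latent progression, program weight matrix, and the
#'   planted program gene sets / CNV events).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  genes <- cohort_genes(config)
  base_shared <- cohort_base_rates(config)
  with_seed_(config$seed, {
    n_genes <- config$n_genes
    n_cells <- config$n_patients * config$n_cells_per_patient
    mito <- genes$chromosome == "MT"
    base <- base_shared

    # three normal epithelial-like cell types with marker blocks, plus a
    # malignant marker block (uniformly upregulated tumor markers)
    normal_types <- c("enterocyte", "goblet", "progenitor")
    free <- setdiff(which(!mito), unlist(config$program_gene_sets))
    marker_sets <- list()
    n_mark <- min(40L, max(1L, length(free) %/% 8L))
    for (ty in c(normal_types, "malignant_marker")) {
      take <- free[seq_len(n_mark)]
      free <- setdiff(free, take)
      marker_sets[[ty]] <- take
    }

    patient <- rep(config$patients, each = config$n_cells_per_patient)
    n_malig <- round(config$malignant_fraction * config$n_cells_per_patient)
    is_malig <- as.vector(vapply(seq_len(config$n_patients), function(p) {
      v <- rep(FALSE, config$n_cells_per_patient)
      v[seq_len(n_malig)] <- TRUE
      v
    }, logical(config$n_cells_per_patient)))
    # every cell, malignant or not, has an epithelial cell of origin whose
    # marker block it keeps; malignant deviations are layered on top
    cell_type <- sample(normal_types, n_cells, replace = TRUE)
    # adjacent-normal tissue supplies reference cells; the remaining normal
    # epithelium sits inside the tumor sample
    tissue <- ifelse(is_malig, "tumor",
                     sample(c("normal", "tumor"), n_cells, replace = TRUE))

    # latent progression for malignant cells
    prog_t <- rep(NA_real_, n_cells)
    branch <- rep(NA_integer_, n_cells)
    prog_t[is_malig] <- stats::runif(sum(is_malig))
    branch[is_malig] <- sample(1:2, sum(is_malig), replace = TRUE)
    weights <- matrix(0, n_cells, 4L, dimnames = list(NULL, PROGRAM_NAMES))
    if (any(is_malig))
      weights[is_malig, ] <- program_weights_on_path(prog_t[is_malig],
                                                     branch[is_malig])

    # per-cell rate matrix
    rate <- matrix(base, n_genes, n_cells)
    for (ty in normal_types) {
      cols <- which(cell_type == ty)
      rate[marker_sets[[ty]], cols] <- rate[marker_sets[[ty]], cols] * 3
    }
    if (any(is_malig)) {
      mcols <- which(is_malig)
      # uniformly upregulated malignant markers; tied to the loading so a
      # zero-loading null config has identically distributed classes
      rate[marker_sets$malignant_marker, mcols] <-
        rate[marker_sets$malignant_marker, mcols] * exp(config$program_loading)
      for (k in seq_len(4L)) {
        gs <- config$program_gene_sets[[k]]
        gi <- if (is.character(gs)) match(gs, genes$gene) else gs
        boost <- exp(outer(rep(config$program_loading, length(gi)),
                           weights[mcols, k]))
        rate[gi, mcols] <- rate[gi, mcols] * boost
      }
      for (i in seq_len(nrow(config$cnv_events))) {
        ev <- config$cnv_events[i, ]
        gi <- which(genes$chromosome == ev$chromosome)
        cols <- which(is_malig & patient == ev$patient)
        if (length(gi) && length(cols))
          rate[gi, cols] <- rate[gi, cols] * ev$multiplier
      }
    }

    # library sizes and expected counts
    lib <- stats::rlnorm(n_cells, meanlog = log(config$library_size_mean),
                         sdlog = 0.1)
    rate <- sweep(rate, 2L, colSums(rate), "/")
    mu <- sweep(rate, 2L, lib, "*")
    counts <- draw_nb_counts(mu, config$dispersion)

    cell_ids <- sprintf("%s_C%04d", patient,
                        as.vector(replicate(config$n_patients,
                                            seq_len(config$n_cells_per_patient))))
    rownames(counts) <- genes$gene
    colnames(counts) <- cell_ids
    meta <- data.frame(patient = patient, tissue = tissue,
                       platform = "STRT", stringsAsFactors = FALSE)

    program_gene_names <- lapply(config$program_gene_sets, function(gs)
      if (is.character(gs)) gs else genes$gene[gs])

    truth <- list(
      cells = data.frame(cell_id = cell_ids, patient = patient,
                         class = ifelse(is_malig, "malignant", "normal"),
                         cell_type = cell_type, tissue = tissue,
                         progression = prog_t, stringsAsFactors = FALSE),
      program_weights = `rownames<-`(weights, cell_ids),
      program_gene_sets = program_gene_names,
      marker_sets = lapply(marker_sets, function(i) genes$gene[i]),
      cnv_events = config$cnv_events)

    list(counts = count_matrix(counts, genes$gene, cell_ids, meta),
         positions = genes, truth = truth)
  })
}

#' Generate a synthetic cell-line drug panel
#'
#' Cell-line expression is drawn with the same gamma-Poisson model as
#' [generate_cohort()] (no CNVs); each line carries four independent
#' program activities drawn uniformly on `[0, 1]` (lines are not
#' constrained to the cohort's progression simplex), so target-gene
#' expression varies independently across lines. The response of a planted-sensitive drug is
#' `AUC = intercept + beta * mean(log-normalized target-gene expression) +
#' N(0, noise_sd)` with `beta < 0` (higher target expression, lower AUC,
#' more sensitive); non-planted drugs have `beta = 0`.
#'
#' @param n_lines number of cell lines.
#' @param n_genes number of genes reported in the panel. Lines are drawn
#'   over the full gene universe of `config` (a cell line expresses the
#'   whole transcriptome, and normalization totals must match the cohort's)
#'   and the panel reports an `n_genes` subset: the planted program genes
#'   plus an evenly spaced fill.
#' @param drugs character vector of drug names.
#' @param planted_sensitive subset of `drugs` given a true negative `beta`.
#' @param effect_size the (negative) `beta` for planted drugs.
#' @param noise_sd Gaussian response noise (>= 0).
#' @param seed integer seed.
#' @param config a [cohort_config()] supplying the gene universe and the
#'   program gene sets the drug targets overlap.
#' @param target_genes optional named list (per planted drug) of target
#'   gene names; default: 10 genes from a planted program, cycling over
#'   programs.
#' @param intercept baseline AUC for a line with zero target expression
#'   (default 1.5, which keeps responses positive over the realistic
#'   range of target expression at the default effect size).
#' @return list with `panel` (list: `line_expression` genes x lines
#'   log-normalized matrix, `response` long data.frame drug/line/auc,
#'   `source` label) and `truth` (per-drug sensitivity flag, beta, targets).
#' @export
generate_drug_panel <- function(n_lines, n_genes, drugs, planted_sensitive,
                                effect_size = -1, noise_sd = 0.02,
                                seed = 1L, config = cohort_config(),
                                target_genes = NULL, intercept = 2.1) {
  n_lines <- assert_count(n_lines, "n_lines", 2L)
  n_genes <- assert_count(n_genes, "n_genes", 10L)
  if (noise_sd < 0) stopf("'noise_sd' must be >= 0")
  if (!all(planted_sensitive %in% drugs))
    stopf("planted_sensitive must be a subset of drugs")
  genes <- cohort_genes(config)
  if (n_genes > nrow(genes)) stopf("n_genes exceeds the config gene universe")
  program_gene_names <- lapply(config$program_gene_sets, function(gs)
    if (is.character(gs)) gs else genes$gene[gs])
  # reported universe: program genes plus an evenly spaced fill
  prog_all <- intersect(unlist(program_gene_names), genes$gene)
  if (length(prog_all) > n_genes)
    stopf("n_genes too small to cover the planted program genes")
  fill <- setdiff(genes$gene[unique(round(seq(1L, nrow(genes),
                                              length.out = n_genes)))],
                  prog_all)
  gene_ids <- sort(c(prog_all, fill[seq_len(n_genes - length(prog_all))]))

  base_abund <- cohort_base_rates(config)
  if (is.null(target_genes)) {
    # broad target sets: a staggered window of half of each program's
    # genes per drug. Averaging the readout over many genes of all four
    # programs makes a drug's target expression track overall malignant
    # program activity; small single-program readouts drown in the
    # progression-mix heterogeneity of tumor pseudo-bulks.
    target_genes <- list()
    for (i in seq_along(planted_sensitive)) {
      tg <- unlist(lapply(program_gene_names, function(prog) {
        avail <- intersect(prog, gene_ids)
        if (length(avail) < 3L)
          stopf("program genes do not intersect the panel gene universe")
        width <- max(3L, length(avail) %/% 2L)
        idx <- (((i - 1L) * 5L) + seq_len(width) - 1L) %% length(avail) + 1L
        avail[idx]
      }))
      target_genes[[planted_sensitive[i]]] <- unique(unname(tg))
    }
  }
  missing_t <- setdiff(planted_sensitive, names(target_genes))
  if (length(missing_t))
    stopf("no target genes for planted drug(s): %s",
          paste(missing_t, collapse = ", "))

  with_seed_(seed, {
    n_univ <- nrow(genes)
    base <- unname(base_abund)  # abundance shared with the cohort
    # independent program activities per line
    w <- matrix(stats::runif(n_lines * 4L), n_lines, 4L)
    rate <- matrix(base, n_univ, n_lines)
    for (k in seq_len(4L)) {
      gi <- which(genes$gene %in% program_gene_names[[k]])
      if (length(gi))
        rate[gi, ] <- rate[gi, ] *
          exp(outer(rep(config$program_loading, length(gi)), w[, k]))
    }
    lib <- stats::rlnorm(n_lines, log(config$library_size_mean), 0.1)
    rate <- sweep(rate, 2L, colSums(rate), "/")
    counts <- draw_nb_counts(sweep(rate, 2L, lib, "*"), config$dispersion)
    line_ids <- sprintf("CL%03d", seq_len(n_lines))
    dimnames(counts) <- list(genes$gene, line_ids)
    # log-normalized over the full transcriptome (same convention as
    # normalize_log), then restricted to the reported panel universe
    expr <- log1p(sweep(counts, 2L, colSums(counts), "/") * 1e4)
    expr <- expr[gene_ids, , drop = FALSE]

    beta <- stats::setNames(rep(0, length(drugs)), drugs)
    beta[planted_sensitive] <- effect_size
    resp <- do.call(rbind, lapply(drugs, function(d) {
      mt <- if (d %in% names(target_genes))
        colMeans(expr[target_genes[[d]], , drop = FALSE]) else rep(0, n_lines)
      data.frame(drug = d, line = line_ids,
                 auc = intercept + beta[[d]] * mt +
                   stats::rnorm(n_lines, 0, noise_sd),
                 stringsAsFactors = FALSE)
    }))
    rownames(resp) <- NULL

    list(panel = list(line_expression = expr, response = resp,
                      source = "synthetic"),
         truth = list(sensitive = drugs %in% planted_sensitive,
                      drugs = drugs, beta = beta,
                      target_genes = target_genes))
  })
}

#' Write a synthetic cohort (and optional drug panel) to plain-text files
#'
#' Produces the standard on-disk layout the readers expect: Matrix Market
#' `matrix.mtx` with `genes.tsv`/`barcodes.tsv` sidecars, `cell_meta.tsv`,
#' `gene_positions.tsv`, a `programs.gmt` of the planted program gene sets,
#' and (if a panel is given) `panel_expression.csv` plus long-format
#' `panel_auc.csv`. Round-trips losslessly through [read_counts()].
#'
#' @param cohort result of [generate_cohort()].
#' @param directory output directory (created if needed).
#' @param panel optional result of [generate_drug_panel()].
#' @return invisibly, the vector of files written.
#' @export
write_fixture <- function(cohort, directory, panel = NULL) {
  counts <- cohort$counts
  if (!inherits(counts, "count_matrix")) stopf("cohort$counts is not a count_matrix")
  if (nrow(counts$values) == 0L || ncol(counts$values) == 0L)
    stopf("refusing to write an empty cohort")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stopf("cannot create directory '%s'", directory)
  p <- function(f) file.path(directory, f)

  Matrix::writeMM(counts$values, p("matrix.mtx"))
  writeLines(counts$gene_ids, p("genes.tsv"))
  writeLines(counts$cell_ids, p("barcodes.tsv"))
  utils::write.table(cbind(cell_id = counts$cell_ids, counts$cell_meta),
                     p("cell_meta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$positions, p("gene_positions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(cohort$truth$program_gene_sets, p("programs.gmt"))
  utils::write.table(cohort$truth$cells, p("truth_cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c("matrix.mtx", "genes.tsv", "barcodes.tsv", "cell_meta.tsv",
             "gene_positions.tsv", "programs.gmt", "truth_cells.tsv")
  if (!is.null(panel)) {
    pe <- panel$panel$line_expression
    utils::write.csv(data.frame(gene = rownames(pe), pe, check.names = FALSE),
                     p("panel_expression.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(panel$panel$response, p("panel_auc.csv"),
                     row.names = FALSE, quote = FALSE)
    files <- c(files, "panel_expression.csv", "panel_auc.csv")
  }
  invisible(file.path(directory, files))
}
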