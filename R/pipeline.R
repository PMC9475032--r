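# End-to-end orchestration: stage ordering, provenance, reproducibility.

#' Default pipeline configuration
#'
#' Returns the full nested parameter list the pipeline understands; any
#' sub-list can be overridden by the caller or a YAML file. A single
#' global `seed` is fanned out deterministically to stage-local seeds.
#'
#' @param out_dir output directory.
#' @param input_dir optional fixture directory (as written by
#'   [write_fixture()]); when `NULL`, a synthetic cohort is simulated.
#' @param seed global integer seed.
#' @return nested configuration list.
#' @export
default_config <- function(out_dir = "scmalig_out", input_dir = NULL,
                           seed = 1L) {
  list(
    out_dir = out_dir,
    input_dir = input_dir,
    seed = as.integer(seed),
    stages = c("simulate", "qc", "normalize", "cluster", "cnv", "programs",
               "score", "edges", "drugpred"),
    cohort = list(),            # overrides for cohort_config()
    qc = list(preset = "tenx"),
    normalize = list(scale_factor = 1e4),
    cluster = list(n_neighbors = 15, resolution = 1, n_pcs = 20),
    cnv = list(window = 101, cap = 3, percentile = 90,
               ref_tissue = "normal", dominance = 0.5),
    programs = list(n_components = 6, n_genes_per_pole = 50,
                    n_factors = 6, n_genes = 50, k = 12, min_support = 2,
                    use_nmf = TRUE),
    score = list(gmt = NULL, method = "module"),
    edges = list(pairs_csv = NULL, threshold = 0.2),
    drugpred = list(expression_csv = NULL, auc_csv = NULL,
                    n_groups = 50, p_cut = 0.05, log2fc_cut = -0.1,
                    cor_cut = -0.5, min_lines = 20)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Values in the file override [default_config()] defaults, recursively.
#'
#' @param path YAML file.
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' not found", path)
  user <- yaml::read_yaml(path)
  modify_defaults(default_config(), user)
}

modify_defaults <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- modify_defaults(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' Reports all range and existence violations at once rather than failing
#' on the first.
#'
#' @param config nested configuration list.
#' @return character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character()
  bad <- function(fmt, ...) errs <<- c(errs, sprintf(fmt, ...))
  num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

  if (!num(config$seed)) bad("seed must be a single integer")
  p <- config$cnv$percentile
  if (!num(p) || p <= 0 || p > 100)
    bad("cnv$percentile must be in (0, 100], got %s", format(p))
  w <- config$cnv$window
  if (!num(w) || w < 3 || w %% 2 == 0)
    bad("cnv$window must be an odd count >= 3, got %s", format(w))
  if (!num(config$cnv$cap) || config$cnv$cap <= 0)
    bad("cnv$cap must be positive")
  d <- config$cnv$dominance
  if (!num(d) || d < 0 || d > 1) bad("cnv$dominance must be in [0, 1]")
  if (!num(config$edges$threshold) || config$edges$threshold < 0 ||
      config$edges$threshold > 1)
    bad("edges$threshold must be in [0, 1]")
  if (!num(config$drugpred$n_groups) || config$drugpred$n_groups < 1)
    bad("drugpred$n_groups must be a positive count")
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir))
    bad("input_dir '%s' does not exist", config$input_dir)
  for (f in c("gmt" = config$score$gmt,
              "pairs_csv" = config$edges$pairs_csv,
              "expression_csv" = config$drugpred$expression_csv,
              "auc_csv" = config$drugpred$auc_csv))
    if (!is.null(f) && !file.exists(f)) bad("file '%s' does not exist", f)
  if ("drugpred" %in% config$stages &&
      xor(is.null(config$drugpred$expression_csv),
          is.null(config$drugpred$auc_csv)))
    bad("drugpred needs both expression_csv and auc_csv (or neither)")
  errs
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline end to end
#'
#' Executes the stages in dependency order (simulate/read, QC,
#' normalization, clustering, CNV and malignant calling, program
#' extraction, gene-set scoring, ligand-receptor edges, drug prediction),
#' writing plain-text outputs under `config$out_dir` and recording
#' parameters, input/output sizes and file checksums per stage. Identical
#' config and seed give byte-identical stage outputs. Optional stages
#' (score, edges, drugpred) are skipped with a message when their inputs
#' are not configured; a failing stage halts with its name, keeping
#' earlier outputs.
#'
#' @param config nested configuration list ([default_config()] or
#'   [read_config()]).
#' @return invisibly, a list with the in-memory stage results and
#'   `record`, the per-stage provenance record (also written as
#'   `run_record.json`).
#' @export
run_pipeline <- function(config = default_config()) {
  errs <- validate_config(config)
  if (length(errs))
    stopf("invalid config:\n  - %s", paste(errs, collapse = "\n  - "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  record <- list()
  results <- list()
  seed <- config$seed
  note <- function(stage, params, files, extra = list()) {
    record[[stage]] <<- c(list(
      stage = stage, parameters = params,
      outputs = as.list(tools::md5sum(files)),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  }
  stage_on <- function(s) s %in% config$stages
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  # --- simulate or read ---------------------------------------------------
  run_stage("simulate", function() {
    if (!is.null(config$input_dir)) {
      results$counts <<- read_counts(config$input_dir)
      results$positions <<- read_gene_positions(
        file.path(config$input_dir, "gene_positions.tsv"))
      note("read_input", list(input_dir = config$input_dir), character())
    } else {
      cc <- do.call(cohort_config,
                    modify_defaults(list(seed = derive_seed(seed, 1L)),
                                    config$cohort))
      cohort <- generate_cohort(cc)
      fx <- file.path(config$out_dir, "fixture")
      files <- write_fixture(cohort, fx)
      results$counts <<- cohort$counts
      results$positions <<- cohort$positions
      results$truth <<- cohort$truth
      note("simulate", cc[setdiff(names(cc), c("cnv_events",
                                               "program_gene_sets"))], files)
    }
  })

  # --- qc + normalize -----------------------------------------------------
  run_stage("qc", function() {
    if (!stage_on("qc")) { results$counts_qc <<- results$counts; return() }
    thr <- do.call(qc_thresholds, config$qc)
    results$counts_qc <<- qc_filter(results$counts, thr)
    f <- write_tsv(qc_stats(results$counts_qc),
                   file.path(config$out_dir, "qc_stats.tsv"))
    note("qc", unclass(thr), f,
         list(cells_in = ncol(results$counts$values),
              cells_out = ncol(results$counts_qc$values)))
  })
  run_stage("normalize", function() {
    results$expr <<- normalize_log(results$counts_qc,
                                   config$normalize$scale_factor)
    note("normalize", config$normalize, character())
  })

  # --- cluster ------------------------------------------------------------
  run_stage("cluster", function() {
    cl <- cluster_cells(results$expr,
                        n_neighbors = config$cluster$n_neighbors,
                        resolution = config$cluster$resolution,
                        n_pcs = config$cluster$n_pcs,
                        seed = derive_seed(seed, 2L))
    results$clusters <<- cl
    f <- write_tsv(data.frame(cell_id = names(cl), cluster = unname(cl)),
                   file.path(config$out_dir, "clusters.tsv"))
    note("cluster", config$cluster, f)
  })

  # --- cnv + malignant call ----------------------------------------------
  run_stage("cnv", function() {
    if (!stage_on("cnv")) return()
    meta <- results$expr$cell_meta
    ref <- results$expr$cell_ids[meta$tissue == config$cnv$ref_tissue]
    if (length(ref) == 0L)
      stopf("no reference cells with tissue '%s'", config$cnv$ref_tissue)
    cnv <- infer_cnv(results$expr, results$positions, ref,
                     window_size = config$cnv$window, cap = config$cnv$cap)
    scores <- msd_score(cnv)
    thr <- malignancy_threshold(scores[ref], config$cnv$percentile)
    call <- call_malignant(scores, thr, results$clusters,
                           dominance = config$cnv$dominance)
    results$cnv <<- cnv
    results$malignancy <<- call
    f <- write_tsv(call, file.path(config$out_dir, "malignancy_calls.tsv"))
    note("cnv", config$cnv, f, list(threshold = unname(thr)))
  })

  # --- programs -----------------------------------------------------------
  run_stage("programs", function() {
    if (!stage_on("programs") || is.null(results$malignancy)) return()
    mal <- results$malignancy$cell_id[results$malignancy$final_call ==
                                        "malignant"]
    if (length(mal) < 10L) { message("too few malignant cells; skipping programs"); return() }
    meta <- results$expr$cell_meta[mal, , drop = FALSE]
    pc <- config$programs
    sigs <- list()
    for (p in unique(meta$patient)) {
      cells <- mal[meta$patient == p]
      if (length(cells) < pc$n_components + 1L) next
      sub <- results$expr
      sub$values <- sub$values[, cells, drop = FALSE]
      sub$cell_ids <- cells
      sigs <- c(sigs, pca_pole_signatures(sub, p, pc$n_components,
                                          pc$n_genes_per_pole))
      if (isTRUE(pc$use_nmf))
        sigs <- c(sigs, nmf_programs(sub, p, pc$n_factors, pc$n_genes,
                                     seed = derive_seed(seed, 3L)))
    }
    if (length(sigs) < 2L) { message("too few signatures; skipping programs"); return() }
    sub <- results$expr
    sub$values <- sub$values[, mal, drop = FALSE]
    sub$cell_ids <- mal
    mps <- cluster_signatures(sigs, sub, k = pc$k, min_support = pc$min_support,
                              seed = derive_seed(seed, 4L))
    shared <- Filter(function(m) m$shared, mps)
    use <- if (length(shared)) shared else mps
    asg <- assign_programs(use, sub, seed = derive_seed(seed, 5L))
    results$meta_programs <<- mps
    results$program_assignment <<- asg
    f1 <- write_gmt(stats::setNames(lapply(mps, `[[`, "consensus_genes"),
                                    vapply(mps, `[[`, "", "name")),
                    file.path(config$out_dir, "meta_programs.gmt"))
    f2 <- write_tsv(data.frame(cell_id = names(asg$labels),
                               program = unname(asg$labels)),
                    file.path(config$out_dir, "program_assignment.tsv"))
    note("programs", pc[c("n_components", "n_genes_per_pole", "n_factors",
                          "k", "min_support", "use_nmf")], c(f1, f2),
         list(n_signatures = length(sigs), n_shared = length(shared)))
  })

  # --- gene-set scoring ---------------------------------------------------
  run_stage("score", function() {
    if (!stage_on("score") || is.null(config$score$gmt)) {
      if (stage_on("score")) message("no GMT configured; skipping score")
      return()
    }
    sets <- read_gmt(config$score$gmt)
    sc <- vapply(names(sets), function(nm) {
      if (identical(config$score$method, "ssgsea"))
        ssgsea_score(results$expr, sets[[nm]])
      else module_score(results$expr, sets[[nm]],
                        seed = derive_seed(seed, 6L))
    }, numeric(ncol(results$expr$values)))
    results$scores <<- sc
    f <- write_tsv(data.frame(cell_id = rownames(sc), sc,
                              check.names = FALSE),
                   file.path(config$out_dir, "gene_set_scores.tsv"))
    note("score", config$score, f)
  })

  # --- ligand-receptor edges ---------------------------------------------
  run_stage("edges", function() {
    if (!stage_on("edges") || is.null(config$edges$pairs_csv)) {
      if (stage_on("edges")) message("no pair table configured; skipping edges")
      return()
    }
    pairs <- read_lr_pairs(config$edges$pairs_csv)
    types <- if (!is.null(results$malignancy))
      stats::setNames(results$malignancy$final_call,
                      results$malignancy$cell_id)
    else stats::setNames(as.character(results$clusters),
                         names(results$clusters))
    edges <- extract_edges(results$expr, types, pairs,
                           config$edges$threshold)
    results$edges <<- edges
    f <- write_tsv(edges, file.path(config$out_dir, "edges.tsv"))
    note("edges", config$edges, f)
  })

  # --- drug prediction ----------------------------------------------------
  run_stage("drugpred", function() {
    dp <- config$drugpred
    if (!stage_on("drugpred") || is.null(dp$expression_csv) ||
        is.null(results$malignancy)) {
      if (stage_on("drugpred")) message("no panel configured; skipping drugpred")
      return()
    }
    panel <- read_drug_panel(dp$expression_csv, dp$auc_csv)
    classes <- stats::setNames(results$malignancy$final_call,
                               results$malignancy$cell_id)
    pb <- pseudobulk_groups(results$expr, classes, dp$n_groups,
                            seed = derive_seed(seed, 7L))
    mal <- names(classes)[classes == "malignant"]
    nrm <- names(classes)[classes == "normal"]
    deg <- deg_test(results$expr, mal, nrm)
    sig <- deg$gene[deg$significant & deg$direction == "up"]
    if (length(sig) < 5L)  # fall back to the strongest upregulated genes
      sig <- utils::head(deg$gene[deg$direction == "up"], 50L)
    if (length(sig) == 0L) stopf("no malignant signature genes found")
    ts <- tumor_score(pb, sig, seed = derive_seed(seed, 8L))
    preds <- ridge_fit_predict(panel, pb, min_lines = dp$min_lines,
                               seed = derive_seed(seed, 9L))
    cand <- filter_candidates(preds, pb$group_class, ts,
                              p_cut = dp$p_cut, log2fc_cut = dp$log2fc_cut,
                              cor_cut = dp$cor_cut)
    results$drug_predictions <<- cand
    f <- write_tsv(cand, file.path(config$out_dir, "drug_predictions.tsv"))
    note("drugpred", dp[c("n_groups", "p_cut", "log2fc_cut", "cor_cut")], f,
         list(n_signature_genes = length(sig)))
  })

  jsonlite::write_json(record, file.path(config$out_dir, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  results$record <- record
  invisible(results)
}
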