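# Plain-text format helpers: GMT gene sets, gene position tables,
# ligand-receptor pair tables, drug panel CSVs.

#' Read a GMT gene-set file
#'
#' @param path GMT file; one set per line: name, description, genes,
#'   tab-separated.
#' @return named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file '%s' not found", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stopf("malformed GMT line: %s", substr(l, 1, 60))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character gene vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("gene sets must be named")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, as.character(sets[[nm]])), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene position table
#'
#' @param path TSV with columns gene, chromosome, start (1-based).
#' @return data.frame with those columns.
#' @export
read_gene_positions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chromosome", "start")
  if (!all(need %in% colnames(tab)))
    stopf("gene position table needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(tab$gene)) stopf("duplicate genes in position table")
  if (any(tab$start <= 0)) stopf("positions must be positive 1-based starts")
  tab[, need]
}

#' Read a ligand-receptor pair table
#'
#' @param path CSV with columns ligand, receptor (extra columns ignored).
#' @return data.frame with unique ligand/receptor rows.
#' @export
read_lr_pairs <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% colnames(tab)))
    stopf("pair table needs columns ligand, receptor")
  tab <- unique(tab[, c("ligand", "receptor")])
  if (any(!nzchar(tab$ligand)) || any(!nzchar(tab$receptor)))
    stopf("empty gene names in pair table")
  tab
}

#' Read a cell-line drug panel from CSV files
#'
#' @param expression_csv genes x lines expression CSV; first column `gene`.
#' @param auc_csv long-format CSV with columns drug, line, auc.
#' @param source label recorded with the panel (e.g. the database name).
#' @return panel list as produced by [generate_drug_panel()]`$panel`.
#' @export
read_drug_panel <- function(expression_csv, auc_csv, source = "panel") {
  ex <- utils::read.csv(expression_csv, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(ex[, -1, drop = FALSE])
  rownames(m) <- ex[[1]]
  resp <- utils::read.csv(auc_csv, stringsAsFactors = FALSE)
  if (!all(c("drug", "line", "auc") %in% colnames(resp)))
    stopf("AUC table needs columns drug, line, auc")
  if (!all(resp$line %in% colnames(m)))
    stopf("response lines missing from the expression matrix")
  list(line_expression = m, response = resp, source = source)
}
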