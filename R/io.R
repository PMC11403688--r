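#' Write / read an expression matrix as TSV
#'
#' The file has genes as rows: first column `gene_id`, one column per
#' sample. [read_expression_tsv()] returns the samples x genes matrix the
#' analysis functions expect.
#'
#' @param x samples x genes matrix.
#' @param path output TSV path.
#' @return `write_expression_tsv` the path invisibly;
#'   `read_expression_tsv` a samples x genes numeric matrix.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = colnames(x), t(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- genes
  storage.mode(m) <- "double"
  m
}

#' Write / read a clinical annotation table as TSV
#'
#' Columns: `sample_id`, `type_2016`, `type_2021`, `os_time`, `os_event`,
#' `idh_status`, `codel_status`, `histology`.
#'
#' @param clinical clinical data frame.
#' @param path TSV path.
#' @return `write_clinical_tsv` the path invisibly; `read_clinical_tsv`
#'   the data frame.
#' @export
write_clinical_tsv <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_tsv
#' @export
read_clinical_tsv <- function(path) {
  req <- c("sample_id", "type_2016", "type_2021", "os_time", "os_event")
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(req %in% names(df)))
    stop("clinical table must have columns ", paste(req, collapse = ", "))
  df
}

#' Write a synthetic cohort to disk
#'
#' Writes `expression.tsv` (genes x samples), `clinical.tsv`, the ground
#' truth as `truth.json` (per-type true edge lists, true connected/hub
#' genes, true Cox coefficients, distorted columns, block table) and the
#' generator configuration as `config.yaml`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "glionet_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  truth <- cohort$truth
  edge_list <- lapply(truth$precisions, function(th) {
    ut <- which(upper.tri(th) & abs(th) > 1e-12, arr.ind = TRUE)
    data.frame(gene_a = rownames(th)[ut[, 1]],
               gene_b = colnames(th)[ut[, 2]], theta = th[ut])
  })
  jsonlite::write_json(
    list(true_edges = edge_list, true_connected = truth$true_connected,
         true_hubs = truth$true_hubs,
         beta_true = as.list(truth$beta_true[truth$beta_true != 0]),
         prognostic_genes = truth$prognostic_genes,
         distorted_cols = truth$distorted_cols,
         block_table = truth$block_table),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a simulation config from YAML
#'
#' @param path YAML file with [sim_config()] fields.
#' @return a validated `glionet_sim_config`.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Serialize a network selection as JSON
#'
#' Writes scheme-level selection results as
#' `type -> {selected, exclusive, hubs}`.
#'
#' @param selection a [network_selection()] result.
#' @param path JSON output path.
#' @return invisibly, the path.
#' @export
write_selection_json <- function(selection, path) {
  obj <- lapply(selection$per_type, function(pt)
    list(selected = pt$selected, exclusive = pt$exclusive, hubs = pt$hubs))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
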