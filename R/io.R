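# Plain-text readers and writers: expression TSV + sample annotation TSV
# (the interchange format between the generator and the analysis
# subcommands), truth JSON, edge-list / centrality / DE tables.

#' Write an ExpressionStudy as expression + annotation TSV
#'
#' Expression: first column `gene`, one column per sample. Annotation:
#' `sample_id`, `condition`, `dataset_id`.
#'
#' @param study an `ExpressionStudy`.
#' @param expr_path output path for the expression table.
#' @param annot_path output path for the sample annotation.
#' @export
write_expression_tsv <- function(study, expr_path, annot_path) {
  stopifnot(inherits(study, "ExpressionStudy"))
  df <- data.frame(gene = study$gene_ids, study$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  an <- data.frame(sample_id = study$sample_ids,
                   condition = unname(study$condition[study$sample_ids]),
                   dataset_id = study$dataset_id,
                   stringsAsFactors = FALSE)
  utils::write.table(an, annot_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(study)
}

#' Read an ExpressionStudy from expression + annotation TSV
#'
#' @param expr_path expression TSV (first column gene id).
#' @param annot_path sample annotation TSV (`sample_id`, `condition`,
#'   optional `dataset_id`).
#' @return an `ExpressionStudy`.
#' @export
read_expression_study <- function(expr_path, annot_path) {
  df <- utils::read.delim(expr_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  an <- utils::read.delim(annot_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "condition") %in% names(an)))
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  missing <- setdiff(colnames(vals), an$sample_id)
  if (length(missing))
    stop("samples without annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  cond <- stats::setNames(an$condition, an$sample_id)[colnames(vals)]
  dataset_id <- if ("dataset_id" %in% names(an)) an$dataset_id[1]
                else "dataset"
  expression_study(vals, unname(cond), dataset_id)
}

#' Write the synthetic ground truth as JSON
#'
#' Records per-condition support pairs, hub genes, cancer-specific hubs
#' and the planted log2 shifts.
#'
#' @param truth a `SyntheticTruth`.
#' @param path output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  payload <- list(
    gene_ids = truth$normal_model$gene_ids,
    normal = list(support = truth$normal_model$support,
                  hub_genes = truth$normal_model$hub_genes),
    cancer = list(support = truth$cancer_model$support,
                  hub_genes = truth$cancer_model$hub_genes),
    de_genes = as.list(truth$de_genes),
    cancer_specific_hubs = truth$cancer_specific_hubs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(truth)
}

#' Write a ranked edge list as TSV
#'
#' @param edges data.frame from [rank_edges()] / [top_k_edges()].
#' @param path output path.
#' @export
write_edges_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges)
}

#' Read an edge list TSV (columns gene_i, gene_j, ...)
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_edges_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_i", "gene_j") %in% names(df)))
  df
}

#' Write a table (DE table, centrality table, enrichment) as TSV
#'
#' @param table data.frame.
#' @param path output path.
#' @export
write_table_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(table)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path text file path.
#' @return character vector (whitespace-stripped, empties dropped).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Write a gene list, one symbol per line
#'
#' @param genes character vector.
#' @param path output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(genes)
}
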