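#' Write / read an expression study as TSV
#'
#' Expression: genes x samples with a `gene_id` first column and sample ids
#' as header. Traits: one row per sample with a `sample_id` first column.
#'
#' @param study an [expression_study()].
#' @param expr_path,traits_path file paths.
#' @name study_tsv
#' @export
write_study_tsv <- function(study, expr_path, traits_path = NULL) {
  df <- data.frame(gene_id = study$genes, study$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(traits_path) && !is.null(study$traits)) {
    tr <- data.frame(sample_id = rownames(study$traits), study$traits,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tr, traits_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(study)
}

#' @param expr_path,traits_path file paths.
#' @rdname study_tsv
#' @export
read_study_tsv <- function(expr_path, traits_path = NULL) {
  df <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  traits <- NULL
  if (!is.null(traits_path)) {
    tr <- read.delim(traits_path, check.names = FALSE, stringsAsFactors = FALSE)
    traits <- tr[, -1, drop = FALSE]
    rownames(traits) <- tr[[1]]
  }
  expression_study(values, traits)
}

#' Write / read marker panels as two-column TSV (panel_name, gene_id)
#'
#' @param panels named list of gene-id vectors.
#' @param path file path.
#' @name panel_tsv
#' @export
write_panels_tsv <- function(panels, path) {
  df <- do.call(rbind, lapply(names(panels), function(nm)
    data.frame(panel_name = nm, gene_id = panels[[nm]],
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(panels)
}

#' @rdname panel_tsv
#' @export
read_panels_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  split(df$gene_id, df$panel_name)
}

#' Write / read genomic intervals as BED (0-based half-open)
#'
#' Thin wrappers over rtracklayer's BED import/export.
#'
#' @param gr a GRanges.
#' @param path file path ending in .bed.
#' @name bed_io
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(gr)
}

#' @rdname bed_io
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write / read a PPI edge list as two-column TSV
#'
#' @param ppi a `ppi_network`.
#' @param path file path.
#' @name ppi_tsv
#' @export
write_ppi_tsv <- function(ppi, path) {
  el <- igraph::as_edgelist(ppi$graph)
  df <- data.frame(protein_a = el[, 1], protein_b = el[, 2],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ppi)
}

#' @rdname ppi_tsv
#' @export
read_ppi_tsv <- function(path) {
  ppi_network(read.delim(path, stringsAsFactors = FALSE))
}

#' Write ground truth as JSON
#'
#' @param truth a `ground_truth`.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  out <- truth[c("module_genes", "driver_tfs", "tf_ids", "regulons",
                 "marker_overlap", "peak_target_genes", "ppi_seed_clique")]
  jsonlite::write_json(out, path, auto_unbox = FALSE, pretty = TRUE,
                       null = "null")
  invisible(truth)
}
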