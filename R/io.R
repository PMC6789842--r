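# Plain-text I/O for the pipeline's tables. All writes are tab-separated
# with headers and logged with row counts so runs are auditable.

#' Read a peptide-level table from TSV
#' @param path TSV with the standard peptide columns.
#' @return validated data.frame.
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) stopf("peptide table not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  dt <- as.data.frame(as_peptide_table(dt))
  wp_log("read %d peptide rows from %s", nrow(dt), path)
  dt
}

#' Read / write a protein abundance matrix as TSV
#'
#' The layout is proteins in rows with leading `protein_id` and
#' `gene_symbol` columns, then one column per sample.
#'
#' @param path TSV file.
#' @param is_log2 whether stored values are log2 (recorded in the object).
#' @return a [protein_matrix].
#' @export
read_protein_matrix <- function(path, is_log2 = TRUE) {
  if (!file.exists(path)) stopf("protein matrix not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (!all(c("protein_id", "gene_symbol") %in% names(dt)))
    stopf("protein matrix TSV must start with protein_id and gene_symbol")
  vals <- as.matrix(dt[, setdiff(names(dt), c("protein_id", "gene_symbol")),
                       drop = FALSE])
  rownames(vals) <- dt$protein_id
  wp_log("read protein matrix %d x %d from %s", nrow(vals), ncol(vals), path)
  protein_matrix(vals, protein_ids = dt$protein_id,
                 gene_symbols = dt$gene_symbol, is_log2 = is_log2)
}

#' @rdname read_protein_matrix
#' @param pm a [protein_matrix].
#' @export
write_protein_matrix <- function(pm, path) {
  df <- data.frame(protein_id = rownames(pm$values),
                   gene_symbol = unname(pm$gene_symbols[rownames(pm$values)]),
                   pm$values, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a sample trait table from CSV
#' @param path CSV with header (`sample_id`, `group`, `age`, `sex`, `pmi`,
#'   optionally `casi`, `cerad`, `braak`).
#' @return validated data.frame.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stopf("trait table not found: %s", path)
  tr <- validate_traits(data.table::fread(path, data.table = FALSE))
  wp_log("read %d samples from %s", nrow(tr), path)
  tr
}

#' Read a module partition table from TSV
#' @param path TSV with at least `gene_symbol` and `module` columns.
#' @return named character vector (gene symbol -> module label).
#' @export
read_partition_table <- function(path) {
  if (!file.exists(path)) stopf("partition table not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (!all(c("gene_symbol", "module") %in% names(dt)))
    stopf("partition TSV needs gene_symbol and module columns")
  stats::setNames(as.character(dt$module), toupper(dt$gene_symbol))
}

# write a data.frame as TSV (deterministic formatting), log the row count
write_tsv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  wp_log("wrote %d rows to %s", nrow(df), path)
  invisible(path)
}

#' Write the partition / eigenprotein / kME triple as TSV files
#'
#' @param net a `wpcna_network` from [build_network].
#' @param pm the [protein_matrix] the network was built from (for symbols).
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_network_tables <- function(net, pm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(net$partition$assignment)
  own <- vapply(ids, function(p) {
    m <- net$partition$assignment[[p]]
    if (m %in% colnames(net$kme$kme)) net$kme$kme[p, m] else NA_real_
  }, numeric(1))
  write_tsv(data.frame(protein_id = ids,
                       gene_symbol = unname(pm$gene_symbols[ids]),
                       module = unname(net$partition$assignment),
                       kme_own = unname(own),
                       stage = net$partition$stage,
                       stringsAsFactors = FALSE),
            file.path(dir, "module_partition.tsv"))
  write_tsv(data.frame(module = rownames(net$eigenproteins$values),
                       variance_explained = unname(net$eigenproteins$variance_explained),
                       net$eigenproteins$values, check.names = FALSE),
            file.path(dir, "eigenproteins.tsv"))
  write_tsv(data.frame(protein_id = rownames(net$kme$kme),
                       net$kme$kme, check.names = FALSE),
            file.path(dir, "kme.tsv"))
  write_dendrogram_newick(list(dendrogram = net$dendrogram),
                          file.path(dir, "dendrogram.nwk"))
  invisible(dir)
}
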