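#' Protein abundance matrix
#'
#' Light-weight container for a proteins-by-samples abundance matrix, the
#' central object of the pipeline. Rows are protein groups, columns samples.
#' Missing abundances are `NA` in `values`; `missing_mask()` recovers the
#' boolean mask. Gene symbols are carried per protein for gene-set work.
#'
#' @param values numeric matrix, proteins in rows, samples in columns.
#'   Rownames are taken as protein ids when `protein_ids` is missing.
#' @param protein_ids character vector of protein-group identifiers.
#' @param gene_symbols character vector, one symbol per protein.
#' @param sample_ids character vector of sample identifiers.
#' @param is_log2 logical; `TRUE` when `values` are log2 transformed.
#' @return an object of class `protein_matrix`: a list with elements
#'   `values`, `gene_symbols` (named by protein id) and `is_log2`.
#' @export
protein_matrix <- function(values, protein_ids = rownames(values),
                           gene_symbols = NULL, sample_ids = colnames(values),
                           is_log2 = FALSE) {
  values <- as.matrix(values)
  if (is.null(protein_ids)) stopf("protein ids are required")
  if (is.null(sample_ids)) stopf("sample ids are required")
  if (anyDuplicated(protein_ids)) stopf("duplicated protein ids")
  if (anyDuplicated(sample_ids)) stopf("duplicated sample ids")
  if (length(protein_ids) != nrow(values) ||
      length(sample_ids) != ncol(values))
    stopf("dimension mismatch between values and identifiers")
  if (is.null(gene_symbols)) gene_symbols <- protein_ids
  if (isTRUE(is_log2) && any(!is.finite(values) & !is.na(values)))
    stopf("log2 values must be finite where not missing")
  dimnames(values) <- list(protein_ids, sample_ids)
  structure(list(values = values,
                 gene_symbols = stats::setNames(as.character(gene_symbols),
                                                protein_ids),
                 is_log2 = isTRUE(is_log2)),
            class = "protein_matrix")
}

#' @export
dim.protein_matrix <- function(x) dim(x$values)

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix: %d proteins x %d samples (%s scale, %d missing cells)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_log2) "log2" else "linear", sum(is.na(x$values))))
  invisible(x)
}

#' @rdname protein_matrix
#' @param x a `protein_matrix`.
#' @export
missing_mask <- function(x) is.na(x$values)

#' Sample trait table checks
#'
#' Validates the clinical trait table used throughout the pipeline: one row
#' per sample with the diagnosis group (`control`, `AsymAD`, `AD`), age at
#' death (years), sex, post-mortem interval (hours) and, optionally, the
#' phenotypes CASI (cognition, higher = better), CERAD (amyloid plaque score)
#' and Braak (tangle stage).
#'
#' @param traits data.frame with at least `sample_id`, `group`, `age`,
#'   `sex`, `pmi`.
#' @return the validated data.frame with `group` as a factor leveled
#'   `control < AsymAD < AD`.
#' @export
validate_traits <- function(traits) {
  need <- c("sample_id", "group", "age", "sex", "pmi")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stopf("trait table lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(traits$sample_id)) stopf("duplicated sample_id in traits")
  if (any(is.na(traits$group))) stopf("missing group assignments")
  if (any(traits$age <= 0)) stopf("age must be positive")
  if (any(traits$pmi <= 0)) stopf("pmi must be positive")
  lv <- c("control", "AsymAD", "AD")
  bad <- setdiff(unique(as.character(traits$group)), lv)
  if (length(bad)) stopf("unknown group label(s): %s", paste(bad, collapse = ", "))
  traits$group <- factor(as.character(traits$group), levels = lv)
  traits
}

# align a trait table to the sample order of a protein_matrix
align_traits <- function(pm, traits) {
  traits <- validate_traits(traits)
  ids <- colnames(pm$values)
  if (!setequal(ids, traits$sample_id))
    stopf("samples in matrix and traits differ")
  traits[match(ids, traits$sample_id), , drop = FALSE]
}
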