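#' @import data.table
NULL

peptide_cols <- c("peptide_sequence", "protein_group", "gene_symbol",
                  "sample_id", "fraction", "intensity", "spectral_counts",
                  "is_unique")

# validate and coerce a peptide-level table
as_peptide_table <- function(peptides) {
  dt <- data.table::as.data.table(peptides)
  miss <- setdiff(peptide_cols, names(dt))
  if (length(miss)) stopf("peptide table lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (nrow(dt) && any(dt$intensity < 0, na.rm = TRUE))
    stopf("negative peptide intensities")
  if (nrow(dt) && any(dt$spectral_counts < 0, na.rm = TRUE))
    stopf("negative spectral counts")
  dt$is_unique <- as.logical(dt$is_unique)
  dt
}

#' Filter protein groups by identification evidence
#'
#' Retains protein groups measured by at least one unique peptide (a peptide
#' mapping to exactly one protein group) and at least two peptide spectral
#' matches, the spectral matches being summed over the group's peptides
#' across all samples and fractions.
#'
#' @param peptides peptide-level table (data.frame) with the columns
#'   `peptide_sequence`, `protein_group`, `gene_symbol`, `sample_id`,
#'   `fraction`, `intensity`, `spectral_counts`, `is_unique`.
#' @param min_unique minimum number of unique peptides per group (default 1).
#' @param min_spectra minimum total spectral counts per group (default 2).
#' @return character vector of retained protein-group identifiers.
#' @export
filter_protein_groups <- function(peptides, min_unique = 1L,
                                  min_spectra = 2L) {
  dt <- as_peptide_table(peptides)
  if (!nrow(dt)) {
    wp_log("empty peptide table: no protein groups retained")
    return(character(0))
  }
  protein_group <- spectral_counts <- is_unique <- peptide_sequence <- NULL
  ev <- dt[, list(
    n_unique = data.table::uniqueN(peptide_sequence[is_unique]),
    total_counts = sum(spectral_counts)
  ), by = protein_group]
  keep <- ev[ev$n_unique >= min_unique & ev$total_counts >= min_spectra, ]
  wp_log("protein-group filter: %d of %d groups retained",
         nrow(keep), nrow(ev))
  sort(as.character(keep$protein_group))
}

#' Top-3 peptide ion-intensity protein quantification
#'
#' Estimates per-protein, per-sample abundance as the arithmetic mean of the
#' extracted ion intensities of the protein's three most intense peptides in
#' that sample. Proteins observed with fewer than three peptides use the mean
#' of all available peptides (the count is reported in the `n_peptides`
#' attribute). Zero or absent intensities are treated as missing; peptide
#' rows from multiple fractions of the same sample are summed per peptide
#' before ranking.
#'
#' @param peptides peptide-level table (see [filter_protein_groups]).
#' @param retained_groups protein groups to quantify, typically the output
#'   of [filter_protein_groups].
#' @param log2_transform return log2 abundances (default `TRUE`).
#' @return a [protein_matrix] with an `n_peptides` attribute (proteins x
#'   samples matrix of peptide counts used per cell). Proteins with no
#'   nonzero intensity in any sample are dropped with a log entry.
#' @export
top3_protein_abundance <- function(peptides, retained_groups = NULL,
                                   log2_transform = TRUE) {
  dt <- as_peptide_table(peptides)
  if (!nrow(dt)) stopf("empty peptide table")
  if (is.null(retained_groups)) retained_groups <- unique(dt$protein_group)
  if (!all(retained_groups %in% dt$protein_group))
    stopf("retained_groups contains groups absent from the table")
  protein_group <- sample_id <- peptide_sequence <- intensity <- NULL
  dt <- dt[dt$protein_group %in% retained_groups, ]
  # collapse fractions: one intensity per peptide per sample
  pep <- dt[, list(intensity = sum(intensity)),
            by = list(protein_group, sample_id, peptide_sequence)]
  pep <- pep[pep$intensity > 0, ]
  top <- pep[, {
    v <- sort(intensity, decreasing = TRUE)
    k <- min(3L, length(v))
    list(abundance = mean(v[seq_len(k)]), n_peptides = k)
  }, by = list(protein_group, sample_id)]

  prot_ids <- sort(unique(as.character(dt$protein_group)))
  samp_ids <- sort(unique(as.character(dt$sample_id)))
  vals <- matrix(NA_real_, length(prot_ids), length(samp_ids),
                 dimnames = list(prot_ids, samp_ids))
  npep <- matrix(0L, length(prot_ids), length(samp_ids),
                 dimnames = list(prot_ids, samp_ids))
  vals[cbind(as.character(top$protein_group),
             as.character(top$sample_id))] <- top$abundance
  npep[cbind(as.character(top$protein_group),
             as.character(top$sample_id))] <- top$n_peptides

  dead <- rowSums(!is.na(vals)) == 0
  if (any(dead)) {
    wp_log("dropping %d protein(s) with no nonzero intensity: %s",
           sum(dead), paste(head(prot_ids[dead], 5), collapse = ", "))
    vals <- vals[!dead, , drop = FALSE]
    npep <- npep[!dead, , drop = FALSE]
    prot_ids <- prot_ids[!dead]
  }
  gene_map <- dt[, list(gene_symbol = gene_symbol[1L]), by = protein_group]
  genes <- stats::setNames(as.character(gene_map$gene_symbol),
                           as.character(gene_map$protein_group))[prot_ids]
  if (log2_transform) vals <- log2(vals)
  pm <- protein_matrix(vals, protein_ids = prot_ids, gene_symbols = genes,
                       sample_ids = samp_ids, is_log2 = log2_transform)
  attr(pm, "n_peptides") <- npep
  pm
}

#' Membrane-vs-soluble enrichment decile profile
#'
#' Summarizes how strongly each protein partitions into the membrane versus
#' the soluble fraction, using the log2 ratio of summed peptide spectral
#' counts (membrane / soluble, each side offset by a pseudocount). Proteins
#' with fewer than `min_counts` total spectral counts are excluded. The
#' remaining proteins are ranked by ratio and cut into 10 near-equal deciles
#' (decile 1 = most soluble-depleted end of the ranking); per decile the mean
#' ratio and, for each compartment class in `class_map`, the fraction of the
#' class's proteins falling in that decile are reported, together with the
#' fraction of each class with ratio > 0 ("membrane-enriched").
#'
#' @param peptides peptide-level table containing both `membrane` and
#'   `soluble` fraction rows.
#' @param class_map named list mapping a compartment class (e.g.
#'   "cytoplasmic", "membrane", "intrinsic_to_membrane") to gene symbols,
#'   e.g. as read by [read_gmt].
#' @param pseudocount added to both numerator and denominator counts
#'   (default 0.5) so membrane-only / soluble-only proteins keep a finite,
#'   sign-preserving ratio.
#' @param min_counts minimum total spectral counts per protein (default 3).
#' @return list with `profile` (per-decile data.frame: decile,
#'   mean_log2_ratio, n_proteins), `class_fractions` (class x decile matrix),
#'   `enriched_fraction` (named vector, per class fraction with ratio > 0)
#'   and `ratios` (per-protein table).
#' @export
membrane_enrichment_profile <- function(peptides, class_map = list(),
                                        pseudocount = 0.5, min_counts = 3L) {
  dt <- as_peptide_table(peptides)
  for (fr in c("membrane", "soluble"))
    if (!any(dt$fraction == fr))
      stopf("peptide table has no '%s' fraction rows", fr)
  gene_symbol <- fraction <- spectral_counts <- NULL
  counts <- dt[dt$fraction %in% c("membrane", "soluble"),
               list(counts = sum(spectral_counts)),
               by = list(gene_symbol, fraction)]
  wide <- data.table::dcast(counts, gene_symbol ~ fraction,
                            value.var = "counts", fill = 0)
  if (is.null(wide$membrane)) wide$membrane <- 0
  if (is.null(wide$soluble)) wide$soluble <- 0
  wide <- wide[(wide$membrane + wide$soluble) >= min_counts, ]
  if (nrow(wide) < 10L) stopf("fewer than 10 proteins pass the count filter")
  wide$ratio <- log2((wide$membrane + pseudocount) /
                       (wide$soluble + pseudocount))
  # stable, reproducible ranking: ratio then gene symbol
  wide <- wide[order(wide$ratio, wide$gene_symbol), ]
  n <- nrow(wide)
  # near-equal decile sizes differing by at most one
  sizes <- rep(n %/% 10L, 10L) + c(rep(1L, n %% 10L), rep(0L, 10L - n %% 10L))
  wide$decile <- rep(seq_len(10L), times = sizes)

  prof <- wide[, list(mean_log2_ratio = mean(ratio),
                      n_proteins = .N), by = "decile"]
  data.table::setorder(prof, decile)

  cls <- names(class_map)
  cf <- matrix(0, length(cls), 10L,
               dimnames = list(cls, paste0("D", 1:10)))
  enr <- stats::setNames(rep(NA_real_, length(cls)), cls)
  for (cl in cls) {
    members <- wide[wide$gene_symbol %in% class_map[[cl]], ]
    if (!nrow(members)) next
    tab <- tabulate(members$decile, nbins = 10L)
    cf[cl, ] <- tab / nrow(members)
    enr[cl] <- mean(members$ratio > 0)
  }
  list(profile = as.data.frame(prof),
       class_fractions = cf,
       enriched_fraction = enr,
       ratios = as.data.frame(wide[, c("gene_symbol", "membrane", "soluble",
                                       "ratio", "decile")]))
}
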