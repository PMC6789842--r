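# default trait coding: diagnosis ordinal (control 0, AsymAD 1, AD 2),
# CASI as-is (higher = better cognition), CERAD and Braak as-is.
default_trait_columns <- c("diagnosis", "casi", "cerad", "braak")

# build the numeric trait matrix used for module-trait correlation
trait_numeric_matrix <- function(traits, trait_columns = default_trait_columns,
                                 diagnosis_coding = c("ordinal", "binary_ad")) {
  diagnosis_coding <- match.arg(diagnosis_coding)
  traits <- validate_traits(traits)
  cols <- list()
  for (tc in trait_columns) {
    if (tc == "diagnosis") {
      cols[[tc]] <- if (diagnosis_coding == "ordinal")
        as.numeric(traits$group) - 1          # control 0, AsymAD 1, AD 2
      else as.numeric(traits$group == "AD")
    } else {
      if (is.null(traits[[tc]])) stopf("trait column '%s' not found", tc)
      cols[[tc]] <- as.numeric(traits[[tc]])
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- traits$sample_id
  m
}

#' Module-trait correlation by biweight midcorrelation
#'
#' Correlates every module eigenprotein with every clinical/pathological
#' trait using the biweight midcorrelation, with two-sided p-values from
#' the t transform at n - 2 degrees of freedom. Diagnosis is coded
#' ordinally (control 0, AsymAD 1, AD 2) by default; dichotomous columns
#' automatically fall back to Pearson (median/mad degenerate for binary
#' codings). CASI is correlated as-is (higher = better cognition), so a
#' negative r means higher module expression with worse cognition. A BH
#' FDR column over the whole grid is additionally emitted.
#'
#' @param eig an `eigenprotein_set`.
#' @param traits trait table (see [validate_traits]).
#' @param trait_columns traits to correlate (default diagnosis, casi,
#'   cerad, braak).
#' @param diagnosis_coding `"ordinal"` or `"binary_ad"` (AD vs rest).
#' @return a `trait_cor_table`: list with matrices `r`, `p`, `fdr`
#'   (modules x traits) and `n` samples.
#' @export
module_trait_bicor <- function(eig, traits,
                               trait_columns = default_trait_columns,
                               diagnosis_coding = "ordinal") {
  tm <- trait_numeric_matrix(traits, trait_columns, diagnosis_coding)
  ids <- colnames(eig$values)
  if (!all(ids %in% rownames(tm)))
    stopf("traits missing for some samples")
  tm <- tm[ids, , drop = FALSE]
  n <- length(ids)
  if (n < 5) stopf("at least 5 samples are required")
  mods <- rownames(eig$values)
  r <- matrix(NA_real_, length(mods), ncol(tm),
              dimnames = list(mods, colnames(tm)))
  for (tc in colnames(tm)) {
    x <- tm[, tc]
    if (stats::sd(x, na.rm = TRUE) == 0) {
      warning(sprintf("trait '%s' is constant; correlations set to NA", tc),
              call. = FALSE)
      next
    }
    for (m in mods) r[m, tc] <- bicor_pair(eig$values[m, ], x)
  }
  p <- cor_pvalue(r, n)
  dimnames(p) <- dimnames(r)
  fdr <- matrix(bh_fdr(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  structure(list(r = r, p = p, fdr = fdr, n = n), class = "trait_cor_table")
}

#' @export
print.trait_cor_table <- function(x, ...) {
  stars <- ifelse(x$p < 0.01, "**", ifelse(x$p < 0.05, "*", ""))
  disp <- matrix(sprintf("%+.2f%s", x$r, stars), nrow(x$r),
                 dimnames = dimnames(x$r))
  cat(sprintf("module-trait bicor (n = %d; * p<0.05, ** p<0.01)\n", x$n))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Kruskal-Wallis test of eigenprotein differences across groups
#'
#' Nonparametric one-way test (with tie correction) of each module
#' eigenprotein across the diagnosis groups; the H statistic is referred to
#' a chi-square distribution with k - 1 degrees of freedom.
#'
#' @param eig an `eigenprotein_set`.
#' @param traits trait table with `sample_id` and `group`.
#' @return data.frame with `module`, `H`, `df`, `p`.
#' @export
eigenprotein_group_test <- function(eig, traits) {
  traits <- validate_traits(traits)
  ids <- colnames(eig$values)
  traits <- traits[match(ids, traits$sample_id), ]
  grp <- droplevels(traits$group)
  if (nlevels(grp) < 2) stopf("at least two groups are required")
  if (any(table(grp) == 0)) stopf("a diagnosis group has no samples")
  rows <- lapply(rownames(eig$values), function(m) {
    v <- eig$values[m, ]
    if (length(unique(v)) == 1L)
      return(data.frame(module = m, H = 0, df = nlevels(grp) - 1L, p = 1))
    kt <- stats::kruskal.test(v, grp)
    data.frame(module = m, H = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value)
  })
  do.call(rbind, rows)
}
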