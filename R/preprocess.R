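#' Remove covariate effects by bootstrap regression
#'
#' For each protein a linear model `abundance ~ group + covariates` is
#' fitted on bootstrap resamples of the samples (drawn with replacement,
#' stratified by diagnosis group so group counts are preserved exactly), and
#' each covariate coefficient is summarized by its median over resamples.
#' The returned matrix is the input minus the fitted covariate contributions
#' computed on mean-centered covariates, so the grand mean and, crucially,
#' the diagnosis-group structure are untouched. Missing cells stay missing
#' and are excluded from fits; proteins with fewer complete observations
#' than model parameters plus two are returned unadjusted with a warning.
#'
#' @param pm a [protein_matrix] (log2 scale expected).
#' @param traits trait table with `sample_id`, `group` and the covariate
#'   columns.
#' @param covariates covariate column names (default age, sex, pmi). A
#'   character `sex` column is coded 0/1.
#' @param n_bootstrap number of bootstrap resamples (default 1000).
#' @param seed integer seed; mandatory for reproducibility.
#' @param max_retries redraws allowed when a resample yields a
#'   rank-deficient design.
#' @return a [protein_matrix] of adjusted abundances, with attribute
#'   `covariate_coefficients` (proteins x covariates matrix of the median
#'   bootstrap coefficients) and `skipped_proteins`.
#' @export
regress_covariates <- function(pm, traits, covariates = c("age", "sex", "pmi"),
                               n_bootstrap = 1000L, seed, max_retries = 100L) {
  if (missing(seed)) stopf("seed is mandatory for bootstrap regression")
  if (n_bootstrap < 1) stopf("n_bootstrap must be at least 1")
  traits <- align_traits(pm, traits)
  miss <- setdiff(covariates, names(traits))
  if (length(miss)) stopf("covariates absent from traits: %s",
                          paste(miss, collapse = ", "))
  xc <- sapply(covariates, function(cv) {
    col <- traits[[cv]]
    if (!is.numeric(col)) as.numeric(factor(col)) - 1 else as.numeric(col)
  })
  xc <- as.matrix(xc)
  colnames(xc) <- covariates
  grp <- model_matrix_group(traits$group)
  design <- cbind(grp, xc)
  n_samp <- nrow(design)
  cov_idx <- ncol(grp) + seq_along(covariates)
  p_par <- ncol(design)

  y <- t(pm$values)                      # samples x proteins
  complete_prot <- colSums(is.na(y)) == 0
  groups <- split(seq_len(n_samp), traits$group)

  with_seed(seed, {
    coefs <- array(NA_real_, c(n_bootstrap, length(covariates), ncol(y)),
                   dimnames = list(NULL, covariates, colnames(y)))
    for (b in seq_len(n_bootstrap)) {
      idx <- draw_stratified(groups, max_retries, design)
      xb <- design[idx, , drop = FALSE]
      xtx <- crossprod(xb)
      # complete proteins in one solve; proteins with NAs individually
      if (any(complete_prot)) {
        bhat <- solve(xtx, crossprod(xb, y[idx, complete_prot, drop = FALSE]))
        coefs[b, , complete_prot] <- bhat[cov_idx, , drop = FALSE]
      }
      for (j in which(!complete_prot)) {
        ok <- !is.na(y[idx, j])
        if (sum(ok) < p_par + 2) next
        xj <- xb[ok, , drop = FALSE]
        if (qr(xj)$rank < p_par) next
        bj <- solve(crossprod(xj), crossprod(xj, y[idx, j][ok]))
        coefs[b, , j] <- bj[cov_idx, 1]
      }
    }
  })

  med <- apply(coefs, c(2, 3), stats::median, na.rm = TRUE)  # cov x protein
  # proteins never fit (too few complete observations) are left unadjusted
  fitted_any <- apply(coefs, 3, function(m) any(!is.na(m)))
  skipped <- colnames(y)[!fitted_any]
  if (length(skipped)) {
    warning(sprintf("%d protein(s) with too few complete observations left unadjusted",
                    length(skipped)), call. = FALSE)
    med[, colnames(y) %in% skipped] <- 0
  }
  med[is.na(med)] <- 0
  xc_centered <- scale(xc, center = TRUE, scale = FALSE)
  adjusted <- y - xc_centered %*% med
  out <- protein_matrix(t(adjusted), gene_symbols = pm$gene_symbols,
                        is_log2 = pm$is_log2)
  attr(out, "covariate_coefficients") <- t(med)
  attr(out, "skipped_proteins") <- skipped
  out
}

# treatment-coded group design with intercept
model_matrix_group <- function(group) {
  stats::model.matrix(~ g, data = data.frame(g = group))
}

# stratified with-replacement resample whose full design keeps rank
draw_stratified <- function(groups, max_retries, design) {
  for (try in seq_len(max_retries)) {
    idx <- unlist(lapply(groups, function(g)
      g[sample.int(length(g), length(g), replace = TRUE)]),
      use.names = FALSE)
    if (qr(design[idx, , drop = FALSE])$rank == ncol(design)) return(idx)
  }
  stopf("could not draw a full-rank bootstrap resample in %d tries",
        max_retries)
}
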