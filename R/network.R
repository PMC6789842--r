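#' Network construction parameters
#'
#' Bundles the tunable parameters of the signed weighted co-expression
#' network. Defaults follow the membrane-proteome study design: soft
#' threshold power 11.5, deep split 4, minimum module size 20, mean-denominator
#' topological overlap, biweight midcorrelation, signed adjacency, module
#' merge cut height 0.07 and a kME reassignment threshold of p = 0.05.
#'
#' @param beta soft-threshold power (> 0).
#' @param deep_split integer 0-4; higher values split the dendrogram more
#'   aggressively into smaller modules.
#' @param min_module_size smallest admissible module.
#' @param tom_denom `"mean"` or `"min"` denominator for the topological
#'   overlap.
#' @param cor_method `"bicor"` (robust, default) or `"pearson"`.
#' @param signed signed network mapping correlation -1 to adjacency 0.
#' @param merge_cut_height eigenprotein dissimilarity (1 - cor) below which
#'   modules are merged.
#' @param reassign_p p-value threshold governing kME-based reassignment.
#' @param pam_respects_dendro restrict the medoid assignment stage to modules
#'   on the protein's own dendrogram branch.
#' @param cut_height dendrogram height above which objects are left out of
#'   branches; `NULL` uses 0.99 of the tallest merge.
#' @return a list of class `network_params`.
#' @export
network_params <- function(beta = 11.5, deep_split = 4L,
                           min_module_size = 20L,
                           tom_denom = c("mean", "min"),
                           cor_method = c("bicor", "pearson"),
                           signed = TRUE, merge_cut_height = 0.07,
                           reassign_p = 0.05, pam_respects_dendro = TRUE,
                           cut_height = NULL) {
  tom_denom <- match.arg(tom_denom)
  cor_method <- match.arg(cor_method)
  if (beta <= 0) stopf("beta must be positive")
  if (!deep_split %in% 0:4) stopf("deep_split must be an integer in 0..4")
  if (min_module_size < 2) stopf("min_module_size must be at least 2")
  if (merge_cut_height < 0 || merge_cut_height >= 1)
    stopf("merge_cut_height must lie in [0, 1)")
  if (reassign_p <= 0 || reassign_p >= 1)
    stopf("reassign_p must lie in (0, 1)")
  structure(list(beta = beta, deep_split = as.integer(deep_split),
                 min_module_size = as.integer(min_module_size),
                 tom_denom = tom_denom, cor_method = cor_method,
                 signed = isTRUE(signed),
                 merge_cut_height = merge_cut_height,
                 reassign_p = reassign_p,
                 pam_respects_dendro = isTRUE(pam_respects_dendro),
                 cut_height = cut_height),
            class = "network_params")
}

#' Signed soft-thresholded adjacency
#'
#' Maps a correlation matrix to a weighted adjacency. In a signed network
#' `a_ij = ((1 + s_ij) / 2)^beta`, so perfectly anti-correlated proteins are
#' unconnected and the soft power suppresses weak correlations. With
#' `signed = FALSE`, `a_ij = |s_ij|^beta`.
#'
#' @param cor correlation matrix with entries in \[-1, 1\].
#' @param beta soft-threshold power.
#' @param signed use the signed transform (default `TRUE`).
#' @return adjacency matrix in \[0, 1\] with unit diagonal.
#' @export
signed_adjacency <- function(cor, beta = 11.5, signed = TRUE) {
  if (beta <= 0) stopf("beta must be positive")
  if (any(cor < -1 - 1e-8 | cor > 1 + 1e-8, na.rm = TRUE))
    stopf("correlations outside [-1, 1]")
  a <- if (signed) ((1 + cor) / 2)^beta else abs(cor)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' Similarity combining direct adjacency with shared-neighbor structure:
#' `TOM_ij = (l_ij + a_ij) / (D_ij + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj`, connectivity `k_i = sum_{u != i} a_iu`,
#' and denominator `D_ij = (k_i + k_j) / 2` (mean variant) or
#' `min(k_i, k_j)` (min variant).
#'
#' @param adj adjacency matrix in \[0, 1\], unit diagonal.
#' @param denom `"mean"` or `"min"`.
#' @return TOM matrix in \[0, 1\] with unit diagonal.
#' @export
tom_similarity <- function(adj, denom = c("mean", "min")) {
  denom <- match.arg(denom)
  a <- as.matrix(adj)
  diag(a) <- 1
  l <- a %*% a - 2 * a          # removes the u = i and u = j terms (diag 1)
  k <- rowSums(a) - 1
  d <- if (denom == "mean") outer(k, k, `+`) / 2 else outer(k, k, pmin)
  tom <- (l + a) / (d + 1 - a)
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Scale-free topology fit across candidate soft powers
#'
#' For each candidate power, builds the (signed) adjacency, computes the
#' connectivity distribution and regresses `log10 p(k)` on `log10 k` over
#' 10 connectivity bins. The signed fit index `-sign(slope) * R^2` is
#' positive for the decreasing degree distribution expected of approximately
#' scale-free networks.
#'
#' @param x a [protein_matrix], numeric matrix (variables in rows), or a
#'   precomputed correlation matrix (square, unit diagonal).
#' @param powers candidate soft-threshold powers (at least two).
#' @param cor_method correlation estimator when `x` is not a correlation
#'   matrix.
#' @param signed signed adjacency (default `TRUE`).
#' @param n_breaks number of connectivity bins (default 10).
#' @return data.frame with `power`, `sft_r_squared` (signed), `slope`,
#'   `mean_connectivity`, `median_connectivity`, `max_connectivity`.
#' @export
pick_soft_threshold <- function(x, powers = c(1:10, seq(12, 20, 2)),
                                cor_method = c("bicor", "pearson"),
                                signed = TRUE, n_breaks = 10L) {
  cor_method <- match.arg(cor_method)
  if (length(powers) < 2) stopf("at least two candidate powers are required")
  v <- if (inherits(x, "protein_matrix")) x$values else as.matrix(x)
  is_cor <- nrow(v) == ncol(v) && all(abs(diag(v) - 1) < 1e-12) &&
    max(abs(v), na.rm = TRUE) <= 1 + 1e-8
  s <- if (is_cor) v else
    if (cor_method == "bicor") bicor_matrix(v) else stats::cor(t(v))
  out <- lapply(powers, function(b) {
    a <- signed_adjacency(s, beta = b, signed = signed)
    k <- rowSums(a) - 1
    fit <- scale_free_fit(k, n_breaks = n_breaks)
    data.frame(power = b, sft_r_squared = fit$signed_r2, slope = fit$slope,
               mean_connectivity = mean(k),
               median_connectivity = stats::median(k),
               max_connectivity = max(k))
  })
  do.call(rbind, out)
}

# log-log regression of the binned connectivity distribution
scale_free_fit <- function(k, n_breaks = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(list(signed_r2 = NA_real_, slope = NA_real_))
  brk <- seq(min(k), max(k), length.out = n_breaks + 1L)
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tabulate(bin, nbins = n_breaks) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(list(signed_r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm.fit(cbind(1, log10(dk[ok])), log10(pk[ok]))
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) /
    sum((log10(pk[ok]) - mean(log10(pk[ok])))^2)
  list(signed_r2 = -sign(slope) * r2, slope = unname(slope))
}
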