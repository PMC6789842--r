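#' Module eigenproteins
#'
#' The eigenprotein of a module is the first principal component of the
#' module's standardized abundance submatrix: each member protein is scaled
#' to mean 0 and sd 1 across samples, and the leading right singular vector
#' over samples is returned (unit norm). Its sign is oriented so that it
#' correlates positively with the module's mean standardized profile, making
#' "increased in disease" directly readable. `variance_explained` is the
#' share of total variance captured by the first component.
#'
#' @param pm a [protein_matrix].
#' @param part a `module_partition` (the `"unassigned"` pool is ignored).
#' @return an `eigenprotein_set`: list with `values` (modules x samples,
#'   rows unit norm), `variance_explained`, and `n_proteins`.
#' @export
module_eigenproteins <- function(pm, part) {
  v <- pm$values
  assignment <- part$assignment[rownames(v)]
  mods <- setdiff(unique(assignment), c("unassigned", NA))
  mods <- mods[order(as.integer(sub("^M", "", mods)))]
  if (!length(mods)) stopf("partition contains no modules")
  es <- matrix(NA_real_, length(mods), ncol(v),
               dimnames = list(mods, colnames(v)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  np <- stats::setNames(integer(length(mods)), mods)
  for (m in mods) {
    idx <- which(assignment == m)
    sub <- v[idx, , drop = FALSE]
    sub <- sub[stats::complete.cases(sub), , drop = FALSE]
    if (nrow(sub) < 2) stopf("module %s has fewer than 2 complete proteins", m)
    sds <- apply(sub, 1, stats::sd)
    if (any(sds == 0)) stopf("module %s contains zero-variance proteins", m)
    z <- (sub - rowMeans(sub)) / sds
    sv <- svd(z, nu = 0, nv = 1)
    ep <- sv$v[, 1]
    if (stats::cor(ep, colMeans(z)) < 0) ep <- -ep
    es[m, ] <- ep
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
    np[m] <- nrow(sub)
  }
  structure(list(values = es, variance_explained = ve, n_proteins = np),
            class = "eigenprotein_set")
}

#' @export
print.eigenprotein_set <- function(x, ...) {
  cat(sprintf("eigenprotein_set: %d modules x %d samples (var explained %.2f-%.2f)\n",
              nrow(x$values), ncol(x$values),
              min(x$variance_explained), max(x$variance_explained)))
  invisible(x)
}

#' Module membership (kME)
#'
#' Pearson correlation of every protein's abundance profile with every
#' module eigenprotein, with two-sided p-values from the t transform
#' (`t = r sqrt((n-2)/(1-r^2))`, df = n - 2). High kME to its own module
#' marks a hub protein.
#'
#' @param pm a [protein_matrix].
#' @param eig an `eigenprotein_set`.
#' @return a `kme_table`: list with matrices `kme` and `p`
#'   (proteins x modules).
#' @export
compute_kme <- function(pm, eig) {
  v <- pm$values
  if (!identical(colnames(v), colnames(eig$values)))
    stopf("matrix and eigenproteins disagree on samples")
  n <- ncol(v)
  if (n < 3) stopf("kME requires at least 3 samples")
  kme <- stats::cor(t(v), t(eig$values), use = "pairwise.complete.obs")
  p <- cor_pvalue(kme, n)
  dimnames(p) <- dimnames(kme)
  structure(list(kme = kme, p = p), class = "kme_table")
}

#' Merge modules with correlated eigenproteins
#'
#' Iteratively merges modules whose eigenproteins are nearly interchangeable:
#' eigenproteins are clustered by average linkage on the dissimilarity
#' `1 - cor(ME_a, ME_b)` and groups below `cut_height` are combined;
#' eigenproteins are recomputed and the procedure repeats until no pair
#' remains below the threshold. Final labels are re-ranked by size.
#'
#' @param pm a [protein_matrix].
#' @param part a `module_partition`.
#' @param cut_height eigenprotein dissimilarity threshold (default 0.07).
#' @param max_iter safety cap on merge iterations.
#' @return list with `partition` (stage `"merged"`) and `eigenproteins`.
#' @export
merge_modules <- function(pm, part, cut_height = 0.07, max_iter = 20L) {
  assignment <- part$assignment
  for (it in seq_len(max_iter)) {
    mods <- setdiff(unique(assignment), "unassigned")
    if (length(mods) < 2) break
    cur <- part; cur$assignment <- assignment
    eig <- module_eigenproteins(pm, cur)
    me_cor <- stats::cor(t(eig$values))
    diss <- 1 - me_cor
    hc <- stats::hclust(stats::as.dist(diss), method = "average")
    grp <- stats::cutree(hc, h = cut_height)
    if (max(grp) == length(grp)) break  # nothing below the threshold
    new <- assignment
    for (g in unique(grp)) {
      members <- names(grp)[grp == g]
      if (length(members) > 1)
        new[new %in% members] <- members[1]
    }
    assignment <- new
  }
  assignment <- rank_module_labels(assignment, names(assignment))
  out <- part
  out$assignment <- assignment
  out$stage <- "merged"
  final_eig <- module_eigenproteins(pm, out)
  list(partition = out, eigenproteins = final_eig)
}

#' Reassign proteins with insignificant module membership
#'
#' One-pass cleanup: a protein is moved to the module of its maximal kME
#' when (a) the p-value of its kME to its own module exceeds `reassign_p`
#' (membership not significant) and (b) the best alternative module's kME
#' p-value is below `reassign_p`. Eigenproteins are recomputed afterwards
#' and labels re-ranked by size.
#'
#' @param pm a [protein_matrix].
#' @param part a `module_partition`.
#' @param kme a `kme_table` consistent with `part`.
#' @param reassign_p p-value threshold (default 0.05).
#' @return list with `partition` (stage `"reassigned"`), `eigenproteins`
#'   and `n_moved`.
#' @export
reassign_low_kme <- function(pm, part, kme = NULL, reassign_p = 0.05) {
  assignment <- part$assignment
  if (is.null(kme)) kme <- compute_kme(pm, module_eigenproteins(pm, part))
  mods <- colnames(kme$kme)
  moved <- 0L
  new <- assignment
  for (pid in names(assignment)) {
    own <- assignment[[pid]]
    if (own == "unassigned" || !own %in% mods) next
    if (kme$p[pid, own] <= reassign_p) next          # membership significant
    others <- setdiff(mods, own)
    if (!length(others)) next
    best <- others[which.max(kme$kme[pid, others])]
    if (kme$p[pid, best] < reassign_p && kme$kme[pid, best] > kme$kme[pid, own]) {
      new[[pid]] <- best
      moved <- moved + 1L
    }
  }
  assignment <- rank_module_labels(new, names(new))
  out <- part
  out$assignment <- assignment
  out$stage <- "reassigned"
  wp_log("kME reassignment moved %d protein(s)", moved)
  list(partition = out, eigenproteins = module_eigenproteins(pm, out),
       n_moved = moved)
}

#' Prune module members with insignificant kME
#'
#' Complement of [reassign_low_kme]: proteins whose kME to their own module
#' eigenprotein is not significant at `p_threshold` and that have no
#' significant alternative module are returned to the `"unassigned"` pool,
#' so chance passengers picked up during branch growth do not dilute module
#' profiles. Eigenproteins are recomputed and labels re-ranked by size.
#'
#' @param pm a [protein_matrix].
#' @param part a `module_partition`.
#' @param kme a `kme_table` consistent with `part` (recomputed when `NULL`).
#' @param p_threshold significance threshold (default 0.05).
#' @return list with `partition`, `eigenproteins` and `n_pruned`.
#' @export
prune_low_kme <- function(pm, part, kme = NULL, p_threshold = 0.05) {
  assignment <- part$assignment
  if (is.null(kme)) kme <- compute_kme(pm, module_eigenproteins(pm, part))
  mods <- colnames(kme$kme)
  new <- assignment
  pruned <- 0L
  for (pid in names(assignment)) {
    own <- assignment[[pid]]
    if (own == "unassigned" || !own %in% mods) next
    if (kme$p[pid, own] <= p_threshold) next
    if (min(kme$p[pid, ]) <= p_threshold) next   # handled by reassignment
    new[[pid]] <- "unassigned"
    pruned <- pruned + 1L
  }
  assignment <- rank_module_labels(new, names(new))
  out <- part
  out$assignment <- assignment
  wp_log("kME pruning unassigned %d protein(s)", pruned)
  list(partition = out, eigenproteins = module_eigenproteins(pm, out),
       n_pruned = pruned)
}

#' Build a weighted protein co-expression network end to end
#'
#' Runs the full network stage: robust (or Pearson) correlation, signed
#' soft-thresholded adjacency, topological overlap, dynamic hybrid module
#' detection, eigenproteins and kME, merging of correlated modules, and
#' kME-based reassignment. Proteins with any missing abundance are excluded
#' from network construction (complete-case network) and reported.
#'
#' @param pm a [protein_matrix].
#' @param params a [network_params] object.
#' @param keep_tom retain the TOM matrix in the result (default `FALSE`;
#'   it is quadratic in the number of proteins).
#' @return a `wpcna_network`: list with `partition`, `eigenproteins`,
#'   `kme`, `dendrogram`, `params`, `excluded_proteins` and (optionally)
#'   `tom`.
#' @export
build_network <- function(pm, params = network_params(), keep_tom = FALSE) {
  v <- pm$values
  complete <- stats::complete.cases(v)
  if (!all(complete)) {
    wp_log("excluding %d protein(s) with missing values from the network",
           sum(!complete))
  }
  use <- protein_matrix(v[complete, , drop = FALSE],
                        gene_symbols = pm$gene_symbols[complete],
                        is_log2 = pm$is_log2)
  s <- if (params$cor_method == "bicor") bicor_matrix(use)
       else stats::cor(t(use$values))
  adj <- signed_adjacency(s, beta = params$beta, signed = params$signed)
  tom <- tom_similarity(adj, denom = params$tom_denom)
  part <- detect_modules(tom, params)
  merged <- merge_modules(use, part, cut_height = params$merge_cut_height)
  kme0 <- compute_kme(use, merged$eigenproteins)
  reass <- reassign_low_kme(use, merged$partition, kme0,
                            reassign_p = params$reassign_p)
  kme1 <- compute_kme(use, reass$eigenproteins)
  final <- prune_low_kme(use, reass$partition, kme1,
                         p_threshold = params$reassign_p)
  structure(list(partition = final$partition,
                 eigenproteins = final$eigenproteins,
                 kme = compute_kme(use, final$eigenproteins),
                 dendrogram = part$dendrogram,
                 params = params,
                 excluded_proteins = rownames(v)[!complete],
                 tom = if (keep_tom) tom else NULL),
            class = "wpcna_network")
}

#' @export
print.wpcna_network <- function(x, ...) {
  print(x$partition)
  invisible(x)
}
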