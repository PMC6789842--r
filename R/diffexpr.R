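# fixed comparison order: first group minus second
diff_comparisons <- list(
  AsymAD_vs_control = c("AsymAD", "control"),
  AD_vs_control     = c("AD", "control"),
  AD_vs_AsymAD      = c("AD", "AsymAD")
)

#' Differential abundance: one-way ANOVA with Tukey post-hoc comparisons
#'
#' Per protein, a fixed-effects one-way ANOVA across the diagnosis groups,
#' followed by Tukey HSD pairwise comparisons with Tukey-Kramer standard
#' errors for unbalanced designs; pairwise p-values come from the
#' studentized-range distribution. Each protein is tested on its complete
#' cases. The log2 difference of a comparison is `mean(first) -
#' mean(second)` with the comparison order fixed as AsymAD vs control,
#' AD vs control, AD vs AsymAD.
#'
#' @param pm a [protein_matrix] (log2 scale expected).
#' @param traits trait table with `sample_id` and `group`.
#' @return a data.frame (class `diffexpr_table`) with `protein_id`,
#'   `gene_symbol`, `anova_F`, `anova_p`, per-comparison
#'   `log2_diff_<cmp>` and `tukey_p_<cmp>`, and `reason` (`NA` when tested;
#'   otherwise why not). Proteins with zero within-group variance but
#'   between-group differences get `anova_F = Inf`, `anova_p = 0` and
#'   `reason = "zero_within_variance"`.
#' @export
anova_tukey <- function(pm, traits) {
  traits <- align_traits(pm, traits)
  grp <- droplevels(traits$group)
  if (nlevels(grp) < 2) stopf("at least two diagnosis groups are required")
  cmp <- diff_comparisons[vapply(diff_comparisons, function(pair)
    all(pair %in% levels(grp)), logical(1))]
  v <- pm$values
  out <- data.frame(protein_id = rownames(v),
                    gene_symbol = unname(pm$gene_symbols[rownames(v)]),
                    anova_F = NA_real_, anova_p = NA_real_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  for (nm in names(cmp)) {
    out[[paste0("log2_diff_", nm)]] <- NA_real_
    out[[paste0("tukey_p_", nm)]] <- NA_real_
  }
  for (i in seq_len(nrow(v))) {
    res <- anova_tukey_one(v[i, ], grp, cmp)
    out$anova_F[i] <- res$F
    out$anova_p[i] <- res$p
    out$reason[i] <- res$reason
    for (nm in names(cmp)) {
      out[[paste0("log2_diff_", nm)]][i] <- res$diff[nm]
      out[[paste0("tukey_p_", nm)]][i] <- res$tukey_p[nm]
    }
  }
  class(out) <- c("diffexpr_table", "data.frame")
  out
}

# one protein: F, p, Tukey-Kramer pairwise p via the studentized range
anova_tukey_one <- function(y, grp, cmp) {
  ok <- !is.na(y)
  y <- y[ok]; g <- droplevels(grp[ok])
  nper <- table(g)
  diff <- stats::setNames(rep(NA_real_, length(cmp)), names(cmp))
  tp <- diff
  bad <- list(F = NA_real_, p = NA_real_, diff = diff, tukey_p = tp,
              reason = "insufficient_observations")
  if (sum(nper >= 2) < 2) return(bad)
  k <- nlevels(g)
  n <- length(y)
  means <- tapply(y, g, mean)
  ss_within <- sum(tapply(y, g, function(x) sum((x - mean(x))^2)))
  ss_between <- sum(nper * (means - mean(y))^2)
  df1 <- k - 1
  df2 <- n - k
  for (nm in names(cmp)) {
    pair <- cmp[[nm]]
    if (all(pair %in% levels(g)))
      diff[nm] <- means[pair[1]] - means[pair[2]]
  }
  if (ss_within <= 1e-12 * max(ss_between, 1e-300)) {
    if (ss_between <= 1e-12) {           # all values identical
      tp[] <- 1
      return(list(F = 0, p = 1, diff = diff, tukey_p = tp, reason = NA_character_))
    }
    tp[] <- ifelse(abs(diff) > 0, 0, 1)  # separated groups, no within noise
    return(list(F = Inf, p = 0, diff = diff, tukey_p = tp,
                reason = "zero_within_variance"))
  }
  mse <- ss_within / df2
  f <- (ss_between / df1) / mse
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  for (nm in names(cmp)) {
    pair <- cmp[[nm]]
    if (!all(pair %in% levels(g))) next
    se <- sqrt(mse / 2 * (1 / nper[pair[1]] + 1 / nper[pair[2]]))
    q <- abs(diff[nm]) / se
    tp[nm] <- stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
  }
  list(F = f, p = p, diff = diff, tukey_p = tp, reason = NA_character_)
}

#' Significantly altered protein sets and their Venn regions
#'
#' Applies the significance threshold to the Tukey pairwise p-values and
#' returns, per comparison, the set of altered proteins together with the
#' seven Venn region counts and the union count.
#'
#' @param tab a `diffexpr_table` from [anova_tukey].
#' @param alpha significance threshold in (0, 1), default 0.05.
#' @return list with `sets` (per comparison), `venn` (named counts for the
#'   7 regions, names like `"AD_vs_control&AD_vs_AsymAD"`), `union_count`
#'   and `per_comparison` counts.
#' @export
significant_sets <- function(tab, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  pcols <- grep("^tukey_p_", names(tab), value = TRUE)
  cmps <- sub("^tukey_p_", "", pcols)
  sets <- lapply(pcols, function(cl)
    tab$protein_id[!is.na(tab[[cl]]) & tab[[cl]] < alpha])
  names(sets) <- cmps
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, cmps))
  regions <- expand.grid(rep(list(c(FALSE, TRUE)), length(cmps)))
  regions <- regions[rowSums(regions) > 0, , drop = FALSE]
  names(regions) <- cmps
  venn <- apply(regions, 1, function(r) {
    if (!length(all_ids)) return(0L)
    sum(apply(member, 1, function(m) all(m == r)))
  })
  names(venn) <- apply(regions, 1, function(r)
    paste(cmps[as.logical(r)], collapse = "&"))
  list(sets = sets, venn = venn, union_count = length(all_ids),
       per_comparison = vapply(sets, length, integer(1)))
}
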