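#' Read a GMT gene-set file
#'
#' Thin wrapper over [fgsea::gmtPathways] that uppercases and deduplicates
#' gene symbols so set membership is matched deterministically.
#'
#' @param path GMT file (one named set of gene symbols per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  sets <- fgsea::gmtPathways(path)
  lapply(sets, function(g) unique(toupper(g)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_(j >= i) p_(j) * m / j`, clipped at 1 and
#' returned in input order (delegates to [stats::p.adjust]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# hypergeometric upper tail P(X >= k) for a 2x2 overlap table
hyper_upper_p <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation of network modules
#'
#' One-tailed Fisher (hypergeometric) over-representation of every module
#' against every gene set, with Benjamini-Hochberg FDR applied across all
#' (module, set) pairs of the collection. The background universe defaults
#' to all genes carried by the partition, i.e. the quantified proteome, the
#' standard choice for proteomic ORA. Genes are matched as uppercased,
#' deduplicated symbols; set members absent from the background are dropped
#' (count logged).
#'
#' @param part a `module_partition`, or a named character vector mapping
#'   gene symbols to module labels.
#' @param sets named list of gene sets (e.g. from [read_gmt]).
#' @param gene_symbols symbols per protein; taken from the partition names
#'   when `part` is already gene-keyed, otherwise required.
#' @param background universe of symbols; defaults to the observed genes.
#' @return data.frame (class `enrichment_result`) with `module`, `set_name`,
#'   `k` (overlap), `n` (module size), `K` (set size in background), `N`
#'   (background size), `odds_ratio`, `p` (one-tailed) and `fdr`.
#' @export
fisher_enrichment <- function(part, sets, gene_symbols = NULL,
                              background = NULL) {
  genes2mod <- partition_gene_modules(part, gene_symbols)
  if (is.null(background)) background <- names(genes2mod)
  background <- unique(toupper(background))
  outside <- setdiff(names(genes2mod), background)
  if (length(outside)) {
    wp_log("%d gene(s) outside the background excluded from ORA",
           length(outside))
    genes2mod <- genes2mod[!names(genes2mod) %in% outside]
  }
  N <- length(background)
  mods <- setdiff(unique(genes2mod), "unassigned")
  mods <- mods[order(as.integer(sub("^M", "", mods)))]
  rows <- list()
  for (m in mods) {
    mod_genes <- names(genes2mod)[genes2mod == m]
    n <- length(mod_genes)
    for (s in names(sets)) {
      set_genes <- intersect(unique(toupper(sets[[s]])), background)
      K <- length(set_genes)
      k <- length(intersect(mod_genes, set_genes))
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, set_name = s, k = k, n = n, K = K, N = N,
        odds_ratio = if ((K - k) * (n - k) == 0) Inf else
          (k * (N - K - n + k)) / ((K - k) * (n - k)),
        p = hyper_upper_p(k, K, n, N), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# normalize a partition-like input into a gene -> module named vector;
# one-to-many protein-to-symbol rows collapse to the first occurrence
partition_gene_modules <- function(part, gene_symbols = NULL) {
  if (inherits(part, "module_partition")) {
    assignment <- part$assignment
    if (is.null(gene_symbols))
      stopf("gene_symbols are required with a module_partition")
    genes <- toupper(unname(gene_symbols[names(assignment)]))
  } else {
    assignment <- part
    genes <- toupper(names(part))
  }
  keep <- !duplicated(genes) & !is.na(genes) & genes != ""
  stats::setNames(unname(assignment)[keep], genes[keep])
}

#' Cross-network module over-representation
#'
#' Relates two module partitions defined on overlapping gene universes
#' (e.g. a membrane-fractionated and an unfractionated brain network).
#' The shared gene universe is the intersection of the two partitions'
#' symbols; per module pair a hypergeometric upper-tail p is computed on
#' the 2x2 overlap table, Benjamini-Hochberg FDR is applied over all pairs,
#' and a positive signed `-log10(FDR p)` (positive when the overlap exceeds
#' its expectation, negative otherwise) is reported. Fisher 95% confidence
#' intervals for the odds ratio are included per pair.
#'
#' @param part_a,part_b `module_partition`s or gene-keyed label vectors
#'   (rows of the result follow `part_a`).
#' @param genes_a,genes_b gene symbols per protein when passing
#'   `module_partition`s.
#' @return list (class `overlap_matrix`) with matrices `counts`, `p`,
#'   `fdr`, `signed_log10_fdr`, the `universe` size, and `table` (long-form
#'   data.frame including odds-ratio confidence intervals).
#' @export
cross_network_overlap <- function(part_a, part_b, genes_a = NULL,
                                  genes_b = NULL) {
  a <- partition_gene_modules(part_a, genes_a)
  b <- partition_gene_modules(part_b, genes_b)
  a <- a[a != "unassigned"]
  b <- b[b != "unassigned"]
  universe <- intersect(names(a), names(b))
  if (!length(universe)) stopf("empty shared gene universe")
  wp_log("cross-network ORA universe: %d shared genes", length(universe))
  a <- a[universe]; b <- b[universe]
  mods_a <- sort_modules(unique(a))
  mods_b <- sort_modules(unique(b))
  N <- length(universe)
  cnt <- p <- matrix(NA_real_, length(mods_a), length(mods_b),
                     dimnames = list(mods_a, mods_b))
  rows <- list()
  for (ma in mods_a) {
    for (mb in mods_b) {
      k <- sum(a == ma & b == mb)
      n <- sum(a == ma)
      K <- sum(b == mb)
      cnt[ma, mb] <- k
      p[ma, mb] <- hyper_upper_p(k, K, n, N)
      ft <- stats::fisher.test(matrix(c(k, n - k, K - k, N - K - n + k), 2),
                               alternative = "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        module_a = ma, module_b = mb, k = k, n = n, K = K, N = N,
        odds_ratio = unname(ft$estimate),
        ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
        p = p[ma, mb], stringsAsFactors = FALSE)
    }
  }
  fdr <- matrix(bh_fdr(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  expected <- outer(rowSums(cnt), colSums(cnt)) / N
  signed <- sign(cnt - expected) * -log10(pmax(fdr, .Machine$double.xmin))
  tab <- do.call(rbind, rows)
  tab$fdr <- fdr[cbind(tab$module_a, tab$module_b)]
  structure(list(counts = cnt, p = p, fdr = fdr,
                 signed_log10_fdr = signed, universe = N, table = tab),
            class = "overlap_matrix")
}

sort_modules <- function(mods) {
  nums <- suppressWarnings(as.integer(sub("^M", "", mods)))
  if (anyNA(nums)) sort(mods) else mods[order(nums)]
}
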