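# Dynamic hybrid tree cut.
#
# Modules are branches of the average-linkage dendrogram of 1 - TOM.
# Objects merging above `cut_height` are separated statically; below it,
# branches are split recursively at their top internal merge whenever BOTH
# sub-branches look like genuine clusters:
#   * size >= min_module_size,
#   * core scatter (mean attachment height of the most tightly attached
#     min_module_size members) below a deep-split-dependent ceiling,
#   * gap between the sub-branch's completion height and the merge that
#     joins it to its sibling above a deep-split-dependent floor.
# deep_split 0..4 maps to progressively permissive (core scatter, gap)
# presets, so higher values carve the tree into more, smaller modules.
# A PAM-like stage then assigns leftover objects to the nearest module
# medoid, by default only to modules on the object's own static branch.

# relative (core scatter ceiling, gap floor) presets indexed by deep_split
deep_split_presets <- function(deep_split) {
  mcs <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1L]
  list(max_core_scatter = mcs, min_gap = (1 - mcs) * 3 / 4)
}

# height at which each leaf first merges into the tree
leaf_attach_heights <- function(hc) {
  n <- length(hc$order)
  att <- rep(NA_real_, n)
  for (m in seq_len(nrow(hc$merge))) {
    for (s in 1:2) {
      v <- hc$merge[m, s]
      if (v < 0) att[-v] <- hc$height[m]
    }
  }
  att
}

# hybrid cut of an hclust tree; returns integer labels, 0 = unassigned.
#
# Branches are grown bottom-up over the merge list (heights nondecreasing).
# A branch is "simple" while it contains no finalized cluster. When two
# simple branches meet and BOTH satisfy the cluster criteria at the merge
# height, both are finalized as clusters and the union becomes a composite;
# simple material joining a composite is finalized if it qualifies and
# otherwise becomes leftover for the PAM stage. Merges above cut_height
# never combine branches.
cutree_hybrid <- function(hc, diss, deep_split = 4L, min_module_size = 20L,
                          cut_height = NULL, pam_stage = TRUE,
                          pam_respects_dendro = TRUE, max_pam_dist = NULL) {
  n <- length(hc$order)
  h <- hc$height
  if (is.null(cut_height)) cut_height <- 0.99 * max(h)
  if (is.null(max_pam_dist)) max_pam_dist <- cut_height
  base <- stats::quantile(h, 0.05, names = FALSE)
  preset <- deep_split_presets(deep_split)
  span <- max(cut_height - base, 0)
  max_abs_scatter <- base + preset$max_core_scatter * span
  min_abs_gap <- preset$min_gap * span

  attach_h <- leaf_attach_heights(hc)

  # branch records, indexed by id; node -> branch id maps for leaves/merges
  branches <- list()
  leaf_branch <- integer(n)
  merge_branch <- integer(n - 1L)
  clusters <- list()

  new_branch <- function(members, top, composite = FALSE) {
    branches[[length(branches) + 1L]] <<- list(members = members, top = top,
                                               composite = composite)
    length(branches)
  }
  get_branch <- function(v) {
    if (v < 0) {
      id <- leaf_branch[-v]
      if (id == 0L) {
        id <- new_branch(-v, 0)
        leaf_branch[-v] <<- id
      }
      id
    } else merge_branch[v]
  }
  # criteria use the branch core: the min_module_size members that attached
  # lowest. Core scatter is their mean attachment height; the gap is
  # measured from the height at which the core was complete, so late-joining
  # stragglers cannot mask a genuine branch boundary.
  qualifies <- function(b, htop) {
    br <- branches[[b]]
    if (br$composite || length(br$members) < min_module_size) return(FALSE)
    core <- sort(attach_h[br$members])[seq_len(min(min_module_size,
                                                   length(br$members)))]
    mean(core) <= max_abs_scatter && (htop - max(core)) >= min_abs_gap
  }
  # a simple branch large enough becomes a cluster when its context ends
  finalize <- function(b) {
    br <- branches[[b]]
    if (!br$composite && length(br$members) >= min_module_size)
      clusters[[length(clusters) + 1L]] <<- br$members
  }
  make_cluster <- function(b) clusters[[length(clusters) + 1L]] <<-
    branches[[b]]$members

  for (m in seq_len(n - 1L)) {
    b1 <- get_branch(hc$merge[m, 1L])
    b2 <- get_branch(hc$merge[m, 2L])
    hm <- h[m]
    if (hm > cut_height) {
      # static separation: close both sides, keep bookkeeping only
      finalize(b1); finalize(b2)
      merge_branch[m] <- new_branch(c(branches[[b1]]$members,
                                      branches[[b2]]$members),
                                    hm, composite = TRUE)
      next
    }
    comp1 <- branches[[b1]]$composite
    comp2 <- branches[[b2]]$composite
    if (!comp1 && !comp2) {
      if (qualifies(b1, hm) && qualifies(b2, hm)) {
        make_cluster(b1); make_cluster(b2)
        merge_branch[m] <- new_branch(c(branches[[b1]]$members,
                                        branches[[b2]]$members),
                                      hm, composite = TRUE)
      } else {
        merge_branch[m] <- new_branch(c(branches[[b1]]$members,
                                        branches[[b2]]$members), hm)
      }
    } else {
      # simple material joining a finalized complex: keep it if it stands
      # on its own, otherwise leave it for the PAM stage
      if (!comp1 && qualifies(b1, hm)) make_cluster(b1)
      if (!comp2 && qualifies(b2, hm)) make_cluster(b2)
      merge_branch[m] <- new_branch(c(branches[[b1]]$members,
                                      branches[[b2]]$members),
                                    hm, composite = TRUE)
    }
  }
  finalize(merge_branch[n - 1L])

  labels <- integer(n)
  nxt <- 1L
  for (cl in clusters) {
    if (length(cl) >= min_module_size) {
      labels[cl] <- nxt
      nxt <- nxt + 1L
    }
  }

  if (pam_stage && nxt > 1L) {
    static <- stats::cutree(hc, h = cut_height)
    sizes <- tabulate(labels, nbins = nxt - 1L)
    medoids <- vapply(seq_len(nxt - 1L), function(k) {
      idx <- which(labels == k)
      idx[which.min(colSums(diss[idx, idx, drop = FALSE]))]
    }, integer(1))
    for (u in which(labels == 0L)) {
      cand <- seq_len(nxt - 1L)
      if (pam_respects_dendro)
        cand <- cand[static[medoids] == static[u]]
      if (!length(cand)) next
      d <- diss[u, medoids[cand]]
      best <- min(d)
      if (best >= max_pam_dist) next
      hit <- cand[d == best]
      if (length(hit) > 1L) hit <- hit[which.max(sizes[hit])]  # tie: larger
      labels[u] <- hit
    }
  }
  labels
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Clusters proteins by average-linkage hierarchical clustering of the
#' dissimilarity `1 - TOM` and extracts modules with a dynamic hybrid tree
#' cut (adaptive branch splitting governed by `deep_split`, minimum module
#' size enforced) followed by a PAM-like stage that assigns borderline or
#' left-over proteins to the nearest module medoid, by default only within
#' the protein's own dendrogram branch. Proteins assignable to no module are
#' labeled `"unassigned"`.
#'
#' @param tom topological overlap (or any similarity) matrix in \[0, 1\] with
#'   unit diagonal and row/column names.
#' @param params a [network_params] object.
#' @return a `module_partition`: list with `assignment` (named character
#'   vector of labels `"M1"`, `"M2"`, ... ordered by decreasing module size,
#'   plus `"unassigned"`), `dendrogram` (the `hclust` tree), `stage`
#'   (`"initial"`) and `params`.
#' @export
detect_modules <- function(tom, params = network_params()) {
  n <- nrow(tom)
  ids <- rownames(tom) %||% paste0("P", seq_len(n))
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  hc$labels <- ids
  if (n <= params$min_module_size) {
    warning(sprintf("%d proteins cannot form a module of size >= %d; all unassigned",
                    n, params$min_module_size), call. = FALSE)
    lab <- rep(0L, n)
  } else if (max(hc$height) - min(hc$height) < 1e-12) {
    warning("degenerate dissimilarity: all merge heights equal", call. = FALSE)
    lab <- if (n >= params$min_module_size) rep(1L, n) else rep(0L, n)
  } else {
    lab <- cutree_hybrid(hc, diss,
                         deep_split = params$deep_split,
                         min_module_size = params$min_module_size,
                         cut_height = params$cut_height,
                         pam_respects_dendro = params$pam_respects_dendro)
  }
  assignment <- rank_module_labels(lab, ids)
  structure(list(assignment = assignment, dendrogram = hc,
                 stage = "initial", params = params),
            class = "module_partition")
}

# order modules by decreasing size (ties: alphabetically first member id)
# and name them M1..Mk; 0/"unassigned" stays "unassigned"
rank_module_labels <- function(lab, ids) {
  if (is.character(lab)) {
    out <- lab
    mods <- setdiff(unique(lab), "unassigned")
  } else {
    out <- ifelse(lab == 0L, "unassigned", paste0("c", lab))
    mods <- setdiff(unique(out), "unassigned")
  }
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(out == m), integer(1))
    first <- vapply(mods, function(m) min(ids[out == m]), character(1))
    ord <- mods[order(-sizes, first)]
    map <- stats::setNames(paste0("M", seq_along(ord)), ord)
    out[out != "unassigned"] <- map[out[out != "unassigned"]]
  }
  stats::setNames(out, ids)
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- table(x$assignment)
  mods <- setdiff(names(tab), "unassigned")
  cat(sprintf("module_partition (%s): %d modules over %d proteins, %d unassigned\n",
              x$stage, length(mods), length(x$assignment),
              sum(x$assignment == "unassigned")))
  invisible(x)
}

#' Module sizes of a partition
#' @param part a `module_partition`.
#' @param drop_unassigned drop the `"unassigned"` pool (default `TRUE`).
#' @return named integer vector of module sizes, largest first.
#' @export
module_sizes <- function(part, drop_unassigned = TRUE) {
  tab <- table(part$assignment)
  if (drop_unassigned) tab <- tab[names(tab) != "unassigned"]
  mods <- names(tab)
  tab <- as.integer(tab)
  names(tab) <- mods
  tab[order(-tab, as.integer(sub("^M", "", names(tab))))]
}

#' Export a module dendrogram in Newick format
#' @param part a `module_partition` carrying a dendrogram.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(part, path) {
  if (is.null(part$dendrogram)) stopf("partition carries no dendrogram")
  ape::write.tree(ape::as.phylo(part$dendrogram), file = path)
  wp_log("wrote dendrogram (%d leaves) to %s",
         length(part$dendrogram$order), path)
  invisible(path)
}
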