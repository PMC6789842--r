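# Programmatic fixtures shared across test files.

# peptide-table row builder
pep_row <- function(pep, group, sample, intensity, counts, unique = TRUE,
                    fraction = "membrane", gene = paste0("G_", group)) {
  data.frame(peptide_sequence = pep, protein_group = group,
             gene_symbol = gene, sample_id = sample, fraction = fraction,
             intensity = intensity, spectral_counts = counts,
             is_unique = unique, stringsAsFactors = FALSE)
}

# tiny three-group trait table
toy_traits <- function(n_per_group = 6, seed = 1) {
  set.seed(seed)
  n <- 3 * n_per_group
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    group = rep(c("control", "AsymAD", "AD"), each = n_per_group),
    age = runif(n, 75, 95), sex = sample(c("M", "F"), n, TRUE),
    pmi = runif(n, 2.5, 8.5),
    casi = rnorm(n, 85, 8), cerad = runif(n, 0, 3), braak = runif(n, 0, 6),
    stringsAsFactors = FALSE)
}

# block-structured TOM-like similarity with planted modules
block_tom <- function(sizes, within = 0.3, between = 0.01, noise = 0.002,
                      seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  tom <- matrix(between, n, n)
  start <- cumsum(c(1, sizes))
  for (b in seq_along(sizes)) {
    idx <- start[b]:(start[b] + sizes[b] - 1)
    tom[idx, idx] <- within
  }
  jit <- matrix(runif(n * n, -noise, noise), n, n)
  tom <- tom + (jit + t(jit)) / 2
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("P%03d", 1:n), sprintf("P%03d", 1:n))
  tom
}

# latent factors with an exact sample correlation matrix (n samples x k)
exact_cor_latents <- function(R, n, seed = 1) {
  set.seed(seed)
  k <- ncol(R)
  z <- matrix(rnorm(n * k), n, k)
  z <- scale(z, center = TRUE, scale = FALSE)
  z <- z %*% solve(chol(cov(z)))        # exactly decorrelated, unit variance
  z %*% chol(R)
}

# protein matrix whose modules follow given latent columns
latent_module_matrix <- function(latents, per_module = 20, noise_sd = 1e-3,
                                 seed = 1) {
  set.seed(seed)
  k <- ncol(latents)
  n <- nrow(latents)
  vals <- do.call(rbind, lapply(seq_len(k), function(m) {
    t(replicate(per_module, latents[, m] + rnorm(n, 0, noise_sd)))
  }))
  rownames(vals) <- sprintf("P%03d", seq_len(nrow(vals)))
  colnames(vals) <- sprintf("S%02d", seq_len(n))
  assignment <- setNames(rep(paste0("M", seq_len(k)), each = per_module),
                         rownames(vals))
  list(pm = protein_matrix(vals, is_log2 = TRUE),
       partition = structure(list(assignment = assignment, stage = "truth"),
                             class = "module_partition"))
}
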