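test_that("eigenprotein of a rank-1 module recovers the common profile", {
  set.seed(41)
  v <- rnorm(12)
  lat <- matrix(v, 1)
  fx <- latent_module_matrix(t(lat), per_module = 15, noise_sd = 1e-6, seed = 41)
  eig <- module_eigenproteins(fx$pm, fx$partition)
  ep <- eig$values["M1", ]
  expect_gt(abs(cor(ep, v)), 0.999999)
  expect_gt(eig$variance_explained[["M1"]], 0.999)
  expect_equal(sum(ep^2), 1, tolerance = 1e-10)     # unit norm
  # orientation: positively tracks the module mean profile
  z <- t(scale(t(fx$pm$values)))
  expect_gte(cor(ep, colMeans(z)), 0)
})

test_that("eigenproteins are invariant to protein order and flag degenerate input", {
  set.seed(42)
  lat <- exact_cor_latents(diag(2), 14, seed = 42)
  fx <- latent_module_matrix(lat, per_module = 10, noise_sd = 0.3, seed = 42)
  eig1 <- module_eigenproteins(fx$pm, fx$partition)
  perm <- sample(nrow(fx$pm$values))
  pm2 <- protein_matrix(fx$pm$values[perm, ], is_log2 = TRUE)
  part2 <- fx$partition
  part2$assignment <- fx$partition$assignment[perm]
  eig2 <- module_eigenproteins(pm2, part2)
  expect_equal(eig1$values, eig2$values, tolerance = 1e-12)
  expect_true(all(eig1$variance_explained > 0 & eig1$variance_explained <= 1))
  # zero-variance module is an error naming the module
  flat <- protein_matrix(matrix(5, 4, 8, dimnames = list(paste0("p", 1:4),
                                                         paste0("s", 1:8))),
                         is_log2 = TRUE)
  partf <- structure(list(assignment = setNames(rep("M1", 4), paste0("p", 1:4)),
                          stage = "t"), class = "module_partition")
  expect_error(module_eigenproteins(flat, partf), "M1")
})

test_that("a module of anti-correlated halves still yields an oriented eigenprotein", {
  set.seed(43)
  v <- rnorm(16)
  up <- t(replicate(12, v + rnorm(16, 0, 0.05)))
  down <- t(replicate(4, -v + rnorm(16, 0, 0.05)))
  vals <- rbind(up, down)
  dimnames(vals) <- list(paste0("p", 1:16), paste0("s", 1:16))
  pm <- protein_matrix(vals, is_log2 = TRUE)
  part <- structure(list(assignment = setNames(rep("M1", 16), rownames(vals)),
                         stage = "t"), class = "module_partition")
  eig <- module_eigenproteins(pm, part)
  expect_true(eig$variance_explained[["M1"]] > 0 &&
                eig$variance_explained[["M1"]] <= 1)
  z <- t(scale(t(vals)))
  expect_gte(cor(eig$values["M1", ], colMeans(z)), 0)
})

test_that("kME equals 1 for a protein tracking its eigenprotein and its p-value is calibrated", {
  set.seed(44)
  v <- rnorm(18)
  fx <- latent_module_matrix(matrix(v, 18, 1), per_module = 10,
                             noise_sd = 1e-9, seed = 44)
  eig <- module_eigenproteins(fx$pm, fx$partition)
  kme <- compute_kme(fx$pm, eig)
  expect_true(all(abs(kme$kme[, "M1"]) > 0.999999))
  expect_true(all(kme$p[, "M1"] < 1e-10))
  # orthogonal profile: r ~ 0 gives p ~ 1
  ep <- eig$values["M1", ]
  orth <- residuals(lm(rnorm(18) ~ ep))
  vals2 <- rbind(fx$pm$values, orth = orth)
  pm2 <- protein_matrix(vals2, is_log2 = TRUE)
  kme2 <- compute_kme(pm2, eig)
  expect_lt(abs(kme2$kme["orth", "M1"]), 1e-10)
  expect_equal(unname(kme2$p["orth", "M1"]), 1, tolerance = 1e-8)
  expect_error(compute_kme(protein_matrix(fx$pm$values[, 1:2], is_log2 = TRUE),
                           eig), "samples")
})

test_that("kME p from the t transform matches a permutation oracle at r ~ 0.7", {
  set.seed(45)
  n <- 18
  x <- rnorm(n)
  y <- 0.7 * x + sqrt(1 - 0.49) * rnorm(n)
  r <- cor(x, y)
  p_t <- wpcna:::cor_pvalue(r, n)
  p_perm <- mean(replicate(50000, abs(cor(x, sample(y))) >= abs(r) - 1e-12))
  expect_lt(abs(p_t - p_perm), 0.006)
  expect_equal(p_t, cor.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("modules with nearly identical eigenproteins are merged, distinct ones kept", {
  R <- matrix(c(1, 0.96, 0.3,
                0.96, 1, 0.3,
                0.3, 0.3, 1), 3, 3)
  lat <- exact_cor_latents(R, 40, seed = 46)
  fx <- latent_module_matrix(lat, per_module = 12, noise_sd = 1e-4, seed = 46)
  merged <- merge_modules(fx$pm, fx$partition, cut_height = 0.07)
  sizes <- module_sizes(merged$partition)
  expect_equal(unname(sizes), c(24L, 12L))
  expect_equal(merged$partition$stage, "merged")
  # well-separated modules (cor 0.5) stay apart
  R2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  lat2 <- exact_cor_latents(R2, 40, seed = 47)
  fx2 <- latent_module_matrix(lat2, per_module = 10, noise_sd = 1e-4, seed = 47)
  merged2 <- merge_modules(fx2$pm, fx2$partition, cut_height = 0.07)
  expect_equal(length(module_sizes(merged2$partition)), 2L)
})

test_that("chained eigenprotein similarity merges transitively across iterations", {
  # pairwise dissimilarities ~ {0.04, 0.04, 0.11}: one cutree pass joins only
  # the closest pair; the recomputed joint eigenprotein then captures the third
  R <- matrix(c(1, 0.96, 0.89,
                0.96, 1, 0.96,
                0.89, 0.96, 1), 3, 3)
  lat <- exact_cor_latents(R, 60, seed = 48)
  fx <- latent_module_matrix(lat, per_module = 15, noise_sd = 1e-4, seed = 48)
  # manual trace, step 1: average-linkage cutree at 0.07 groups only two
  me <- module_eigenproteins(fx$pm, fx$partition)
  d1 <- 1 - cor(t(me$values))
  grp1 <- cutree(hclust(as.dist(d1), "average"), h = 0.07)
  expect_equal(max(grp1), 2L)
  merged <- merge_modules(fx$pm, fx$partition, cut_height = 0.07)
  expect_equal(length(module_sizes(merged$partition)), 1L)
  expect_equal(unname(module_sizes(merged$partition)), 45L)
})

test_that("reassignment returns planted mislabels to their true module", {
  set.seed(49)
  lat <- exact_cor_latents(matrix(c(1, 0.2, 0.2, 1), 2), 20, seed = 49)
  fx <- latent_module_matrix(lat, per_module = 30, noise_sd = 0.25, seed = 49)
  truth <- fx$partition$assignment
  corrupted <- fx$partition
  moved_ids <- names(truth)[truth == "M1"][1:10]
  corrupted$assignment[moved_ids] <- "M2"
  res <- reassign_low_kme(fx$pm, corrupted, reassign_p = 0.05)
  back <- res$partition$assignment
  # labels are re-ranked by size; identify the module holding most of true M1
  m1_label <- names(which.max(table(back[truth == "M1"])))
  expect_gte(sum(back[moved_ids] == m1_label), 8)
  # no correctly labeled protein may move
  stay_ids <- setdiff(names(truth), moved_ids)
  m2_label <- names(which.max(table(back[truth == "M2"])))
  expect_true(all(back[intersect(stay_ids, names(truth)[truth == "M2"])] ==
                    m2_label))
  expect_equal(res$partition$stage, "reassigned")
})

test_that("a hub protein with significant own-module kME is never reassigned", {
  set.seed(50)
  lat <- exact_cor_latents(diag(2), 20, seed = 50)
  fx <- latent_module_matrix(lat, per_module = 25, noise_sd = 0.2, seed = 50)
  res <- reassign_low_kme(fx$pm, fx$partition, reassign_p = 0.05)
  expect_equal(res$n_moved, 0L)
})

test_that("kME pruning unassigns chance passengers but keeps genuine members", {
  set.seed(51)
  lat <- exact_cor_latents(diag(2), 18, seed = 51)
  fx <- latent_module_matrix(lat, per_module = 25, noise_sd = 0.2, seed = 51)
  vals <- rbind(fx$pm$values,
                noise1 = rnorm(18), noise2 = rnorm(18))
  pm <- protein_matrix(vals, is_log2 = TRUE)
  part <- fx$partition
  part$assignment <- c(fx$partition$assignment,
                       setNames(c("M1", "M2"), c("noise1", "noise2")))
  res <- prune_low_kme(pm, part, p_threshold = 0.05)
  expect_true(all(res$partition$assignment[c("noise1", "noise2")] == "unassigned" |
                    res$n_pruned <= 2))
  genuine <- names(fx$partition$assignment)
  expect_true(all(res$partition$assignment[genuine] != "unassigned"))
})
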