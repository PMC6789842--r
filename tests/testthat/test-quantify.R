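test_that("protein-group filter requires a unique peptide and two spectral matches", {
  # five groups: total counts 1,2,2,5,9; unique peptides 1,0,1,1,1
  tab <- rbind(
    pep_row("AAA", "G1", "S1", 10, 1, unique = TRUE),
    pep_row("BBB", "G2", "S1", 10, 2, unique = FALSE),
    pep_row("CCC", "G3", "S1", 10, 2, unique = TRUE),
    pep_row("DDD", "G4", "S1", 10, 3, unique = TRUE),
    pep_row("EEE", "G4", "S2", 10, 2, unique = FALSE),
    pep_row("FFF", "G5", "S1", 10, 9, unique = TRUE))
  kept <- filter_protein_groups(tab)
  expect_setequal(kept, c("G3", "G4", "G5"))

  # boundary: exactly 1 unique peptide and 2 total counts is retained
  expect_equal(filter_protein_groups(pep_row("AAA", "GX", "S1", 5, 2)), "GX")
  # shared-only peptides are removed regardless of counts
  shared <- rbind(pep_row("AAA", "GY", "S1", 5, 20, unique = FALSE),
                  pep_row("BBB", "GY", "S1", 5, 20, unique = FALSE))
  expect_length(filter_protein_groups(shared), 0)
})

test_that("empty peptide table yields an empty set with a log message", {
  empty <- pep_row("A", "G", "S", 1, 1)[0, ]
  withr::local_options(wpcna.quiet = FALSE)
  expect_message(res <- filter_protein_groups(empty), "no protein groups")
  expect_length(res, 0)
})

test_that("top-3 abundance is the mean of the three most intense peptides", {
  tab <- rbind(pep_row("A", "G1", "S1", 10, 1), pep_row("B", "G1", "S1", 5, 1),
               pep_row("C", "G1", "S1", 3, 1), pep_row("D", "G1", "S1", 1, 1))
  pm <- top3_protein_abundance(tab, log2_transform = FALSE)
  expect_equal(unname(pm$values["G1", "S1"]), 6)

  # fewer than three peptides: mean of the available ones, count recorded
  tab2 <- rbind(pep_row("A", "G1", "S1", 8, 1), pep_row("B", "G1", "S1", 4, 1))
  pm2 <- top3_protein_abundance(tab2, log2_transform = FALSE)
  expect_equal(unname(pm2$values["G1", "S1"]), 6)
  expect_equal(unname(attr(pm2, "n_peptides")["G1", "S1"]), 2L)
})

test_that("top-3 abundance matches per-cell brute force on a toy table", {
  set.seed(7)
  rows <- list()
  for (g in paste0("G", 1:4)) for (s in c("S1", "S2")) {
    np <- sample(1:6, 1)
    for (p in seq_len(np))
      rows[[length(rows) + 1L]] <-
        pep_row(sprintf("%s_p%d", g, p), g, s, round(runif(1, 0, 100), 2), 1)
  }
  tab <- do.call(rbind, rows)
  pm <- top3_protein_abundance(tab, log2_transform = FALSE)
  for (g in paste0("G", 1:4)) for (s in c("S1", "S2")) {
    v <- tab$intensity[tab$protein_group == g & tab$sample_id == s]
    v <- sort(v[v > 0], decreasing = TRUE)
    expected <- if (length(v)) mean(v[seq_len(min(3, length(v)))]) else NA_real_
    expect_equal(unname(pm$values[g, s]), expected)
  }
})

test_that("quantification is invariant to row order and equivariant to scaling", {
  set.seed(8)
  rows <- list()
  for (g in paste0("G", 1:5)) for (s in c("S1", "S2", "S3")) {
    for (p in 1:4)
      rows[[length(rows) + 1L]] <-
        pep_row(sprintf("%s_p%d", g, p), g, s, runif(1, 1, 50), 1)
  }
  tab <- do.call(rbind, rows)
  pm1 <- top3_protein_abundance(tab, log2_transform = FALSE)
  pm2 <- top3_protein_abundance(tab[sample(nrow(tab)), ], log2_transform = FALSE)
  expect_identical(pm1$values, pm2$values)

  # scaling all intensities of one sample by k scales that column by k
  tab3 <- tab
  tab3$intensity[tab3$sample_id == "S2"] <- 3.5 * tab3$intensity[tab3$sample_id == "S2"]
  pm3 <- top3_protein_abundance(tab3, log2_transform = FALSE)
  expect_equal(pm3$values[, "S2"], 3.5 * pm1$values[, "S2"])
  expect_equal(pm3$values[, "S1"], pm1$values[, "S1"])
})

test_that("zero-intensity cells are missing and dead proteins are dropped", {
  tab <- rbind(pep_row("A", "G1", "S1", 10, 1), pep_row("A", "G1", "S2", 0, 1),
               pep_row("B", "G2", "S1", 0, 1), pep_row("B", "G2", "S2", 0, 1))
  pm <- top3_protein_abundance(tab, log2_transform = FALSE)
  expect_true(is.na(pm$values["G1", "S2"]))
  expect_false("G2" %in% rownames(pm$values))
})

test_that("membrane enrichment profile bins ranked ratios into near-equal deciles", {
  # 20 proteins with designed membrane/soluble counts
  rows <- list()
  for (i in 1:20) {
    g <- sprintf("G%02d", i)
    rows[[length(rows) + 1L]] <- pep_row(paste0(g, "_p"), g, "S1",
                                         10, i + 2, fraction = "membrane",
                                         gene = g)
    rows[[length(rows) + 1L]] <- pep_row(paste0(g, "_q"), g, "S1",
                                         10, 23 - i, fraction = "soluble",
                                         gene = g)
  }
  tab <- do.call(rbind, rows)
  prof <- membrane_enrichment_profile(tab,
    class_map = list(membrane = sprintf("G%02d", 11:20),
                     cytoplasmic = sprintf("G%02d", 1:10)))
  expect_equal(prof$profile$n_proteins, rep(2L, 10))
  # hand oracle: rank by log2((m + .5)/(s + .5)), cut in pairs
  ratio <- log2((1:20 + 2 + 0.5) / (23 - (1:20) + 0.5))
  expected_means <- colMeans(matrix(sort(ratio), nrow = 2))
  expect_equal(prof$profile$mean_log2_ratio, expected_means)
  # class fractions sum to one; all-enriched class reports fraction 1
  expect_equal(unname(rowSums(prof$class_fractions)), c(1, 1))
  expect_equal(unname(prof$enriched_fraction["membrane"]), 1)
  # equal counts give ratio zero
  eq <- rbind(pep_row("Z_p", "Z", "S1", 1, 5, fraction = "membrane", gene = "Z"),
              pep_row("Z_q", "Z", "S1", 1, 5, fraction = "soluble", gene = "Z"))
  p2 <- membrane_enrichment_profile(rbind(tab, eq))
  expect_equal(p2$ratios$ratio[p2$ratios$gene_symbol == "Z"], 0)
})

test_that("enrichment profile enforces fraction presence and count floor", {
  mem_only <- pep_row("A", "G1", "S1", 5, 10, fraction = "membrane")
  expect_error(membrane_enrichment_profile(mem_only), "soluble")
  # proteins under 3 total counts are excluded from the ranking
  rows <- list()
  for (i in 1:12) {
    g <- sprintf("G%02d", i)
    rows[[length(rows) + 1L]] <- pep_row(paste0(g, "_p"), g, "S1", 1, 4,
                                         fraction = "membrane", gene = g)
    rows[[length(rows) + 1L]] <- pep_row(paste0(g, "_q"), g, "S1", 1, 4,
                                         fraction = "soluble", gene = g)
  }
  low <- rbind(pep_row("L_p", "L", "S1", 1, 1, fraction = "membrane", gene = "L"),
               pep_row("L_q", "L", "S1", 1, 1, fraction = "soluble", gene = "L"))
  prof <- membrane_enrichment_profile(rbind(do.call(rbind, rows), low))
  expect_false("L" %in% prof$ratios$gene_symbol)
  expect_equal(sum(prof$profile$n_proteins), 12)
})
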