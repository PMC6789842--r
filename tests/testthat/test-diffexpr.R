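pm_from_rows <- function(rows, traits) {
  vals <- do.call(rbind, rows)
  rownames(vals) <- sprintf("P%02d", seq_along(rows))
  colnames(vals) <- traits$sample_id
  protein_matrix(vals, is_log2 = TRUE)
}

test_that("identical groups give F = 0, p = 1 and all Tukey p = 1", {
  traits <- toy_traits(n_per_group = 3, seed = 1)
  pm <- pm_from_rows(list(rep(5, 9)), traits)
  res <- anova_tukey(pm, traits)
  expect_equal(res$anova_F, 0)
  expect_equal(res$anova_p, 1)
  expect_equal(res$tukey_p_AD_vs_control, 1)
  expect_equal(res$tukey_p_AsymAD_vs_control, 1)
  expect_equal(res$tukey_p_AD_vs_AsymAD, 1)
})

test_that("a separated third group is detected and matches stats::TukeyHSD", {
  traits <- toy_traits(n_per_group = 3, seed = 2)
  y <- c(1, 2, 3, 1, 2, 3, 7, 8, 9)   # control, AsymAD, AD
  pm <- pm_from_rows(list(y), traits)
  res <- anova_tukey(pm, traits)
  expect_lt(res$anova_p, 0.001)
  expect_lt(res$tukey_p_AD_vs_control, 0.01)
  expect_gt(res$tukey_p_AsymAD_vs_control, 0.95)
  # independent route: aov + TukeyHSD
  fit <- aov(y ~ g, data = data.frame(y = y, g = factor(rep(c("control",
    "AsymAD", "AD"), each = 3), levels = c("control", "AsymAD", "AD"))))
  tk <- TukeyHSD(fit)$g
  expect_equal(res$tukey_p_AsymAD_vs_control,
               tk["AsymAD-control", "p adj"], tolerance = 1e-8)
  expect_equal(res$tukey_p_AD_vs_control,
               tk["AD-control", "p adj"], tolerance = 1e-8)
  expect_equal(res$tukey_p_AD_vs_AsymAD,
               tk["AD-AsymAD", "p adj"], tolerance = 1e-8)
  expect_equal(unname(summary(fit)[[1]]$`F value`[1]), res$anova_F,
               tolerance = 1e-10)
})

test_that("log2 difference is the plain group-mean difference in fixed order", {
  traits <- toy_traits(n_per_group = 2, seed = 3)
  y <- c(3, 3, 5, 5, 4, 4)            # control 3, AsymAD 5, AD 4
  res <- anova_tukey(pm_from_rows(list(y), traits), traits)
  expect_equal(res$log2_diff_AsymAD_vs_control, 2)
  expect_equal(res$log2_diff_AD_vs_control, 1)
  expect_equal(res$log2_diff_AD_vs_AsymAD, -1)
})

test_that("Tukey p is never below the unadjusted pairwise t-test p (balanced)", {
  set.seed(4)
  traits <- toy_traits(n_per_group = 5, seed = 4)
  for (i in 1:20) {
    y <- rnorm(15, rep(c(0, 0.6, 1.1), each = 5))
    res <- anova_tukey(pm_from_rows(list(y), traits), traits)
    tt <- t.test(y[1:5], y[6:10], var.equal = TRUE)$p.value
    expect_gte(res$tukey_p_AsymAD_vs_control + 1e-12, tt)
  }
})

test_that("ANOVA p is invariant under shifting and rescaling", {
  traits <- toy_traits(n_per_group = 4, seed = 5)
  set.seed(5)
  y <- rnorm(12, rep(c(0, 1, 2), each = 4))
  a <- anova_tukey(pm_from_rows(list(y), traits), traits)
  b <- anova_tukey(pm_from_rows(list(10 + 3 * y), traits), traits)
  expect_equal(a$anova_p, b$anova_p, tolerance = 1e-12)
  expect_equal(a$tukey_p_AD_vs_control, b$tukey_p_AD_vs_control,
               tolerance = 1e-12)
})

test_that("degenerate proteins are flagged rather than mis-tested", {
  traits <- toy_traits(n_per_group = 3, seed = 6)
  # zero within-group variance, separated means
  res <- anova_tukey(pm_from_rows(list(rep(c(1, 2, 3), each = 3)), traits),
                     traits)
  expect_equal(res$anova_F, Inf)
  expect_equal(res$anova_p, 0)
  expect_equal(res$reason, "zero_within_variance")
  # too many missing values
  y <- c(NA, NA, NA, NA, NA, NA, NA, 1, 2)
  res2 <- anova_tukey(pm_from_rows(list(y), traits), traits)
  expect_true(is.na(res2$anova_p))
  expect_equal(res2$reason, "insufficient_observations")
  # single-group input errors
  tr1 <- toy_traits(n_per_group = 3, seed = 7)
  tr1$group <- "AD"
  pm1 <- pm_from_rows(list(rnorm(9)), tr1)
  expect_error(anova_tukey(pm1, tr1), "two diagnosis groups")
})

test_that("significant sets and Venn regions match exhaustive enumeration", {
  traits <- toy_traits(n_per_group = 3, seed = 8)
  # synthesize a diffexpr table directly
  set.seed(8)
  tab <- data.frame(protein_id = sprintf("P%02d", 1:10))
  tab$tukey_p_AsymAD_vs_control <- runif(10)
  tab$tukey_p_AD_vs_control <- runif(10)
  tab$tukey_p_AD_vs_AsymAD <- runif(10)
  res <- significant_sets(tab, alpha = 0.4)
  sets <- lapply(c("tukey_p_AsymAD_vs_control", "tukey_p_AD_vs_control",
                   "tukey_p_AD_vs_AsymAD"),
                 function(cl) tab$protein_id[tab[[cl]] < 0.4])
  expect_equal(res$union_count, length(unique(unlist(sets))))
  expect_equal(sum(res$venn), res$union_count)
  # region counts by brute force over all membership patterns
  for (nm in names(res$venn)) {
    inset <- strsplit(nm, "&", fixed = TRUE)[[1]]
    cmps <- names(res$sets)
    ids <- Reduce(intersect, res$sets[inset])
    for (out in setdiff(cmps, inset)) ids <- setdiff(ids, res$sets[[out]])
    expect_equal(unname(res$venn[nm]), length(ids))
  }
  # thresholding one protein with p {0.01, 0.2, 0.04} at alpha 0.05
  one <- data.frame(protein_id = "X",
                    tukey_p_AsymAD_vs_control = 0.01,
                    tukey_p_AD_vs_control = 0.2,
                    tukey_p_AD_vs_AsymAD = 0.04)
  r1 <- significant_sets(one, 0.05)
  expect_equal(r1$sets$AsymAD_vs_control, "X")
  expect_equal(r1$sets$AD_vs_control, character(0))
  expect_equal(r1$sets$AD_vs_AsymAD, "X")
  # all p = 1: empty everywhere
  none <- data.frame(protein_id = "X", tukey_p_AsymAD_vs_control = 1,
                     tukey_p_AD_vs_control = 1, tukey_p_AD_vs_AsymAD = 1)
  expect_equal(significant_sets(none, 0.05)$union_count, 0)
})
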