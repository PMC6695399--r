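norm_em <- function(signals, ...) make_em(signals, is_log2 = TRUE,
                                          normalized = TRUE, ...)

test_that("log2 fold change is the difference of group means", {
  em <- norm_em(sig(c(3, 3, 5, 5), c(2, 2, 2, 2)))
  lfc <- log2_fold_changes(em)
  expect_equal(unname(lfc), c(2, 0))
  expect_named(lfc, c("F1", "F2"))
  expect_error(log2_fold_changes(em, group2 = "substate3"),
               "no samples")
  linear <- make_em(sig(c(1, 1, 4, 4)))
  expect_error(log2_fold_changes(linear), "log2")
})

test_that("zscore_select standardizes the fold-change distribution", {
  res <- zscore_select(c(A = 1, B = 2, C = 3), z_threshold = 1)
  expect_equal(res$table$z, c(-1, 0, 1))
  expect_equal(res$up_set, "C")
  expect_equal(res$down_set, "A")
  expect_equal(res$thresholds$fc_mean, 2)
  expect_equal(res$thresholds$fc_sd, 1)

  # location invariance: shifting all fold changes leaves z untouched
  set.seed(1)
  fc <- setNames(rnorm(100), paste0("g", 1:100))
  r1 <- zscore_select(fc, 2)
  r2 <- zscore_select(fc + 5, 2)
  expect_equal(r1$table$z, r2$table$z)
  expect_equal(r1$up_set, r2$up_set)

  # feature order must not matter
  perm <- sample(length(fc))
  r3 <- zscore_select(fc[perm], 2)
  expect_setequal(r3$up_set, r1$up_set)
  expect_setequal(r3$down_set, r1$down_set)

  expect_error(zscore_select(c(a = 1, b = 1, c = 1)), "degenerate")
  expect_error(zscore_select(c(a = 1, b = 2)), "at least 3")
})

test_that("z threshold 2 calls about the normal two-tail mass", {
  set.seed(2024)
  fc <- setNames(rnorm(10000), paste0("g", 1:10000))
  res <- zscore_select(fc, 2)
  frac <- (length(res$up_set) + length(res$down_set)) / 10000
  expect_gt(frac, 0.035)   # 2 * pnorm(-2) = 0.0455
  expect_lt(frac, 0.056)
})

test_that("paired t matches the closed form and t.test", {
  # paired differences [1, 2, 3]: t = 2 / (1 / sqrt(3)) = 3.4641,
  # two-sided p with 2 df = 0.0742
  em <- norm_em(sig(c(0, 0, 0, 1, 2, 3), c(5, 5, 5, 5, 5, 5)))
  tt <- paired_ttest(em)
  expect_equal(tt$t_stat[1], 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(tt$t_stat[1], 3.4641, tolerance = 1e-4)
  expect_equal(tt$p[1], 0.0742, tolerance = 1e-3)
  oracle <- t.test(c(1, 2, 3), c(0, 0, 0), paired = TRUE)
  expect_equal(tt$t_stat[1], unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(tt$p[1], oracle$p.value, tolerance = 1e-10)
  # all-zero differences: p = 1
  expect_equal(tt$p[2], 1)
  expect_equal(tt$t_stat[2], 0)
})

test_that("paired t handles degenerate variance and bad pairing", {
  em <- norm_em(sig(c(0, 0, 0, 1, 1, 1)))
  expect_warning(tt <- paired_ttest(em), "zero-variance")
  expect_equal(tt$p[1], 0)

  bad <- norm_em(sig(c(1, 2, 3, 4)))
  bad$sample_meta$replicate <- c(1, 2, 3, 4)
  expect_error(paired_ttest(bad), "unpairable")
})

test_that("row-wise paired t agrees with t.test on random matrices", {
  set.seed(5)
  s <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(paste0("F", 1:50), NULL))
  em <- norm_em(s)
  tt <- paired_ttest(em)
  for (i in c(1, 17, 50)) {
    oracle <- t.test(s[i, 5:8], s[i, 1:4], paired = TRUE)
    expect_equal(tt$t_stat[i], unname(oracle$statistic),
                 tolerance = 1e-10)
    expect_equal(tt$p[i], oracle$p.value, tolerance = 1e-10)
  }
})

test_that("bh_fdr reproduces hand-computed q-values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_equal(bh_fdr(c(0.04, 0.5), "bonferroni"), c(0.08, 1))
})

test_that("mirna_de applies the fold filter before testing", {
  # F1 passes the 2-fold filter and is strongly significant;
  # F2 (log2FC = 0.8) must be excluded before any testing
  s <- sig(c(0, 0.1, -0.1, 2, 2.2, 1.8),
           c(0, 0.05, -0.05, 0.8, 0.85, 0.75),
           c(0, 0.1, -0.1, -1.5, -1.3, -1.7))
  em <- norm_em(s)
  res <- mirna_de(em, fold_threshold = 2, q_threshold = 0.05)
  expect_true(is.na(res$table$p[2]))
  expect_equal(res$table$call[2], "neither")
  expect_equal(res$up_set, "F1")
  expect_equal(res$down_set, "F3")
  # q-values computed over the tested subset only (2 features here)
  tested <- res$table[!is.na(res$table$p), ]
  expect_equal(sort(tested$q), sort(bh_brute(tested$p)))

  # fold_threshold 1 admits every feature
  all_in <- mirna_de(em, fold_threshold = 1)
  expect_false(anyNA(all_in$table$p))
})

test_that("swapping group labels swaps up and down calls exactly", {
  study <- generate_study(synthetic_config(
    n_genes = 50, n_mirnas = 40, n_de_mirnas_up = 6,
    n_de_mirnas_down = 6, n_de_genes_up = 5, n_de_genes_down = 5,
    n_biomarkers_up = 2, n_biomarkers_down = 1,
    targets_per_mirna = 5, seed = 8))
  em <- normalize_chips(study$mirna_cell,
                        normalization_spec(percentile = 99))
  fwd <- mirna_de(em)
  rev <- mirna_de(swap_groups(em))
  expect_setequal(fwd$up_set, rev$down_set)
  expect_setequal(fwd$down_set, rev$up_set)
  expect_equal(fwd$table$log2FC, -rev$table$log2FC)
})

test_that("empty post-filter subset yields a valid empty result", {
  em <- norm_em(sig(c(0, 0.1, -0.1, 0.2, 0.1, 0),
                    c(0, 0, 0, 0.1, 0, 0.1)))
  expect_warning(res <- mirna_de(em), "fold filter")
  expect_length(res$up_set, 0)
  expect_length(res$down_set, 0)
  expect_true(all(res$table$call == "neither"))
})
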