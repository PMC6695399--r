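small_cfg <- function(seed = 7, ...) {
  args <- list(n_genes = 100, n_mirnas = 40, n_de_genes_up = 10,
               n_de_genes_down = 10, n_de_mirnas_up = 6,
               n_de_mirnas_down = 10, n_biomarkers_up = 3,
               n_biomarkers_down = 2, targets_per_mirna = 8,
               seed = seed)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

test_that("identical seeds give bit-identical studies", {
  a <- generate_study(small_cfg(seed = 7))
  b <- generate_study(small_cfg(seed = 7))
  expect_identical(a$mrna$signals, b$mrna$signals)
  expect_identical(a$mirna_exo$signals, b$mirna_exo$signals)
  expect_identical(a$targets$entries, b$targets$entries)
  expect_identical(a$qpcr$ct, b$qpcr$ct)
  expect_identical(a$truth, b$truth)
  c <- generate_study(small_cfg(seed = 8))
  expect_false(identical(a$mrna$signals, c$mrna$signals))
})

test_that("planted truth satisfies its structural invariants", {
  st <- generate_study(small_cfg())
  tr <- st$truth
  expect_true(all(tr$biomarker_genes_up %in% tr$de_genes_up))
  expect_true(all(tr$biomarker_genes_down %in% tr$de_genes_down))
  expect_true(all(tr$shared_mirnas_up %in% tr$de_mirnas_up$cell))
  expect_true(all(tr$shared_mirnas_up %in% tr$de_mirnas_up$exosome))
  expect_true(all(tr$shared_mirnas_down %in% tr$de_mirnas_down$cell))
  expect_true(all(tr$shared_mirnas_down %in% tr$de_mirnas_down$exosome))
  expect_length(intersect(tr$de_genes_up, tr$de_genes_down), 0)
  # every gene has an Entrez ID
  expect_true(all(rownames(st$mrna$signals) %in% names(st$id_map$ids)))
})

test_that("biomarker genes get the promised target coverage", {
  cfg <- small_cfg()
  st <- generate_study(cfg)
  tr <- st$truth
  need <- ceiling(cfg$biomarker_coverage *
                    length(tr$shared_mirnas_down))
  for (g in tr$biomarker_genes_up) {
    hits <- sum(vapply(tr$shared_mirnas_down, function(m)
      g %in% st$targets$entries[[m]], logical(1)))
    expect_gte(hits, need)
  }
  # decoys: non-differential miRNAs never target differential genes
  de_genes <- c(tr$de_genes_up, tr$de_genes_down)
  nonde_mirnas <- setdiff(names(st$targets$entries),
                          c(tr$de_mirnas_up$cell, tr$de_mirnas_up$exosome,
                            tr$de_mirnas_down$cell,
                            tr$de_mirnas_down$exosome))
  for (m in nonde_mirnas)
    expect_length(intersect(st$targets$entries[[m]], de_genes), 0)
})

test_that("planted effects are recovered within noise bounds", {
  cfg <- synthetic_config(seed = 31)
  st <- generate_study(cfg)
  em <- normalize_chips(st$mrna, normalization_spec(percentile = 75))
  lfc <- log2_fold_changes(em)
  err_up <- lfc[st$truth$de_genes_up] - cfg$effect_log2fc
  err_down <- lfc[st$truth$de_genes_down] + cfg$effect_log2fc
  err <- c(err_up, err_down)
  # per-feature error sd is noise_sd * sqrt(2 / replicates); at least
  # 95% of planted features must land inside the 3-sigma-style band
  # noise_sd * 3 / sqrt(replicates), and none far outside it
  band <- 3 * cfg$noise_sd / sqrt(cfg$replicates_per_group)
  expect_gte(mean(abs(err) <= band), 0.95)
  expect_lt(max(abs(err)), 2.5 * band)
  expect_lt(abs(mean(err)), 0.08)
})

test_that("zero effect size produces fold changes shrinking with n", {
  cfg3 <- small_cfg(effect_log2fc = 0)
  cfg8 <- small_cfg(effect_log2fc = 0, replicates_per_group = 8)
  m3 <- normalize_chips(generate_study(cfg3)$mrna,
                        normalization_spec(percentile = 75))
  m8 <- normalize_chips(generate_study(cfg8)$mrna,
                        normalization_spec(percentile = 75))
  expect_lt(mean(abs(log2_fold_changes(m8))),
            mean(abs(log2_fold_changes(m3))))
  expect_lt(mean(abs(log2_fold_changes(m8))), 0.2)
})

test_that("null studies have empty truth but fresh noise per seed", {
  n1 <- generate_null_study(small_cfg(seed = 1))
  n2 <- generate_null_study(small_cfg(seed = 2))
  expect_length(n1$truth$de_genes_up, 0)
  expect_length(n1$truth$de_mirnas_down$cell, 0)
  expect_length(n1$truth$biomarker_genes_up, 0)
  expect_false(identical(n1$mrna$signals, n2$mrna$signals))
})

test_that("pairing carries a chip-batch signal the paired test exploits", {
  # variance of paired differences should be smaller than the variance
  # implied by treating samples as independent (pair offsets cancel)
  cfg <- synthetic_config(n_genes = 500, n_mirnas = 20,
                          n_de_genes_up = 0, n_de_genes_down = 0,
                          n_de_mirnas_up = 0, n_de_mirnas_down = 0,
                          n_biomarkers_up = 0, n_biomarkers_down = 0,
                          seed = 13)
  st <- generate_study(cfg)
  em <- normalize_chips(st$mrna, normalization_spec(percentile = 75))
  s <- em$signals
  r <- cfg$replicates_per_group
  d_paired <- s[, r + seq_len(r)] - s[, seq_len(r)]
  centered1 <- s[, seq_len(r)] - rowMeans(s[, seq_len(r)])
  centered2 <- s[, r + seq_len(r)] - rowMeans(s[, r + seq_len(r)])
  var_within <- mean(centered1^2) * r / (r - 1) +
    mean(centered2^2) * r / (r - 1)
  expect_lt(mean(apply(d_paired, 1, var)), var_within)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(n_genes = 10, n_de_genes_up = 8,
                                n_de_genes_down = 8), "infeasible")
  expect_error(small_cfg(n_biomarkers_up = 50), "infeasible")
  expect_error(small_cfg(compartment_share_fraction = 0,
                         n_biomarkers_up = 1), "infeasible")
  expect_error(small_cfg(noise_sd = 0), "infeasible")
  expect_error(synthetic_config(n_mirnas = 10, n_de_mirnas_up = 5,
                                n_de_mirnas_down = 5), "infeasible")
})
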