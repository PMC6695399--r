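test_that("common_mirnas intersects per direction after normalization", {
  cell <- de_stub(up = c("hsa-miR-1-5p", "hsa-miR-2-5p", "hsa-miR-3-5p"),
                  down = "hsa-miR-9-3p")
  exo <- de_stub(up = c("HSA-MIR-2-5P", "hsa-miR-3-5p", "hsa-miR-4-5p"),
                 down = "hsa-miR-10-3p")
  cm <- common_mirnas(cell, exo)
  expect_setequal(cm$common_up, c("hsa-miR-2-5p", "hsa-miR-3-5p"))
  expect_length(cm$common_down, 0)

  # a miRNA moving in opposite directions is in neither common set
  cell2 <- de_stub(up = "hsa-miR-7-5p")
  exo2 <- de_stub(down = "hsa-miR-7-5p")
  cm2 <- common_mirnas(cell2, exo2)
  expect_length(cm2$common_up, 0)
  expect_length(cm2$common_down, 0)
})

test_that("coverage filter applies the strict more-than rule", {
  tt <- target_table(list(
    "hsa-miR-1-5p" = c("G", "H"),
    "hsa-miR-2-5p" = c("G", "H"),
    "hsa-miR-3-5p" = "G",
    "hsa-miR-4-5p" = "X"))
  # 3 miRNAs: G hit by 3/3, H by 2/3 -> both qualify (> 0.5)
  cov3 <- coverage_targets(paste0("hsa-miR-", 1:3, "-5p"), "down", tt)
  expect_setequal(cov3$qualifying_genes, c("G", "H"))
  expect_equal(cov3$predicted_direction, "up")
  expect_equal(unname(cov3$predicted_genes["H"]), 2L)

  # 4 miRNAs: H hit by 2/4 = 0.5 exactly -> excluded by the strict >
  cov4 <- coverage_targets(paste0("hsa-miR-", 1:4, "-5p"), "down", tt)
  expect_true("G" %in% cov4$qualifying_genes)
  expect_false("H" %in% cov4$qualifying_genes)

  expect_error(coverage_targets(character(), "down", tt), "empty")
})

test_that("coverage denominator counts absent miRNAs unless told not to", {
  tt <- target_table(list("hsa-miR-1-5p" = "G", "hsa-miR-2-5p" = "G"))
  set4 <- c(paste0("hsa-miR-", 1:2, "-5p"),
            paste0("hsa-miR-", 8:9, "-5p"))  # two absent from the table
  strict <- coverage_targets(set4, "down", tt)
  expect_length(strict$qualifying_genes, 0)   # 2/4 is not > 0.5
  loose <- coverage_targets(set4, "down", tt, denominator = "in_table")
  expect_equal(loose$qualifying_genes, "G")   # 2/2
  off <- coverage_targets(set4, "down", tt, coverage_filter = FALSE)
  expect_equal(off$qualifying_genes, "G")     # union of targets
})

test_that("coverage counts match brute-force enumeration", {
  set.seed(21)
  for (rep in 1:20) {
    mirnas <- sprintf("hsa-miR-%d-5p", 1:8)
    genes <- sprintf("G%02d", 1:15)
    pairs <- unique(data.frame(
      mirna = sample(mirnas, 60, replace = TRUE),
      gene = sample(genes, 60, replace = TRUE)))
    tt <- target_table(split(pairs$gene, pairs$mirna))
    mset <- sample(mirnas, sample(2:8, 1))
    cov <- coverage_targets(mset, "down", tt)
    expect_equal(cov$qualifying_genes, coverage_brute(mset, pairs))
  }
})

test_that("map_ids separates mapped and unmapped symbols", {
  m <- gene_id_map(c(GBX2 = 2637L, TLR4 = 7099L))
  res <- map_ids(c("gbx2", "TLR4"), m)
  expect_equal(sort(unname(res$ids)), c(2637L, 7099L))
  expect_length(res$unmapped, 0)
  res2 <- map_ids(c("GBX2", "NOVELX"), m)
  expect_equal(unname(res2$ids), 2637L)
  expect_equal(res2$unmapped, "NOVELX")
  res3 <- map_ids(character(), m)
  expect_length(res3$ids, 0)
  expect_length(res3$unmapped, 0)
})

toy_setup <- function() {
  # mrna up {G1,G2,G3}; common down-miRNAs {m1,m2,m3} all target
  # {G2,G3,G4}; G5 is targeted by only one of three (coverage fails)
  tt <- target_table(list(
    "hsa-miR-1-5p" = c("G2", "G3", "G4"),
    "hsa-miR-2-5p" = c("G2", "G3", "G4"),
    "hsa-miR-3-5p" = c("G2", "G3", "G4", "G5")))
  ids <- setNames(101:106, paste0("G", 1:6))
  list(
    tt = tt, map = gene_id_map(ids),
    mrna = de_stub(up = c("G1", "G2", "G3"), down = "G6"),
    cell = de_stub(down = paste0("hsa-miR-", 1:3, "-5p")),
    exo = de_stub(down = paste0("hsa-miR-", 1:3, "-5p")))
}

test_that("integrate_candidates intersects predicted and observed", {
  s <- toy_setup()
  res <- integrate_candidates(s$mrna, s$cell, s$exo, s$tt, s$map)
  expect_equal(res$up_genes$symbol, c("G2", "G3"))
  expect_equal(res$up_genes$entrez, c(102L, 103L))
  expect_equal(nrow(res$down_genes), 0L)
  expect_equal(res$cardinalities$n_common_mirna_down, 3L)
  expect_equal(res$cardinalities$n_predicted_up, 3L)  # G2 G3 G4
  expect_equal(res$cardinalities$n_candidates_up, 2L)
  expect_match(res$up_genes$provenance[1], "predicted_up_from_common")
})

test_that("per_compartment strategy needs all three sets", {
  s <- toy_setup()
  res <- integrate_candidates(s$mrna, s$cell, s$exo, s$tt, s$map,
                              strategy = "per_compartment")
  expect_equal(res$up_genes$symbol, c("G2", "G3"))
  # empty exosome prediction absorbs the intersection
  res2 <- integrate_candidates(s$mrna, s$cell, de_stub(), s$tt, s$map,
                               strategy = "per_compartment")
  expect_equal(nrow(res2$up_genes), 0L)
  expect_equal(res2$cardinalities$n_predicted_up_exo, 0L)
  expect_equal(res2$cardinalities$n_predicted_up_cell, 3L)
})

test_that("unmapped symbols drop out before intersection", {
  s <- toy_setup()
  partial <- gene_id_map(setNames(c(101L, 103L), c("G1", "G3")))
  res <- integrate_candidates(s$mrna, s$cell, s$exo, s$tt, partial)
  expect_equal(res$up_genes$symbol, "G3")  # G2 has no Entrez ID
  expect_true("G2" %in% res$unmapped)
  expect_equal(res$cardinalities$n_mrna_up, 3L)
  expect_equal(res$cardinalities$n_mrna_up_mapped, 2L)
})

test_that("candidate count never exceeds any intersected set", {
  run <- run_pipeline(run_config(synthetic = synthetic_config(
    n_genes = 50, n_mirnas = 20, n_de_genes_up = 8, n_de_genes_down = 8,
    n_de_mirnas_up = 4, n_de_mirnas_down = 6, n_biomarkers_up = 3,
    n_biomarkers_down = 1, targets_per_mirna = 4, seed = 17)))
  card <- run$candidates$cardinalities
  expect_lte(card$n_candidates_up,
             min(card$n_mrna_up_mapped, card$n_predicted_up))
  expect_lte(card$n_candidates_down,
             min(card$n_mrna_down_mapped, card$n_predicted_down))
})

test_that("integration agrees with a brute-force gene enumeration", {
  # brute force: for every gene, test the membership predicates directly
  for (seed in c(3, 9, 27)) {
    st <- generate_study(synthetic_config(
      n_genes = 50, n_mirnas = 20, n_de_genes_up = 6,
      n_de_genes_down = 6, n_de_mirnas_up = 4, n_de_mirnas_down = 6,
      n_biomarkers_up = 2, n_biomarkers_down = 1,
      targets_per_mirna = 4, seed = seed))
    mrna_n <- normalize_chips(st$mrna, normalization_spec(percentile = 75))
    cell_n <- normalize_chips(st$mirna_cell,
                              normalization_spec(percentile = 99))
    exo_n <- normalize_chips(st$mirna_exo,
                             normalization_spec(percentile = 99))
    mrna_res <- mrna_de(mrna_n)
    cell_res <- suppressWarnings(mirna_de(cell_n))
    exo_res <- suppressWarnings(mirna_de(exo_n))
    res <- integrate_candidates(mrna_res, cell_res, exo_res, st$targets,
                                st$id_map)

    common_down <- intersect(cell_res$down_set, exo_res$down_set)
    brute_up <- character()
    if (length(common_down)) {
      for (g in rownames(st$mrna$signals)) {
        n_hit <- sum(vapply(common_down, function(m)
          g %in% st$targets$entries[[m]], logical(1)))
        if (n_hit / length(common_down) > 0.5 &&
            g %in% mrna_res$up_set &&
            g %in% names(st$id_map$ids))
          brute_up <- c(brute_up, g)
      }
    }
    expect_setequal(res$up_genes$symbol, brute_up)
  }
})

test_that("swapping substate labels swaps candidate directions", {
  cfg <- synthetic_config(
    n_genes = 80, n_mirnas = 40, n_de_genes_up = 10,
    n_de_genes_down = 10, n_de_mirnas_up = 6, n_de_mirnas_down = 8,
    n_biomarkers_up = 3, n_biomarkers_down = 2, targets_per_mirna = 6,
    seed = 23)
  st <- generate_study(cfg)
  analyze <- function(g1, g2) {
    mrna_n <- normalize_chips(st$mrna, normalization_spec(percentile = 75))
    cell_n <- normalize_chips(st$mirna_cell,
                              normalization_spec(percentile = 99))
    exo_n <- normalize_chips(st$mirna_exo,
                             normalization_spec(percentile = 99))
    integrate_candidates(
      mrna_de(mrna_n, group1 = g1, group2 = g2),
      mirna_de(cell_n, group1 = g1, group2 = g2),
      mirna_de(exo_n, group1 = g1, group2 = g2),
      st$targets, st$id_map)
  }
  fwd <- analyze("substate1", "substate2")
  rev <- analyze("substate2", "substate1")
  expect_setequal(fwd$up_genes$symbol, rev$down_genes$symbol)
  expect_setequal(fwd$down_genes$symbol, rev$up_genes$symbol)
})
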