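#' Configuration of a synthetic two-substate study
#'
#' Describes the data-generating model used throughout the test suite: a
#' log-normal signal (normal on the log2 scale) with additive group
#' effects, paired replicate chips (replicate i of each group shares a
#' per-pair, per-feature offset, emulating chip-batch correlation that a
#' paired test can exploit), planted two-fold effects on subsets of
#' mRNAs and miRNAs, partial sharing of differential miRNAs between the
#' cell and exosome compartments, and a target table in which planted
#' biomarker genes are collectively targeted by the planted shared
#' miRNAs of the opposite direction while non-differential miRNAs get
#' random decoy targets among non-differential genes.
#'
#' @param n_genes,n_mirnas universe sizes (default 2000 genes, 300
#'   miRNAs).
#' @param replicates_per_group paired replicate chips per group
#'   (default 3).
#' @param baseline_log2_mean,baseline_log2_sd feature baseline abundance
#'   on the log2 scale (defaults 8 and 2).
#' @param low_fraction fraction of non-differential features planted at
#'   a baseline below the detection floor so flooring is exercised
#'   (default 0.01).
#' @param noise_sd per-replicate log2 noise sd, also used for the
#'   per-pair chip-batch offsets (default 0.25).
#' @param effect_log2fc planted absolute effect size in log2 units
#'   (default 2.0, i.e. four-fold).
#' @param n_de_genes_up,n_de_genes_down planted differential mRNAs
#'   (defaults 60 each).
#' @param n_de_mirnas_up,n_de_mirnas_down planted differential miRNAs
#'   per compartment (defaults 20 and 30).
#' @param compartment_share_fraction fraction of each compartment's
#'   differential miRNAs shared with the other compartment
#'   (default 0.6).
#' @param targets_per_mirna decoy targets drawn per miRNA (default 25).
#' @param biomarker_coverage fraction of the planted shared
#'   opposite-direction miRNAs that target each planted biomarker gene
#'   (default 0.6, comfortably above the >50% coverage filter).
#' @param n_biomarkers_up,n_biomarkers_down planted biomarker genes,
#'   subsets of the planted differential genes (defaults 10 and 3).
#' @param de_baseline_quantile differential features are planted only
#'   among features whose baseline abundance lies below this quantile of
#'   the baseline distribution (default 0.9). Percentile-shift
#'   normalization assumes the anchor percentile tracks
#'   non-differential signal — on real chips the brightest probes are
#'   abundant constitutive species — and the generator reproduces that
#'   property.
#' @param bright_noise_factor multiplier applied to the log2 noise of
#'   features above the \code{de_baseline_quantile} abundance band
#'   (default 0.2). Array log-scale noise is strongly
#'   intensity-dependent: bright probes are measured with a far smaller
#'   log2 coefficient of variation than mid-range ones, which is what
#'   makes an upper-percentile normalization anchor estimable per chip.
#' @param qpcr_ct_sd technical sd of simulated Ct values in cycles
#'   (default 0.15).
#' @param seed RNG seed (Mersenne-Twister; recorded in the truth).
#' @return a validated \code{SyntheticConfig} list.
#' @export
synthetic_config <- function(n_genes = 2000, n_mirnas = 300,
                             replicates_per_group = 3,
                             baseline_log2_mean = 8,
                             baseline_log2_sd = 2,
                             low_fraction = 0.01,
                             noise_sd = 0.25, effect_log2fc = 2,
                             n_de_genes_up = 60, n_de_genes_down = 60,
                             n_de_mirnas_up = 20, n_de_mirnas_down = 30,
                             compartment_share_fraction = 0.6,
                             targets_per_mirna = 25,
                             biomarker_coverage = 0.6,
                             n_biomarkers_up = 10, n_biomarkers_down = 3,
                             de_baseline_quantile = 0.9,
                             bright_noise_factor = 0.2,
                             qpcr_ct_sd = 0.15, seed = 1) {
  cfg <- list(n_genes = n_genes, n_mirnas = n_mirnas,
              replicates_per_group = replicates_per_group,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              low_fraction = low_fraction,
              noise_sd = noise_sd, effect_log2fc = effect_log2fc,
              n_de_genes_up = n_de_genes_up,
              n_de_genes_down = n_de_genes_down,
              n_de_mirnas_up = n_de_mirnas_up,
              n_de_mirnas_down = n_de_mirnas_down,
              compartment_share_fraction = compartment_share_fraction,
              targets_per_mirna = targets_per_mirna,
              biomarker_coverage = biomarker_coverage,
              n_biomarkers_up = n_biomarkers_up,
              n_biomarkers_down = n_biomarkers_down,
              de_baseline_quantile = de_baseline_quantile,
              bright_noise_factor = bright_noise_factor,
              qpcr_ct_sd = qpcr_ct_sd, seed = seed)
  counts <- cfg[c("n_genes", "n_mirnas", "replicates_per_group",
                  "n_de_genes_up", "n_de_genes_down", "n_de_mirnas_up",
                  "n_de_mirnas_down", "targets_per_mirna",
                  "n_biomarkers_up", "n_biomarkers_down")]
  if (any(vapply(counts, function(v) v < 0 || v != round(v), logical(1))))
    stop("infeasible config: counts must be non-negative integers")
  if (replicates_per_group < 2)
    stop("infeasible config: paired design needs >= 2 replicates")
  if (n_de_genes_up + n_de_genes_down > n_genes)
    stop("infeasible config: more planted differential genes than genes")
  if (noise_sd <= 0 || qpcr_ct_sd <= 0)
    stop("infeasible config: noise sds must be > 0")
  if (bright_noise_factor <= 0 || bright_noise_factor > 1)
    stop("infeasible config: bright_noise_factor must lie in (0, 1]")
  frac <- c(compartment_share_fraction, biomarker_coverage, low_fraction,
            de_baseline_quantile)
  if (any(frac < 0 | frac > 1))
    stop("infeasible config: fractions must lie in [0, 1]")
  if (n_de_genes_up + n_de_genes_down >
        floor(de_baseline_quantile * n_genes))
    stop("infeasible config: planted differential genes exceed the ",
         "sub-anchor abundance band")
  if (n_biomarkers_up > n_de_genes_up ||
      n_biomarkers_down > n_de_genes_down)
    stop("infeasible config: biomarkers exceed planted differential genes")
  sh <- shared_counts(cfg)
  if (sh$distinct_total > floor(de_baseline_quantile * n_mirnas))
    stop("infeasible config: compartment-private miRNA sets exceed ",
         "the sub-anchor abundance band of the miRNA universe")
  if (n_biomarkers_up > 0 && sh$shared_down == 0)
    stop("infeasible config: biomarker-up genes need >= 1 shared ",
         "down-regulated miRNA to be targeted by")
  if (n_biomarkers_down > 0 && sh$shared_up == 0)
    stop("infeasible config: biomarker-down genes need >= 1 shared ",
         "up-regulated miRNA to be targeted by")
  structure(cfg, class = "SyntheticConfig")
}

shared_counts <- function(cfg) {
  shared_up <- round(cfg$compartment_share_fraction * cfg$n_de_mirnas_up)
  shared_down <- round(cfg$compartment_share_fraction * cfg$n_de_mirnas_down)
  distinct_up <- 2L * cfg$n_de_mirnas_up - shared_up
  distinct_down <- 2L * cfg$n_de_mirnas_down - shared_down
  list(shared_up = shared_up, shared_down = shared_down,
       distinct_total = distinct_up + distinct_down)
}

sim_matrix <- function(features, baseline, up_set, down_set, cfg,
                       compartment, assay) {
  r <- cfg$replicates_per_group
  n <- length(features)
  effect <- numeric(n)
  names(effect) <- features
  effect[up_set] <- cfg$effect_log2fc
  effect[down_set] <- -cfg$effect_log2fc
  # intensity-dependent technical noise: bright constitutive features
  # (above the DE-eligible band) have a much smaller log2 sd
  bright_cut <- stats::quantile(baseline, cfg$de_baseline_quantile,
                                type = 7)
  sd_f <- ifelse(baseline >= bright_cut,
                 cfg$noise_sd * cfg$bright_noise_factor, cfg$noise_sd)
  pair_offset <- matrix(stats::rnorm(n * r, 0, sd_f), n, r)
  eps <- matrix(stats::rnorm(n * 2 * r, 0, sd_f), n, 2 * r)
  log2sig <- cbind(pair_offset, pair_offset + effect) + baseline + eps
  meta <- data.frame(
    sample = paste0(compartment, "_", assay, "_",
                    rep(c("substate1", "substate2"), each = r),
                    "_rep", rep(seq_len(r), 2)),
    group = rep(c("substate1", "substate2"), each = r),
    replicate = rep(seq_len(r), 2),
    compartment = compartment, assay = assay,
    stringsAsFactors = FALSE)
  signals <- 2^log2sig
  rownames(signals) <- features
  expression_matrix(signals, meta)
}

#' Generate a synthetic two-substate study with planted truth
#'
#' Produces every input the pipeline consumes — mRNA array, cellular and
#' exosomal miRNA arrays, target table, gene-ID map and a qPCR panel —
#' together with the planted truth against which recovery is scored. The
#' same seed yields bit-identical output.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with elements \code{mrna}, \code{mirna_cell},
#'   \code{mirna_exo} (\code{ExpressionMatrix}), \code{targets}
#'   (\code{TargetTable}), \code{id_map} (\code{GeneIdMap}), \code{qpcr}
#'   (\code{QpcrDataset}) and \code{truth} (\code{SyntheticTruth}).
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cfg <- config
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  genes <- sprintf("GENE%05d", seq_len(cfg$n_genes))
  mirnas <- sprintf("hsa-miR-%04d-5p", seq_len(cfg$n_mirnas))

  # feature-intrinsic baseline abundances, shared across compartments;
  # effects are planted only below the de_baseline_quantile abundance
  # band so the normalization anchor percentile stays non-differential
  baseline_g <- stats::rnorm(cfg$n_genes, cfg$baseline_log2_mean,
                             cfg$baseline_log2_sd)
  names(baseline_g) <- genes
  baseline_m <- stats::rnorm(cfg$n_mirnas, cfg$baseline_log2_mean,
                             cfg$baseline_log2_sd)
  names(baseline_m) <- mirnas
  eligible_g <- genes[baseline_g < stats::quantile(
    baseline_g, cfg$de_baseline_quantile, type = 7)]
  eligible_m <- mirnas[baseline_m < stats::quantile(
    baseline_m, cfg$de_baseline_quantile, type = 7)]

  gi <- sample.int(length(eligible_g),
                   cfg$n_de_genes_up + cfg$n_de_genes_down)
  genes_up <- eligible_g[gi[seq_len(cfg$n_de_genes_up)]]
  genes_down <- eligible_g[gi[cfg$n_de_genes_up +
                                seq_len(cfg$n_de_genes_down)]]
  biomarkers_up <- genes_up[seq_len(cfg$n_biomarkers_up)]
  biomarkers_down <- genes_down[seq_len(cfg$n_biomarkers_down)]

  sh <- shared_counts(cfg)
  priv_up <- cfg$n_de_mirnas_up - sh$shared_up
  priv_down <- cfg$n_de_mirnas_down - sh$shared_down
  mi <- sample.int(length(eligible_m), sh$distinct_total)
  pool <- eligible_m[mi]
  take <- function(k) {
    if (k == 0L) return(character())
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  shared_up <- take(sh$shared_up)
  cell_priv_up <- take(priv_up)
  exo_priv_up <- take(priv_up)
  shared_down <- take(sh$shared_down)
  cell_priv_down <- take(priv_down)
  exo_priv_down <- take(priv_down)
  cell_up <- c(shared_up, cell_priv_up)
  cell_down <- c(shared_down, cell_priv_down)
  exo_up <- c(shared_up, exo_priv_up)
  exo_down <- c(shared_down, exo_priv_down)

  nonde_genes <- setdiff(genes, c(genes_up, genes_down))
  n_low <- round(cfg$low_fraction * cfg$n_genes)
  low_pool <- setdiff(nonde_genes, names(baseline_g)[rank(baseline_g) >
                                                       cfg$n_genes * 0.5])
  low_genes <- low_pool[sample.int(length(low_pool),
                                   min(n_low, length(low_pool)))]
  baseline_g[low_genes] <- -1

  mrna <- sim_matrix(genes, baseline_g, genes_up, genes_down, cfg,
                     "cell", "mRNA")
  mirna_cell <- sim_matrix(mirnas, baseline_m, cell_up, cell_down, cfg,
                           "cell", "miRNA")
  mirna_exo <- sim_matrix(mirnas, baseline_m, exo_up, exo_down, cfg,
                          "exosome", "miRNA")

  # target table: planted coverage for biomarkers, random decoys for all
  entries <- stats::setNames(vector("list", cfg$n_mirnas), mirnas)
  add_targets <- function(mir, gene) {
    for (m in mir) entries[[m]] <<- c(entries[[m]], gene)
  }
  cover <- function(biomarkers, source_mirnas) {
    if (!length(biomarkers)) return(invisible())
    k <- ceiling(cfg$biomarker_coverage * length(source_mirnas))
    for (g in biomarkers)
      add_targets(source_mirnas[sample.int(length(source_mirnas), k)], g)
  }
  cover(biomarkers_up, shared_down)
  cover(biomarkers_down, shared_up)
  if (cfg$targets_per_mirna > 0 && length(nonde_genes)) {
    k <- min(cfg$targets_per_mirna, length(nonde_genes))
    for (m in mirnas)
      add_targets(m, nonde_genes[sample.int(length(nonde_genes), k)])
  }
  entries <- entries[lengths(entries) > 0]
  targets <- target_table(entries, dialect = "two_column")

  id_map <- gene_id_map(stats::setNames(100000L + seq_len(cfg$n_genes),
                                        genes))

  qpcr <- sim_qpcr(cfg, biomarkers_up, biomarkers_down, nonde_genes)

  truth <- structure(
    list(de_genes_up = sort(genes_up), de_genes_down = sort(genes_down),
         de_mirnas_up = list(cell = sort(cell_up), exosome = sort(exo_up)),
         de_mirnas_down = list(cell = sort(cell_down),
                               exosome = sort(exo_down)),
         shared_mirnas_up = sort(shared_up),
         shared_mirnas_down = sort(shared_down),
         biomarker_genes_up = sort(biomarkers_up),
         biomarker_genes_down = sort(biomarkers_down),
         seed = cfg$seed, rng_kind = "Mersenne-Twister"),
    class = "SyntheticTruth")

  list(mrna = mrna, mirna_cell = mirna_cell, mirna_exo = mirna_exo,
       targets = targets, id_map = id_map, qpcr = qpcr, truth = truth)
}

sim_qpcr <- function(cfg, biomarkers_up, biomarkers_down, nonde_genes) {
  controls <- nonde_genes[seq_len(min(4L, length(nonde_genes)))]
  panel <- c(biomarkers_up, biomarkers_down, controls)
  shift <- c(rep(-cfg$effect_log2fc, length(biomarkers_up)),
             rep(cfg$effect_log2fc, length(biomarkers_down)),
             rep(0, length(controls)))
  r <- cfg$replicates_per_group
  rows <- list()
  for (g in c("substate1", "substate2")) {
    for (i in seq_len(r)) {
      ref_ct <- 20 + stats::rnorm(1, 0, cfg$qpcr_ct_sd)
      gene_ct <- 25 + (g == "substate2") * shift +
        stats::rnorm(length(panel), 0, cfg$qpcr_ct_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = c(panel, "GAPDH"), group = g, replicate = i,
        ct = c(gene_ct, ref_ct), stringsAsFactors = FALSE)
    }
  }
  qpcr_dataset(do.call(rbind, rows), reference_gene = "GAPDH")
}

#' Generate a null study (no planted effects)
#'
#' Same generator with all effect sizes forced to zero and no planted
#' differential features or biomarkers; the truth sets are empty. Used
#' for false-positive-rate properties.
#'
#' @param config a \code{\link{synthetic_config}}; its effect and
#'   planted-count fields are overridden.
#' @return same structure as \code{\link{generate_study}}.
#' @export
generate_null_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cfg <- unclass(config)
  cfg$effect_log2fc <- 0
  cfg$n_de_genes_up <- 0L
  cfg$n_de_genes_down <- 0L
  cfg$n_de_mirnas_up <- 0L
  cfg$n_de_mirnas_down <- 0L
  cfg$n_biomarkers_up <- 0L
  cfg$n_biomarkers_down <- 0L
  generate_study(do.call(synthetic_config, cfg))
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth: ", length(x$de_genes_up), "/",
      length(x$de_genes_down), " up/down genes, ",
      length(x$de_mirnas_up$cell), "/", length(x$de_mirnas_down$cell),
      " up/down cell miRNAs, ",
      length(x$biomarker_genes_up), "/", length(x$biomarker_genes_down),
      " up/down biomarkers (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
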