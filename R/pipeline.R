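#' Run configuration
#'
#' Bundles everything one analysis run needs: either a synthetic-study
#' block or a set of input file paths (never both), the per-assay
#' normalization (75th percentile for mRNA chips, 99th for miRNA chips),
#' the differential-expression thresholds, the integration strategy and
#' coverage fraction, the qPCR confirmation thresholds, and the seed.
#' Every threshold defaults to the pipeline's standard value (2-fold,
#' q < 0.05, |z| >= 2, coverage > 50 percent, 1.5-fold qPCR, p < 0.05).
#'
#' @param synthetic a \code{\link{synthetic_config}}, or NULL when
#'   reading from files.
#' @param inputs NULL, or a list of input descriptors: \code{mrna},
#'   \code{mirna_cell}, \code{mirna_exo} (each
#'   \code{list(path =, meta =)} with \code{meta} a sample-metadata TSV),
#'   \code{targets} (\code{list(path =, dialect =)}), \code{id_map}
#'   (path), and optionally \code{qpcr}
#'   (\code{list(path =, reference_gene =)}).
#' @param mrna_norm,mirna_norm \code{\link{normalization_spec}} per
#'   assay.
#' @param exo_mass_factors optional per-sample mass-correction factors
#'   for the exosomal miRNA chips.
#' @param z_threshold,center mRNA Z-score selection parameters.
#' @param fold_threshold,q_threshold,genomewide_fdr,correction miRNA
#'   branch parameters.
#' @param strategy,min_fraction,denominator,coverage_filter integration
#'   parameters.
#' @param qpcr_fold_threshold,qpcr_alpha qPCR confirmation parameters.
#' @param out_dir output directory, or NULL to skip writing files.
#' @param seed run seed; overrides the synthetic block's seed when set.
#' @return a \code{RunConfig} list.
#' @export
run_config <- function(synthetic = synthetic_config(), inputs = NULL,
                       mrna_norm = normalization_spec(percentile = 75),
                       mirna_norm = normalization_spec(percentile = 99),
                       exo_mass_factors = NULL,
                       z_threshold = 2, center = TRUE,
                       fold_threshold = 2, q_threshold = 0.05,
                       genomewide_fdr = FALSE, correction = "BH",
                       strategy = "common_mirna_first",
                       min_fraction = 0.5, denominator = "all",
                       coverage_filter = TRUE,
                       qpcr_fold_threshold = 1.5, qpcr_alpha = 0.05,
                       out_dir = NULL, seed = NULL) {
  if (is.null(synthetic) == is.null(inputs))
    stop("exactly one of 'synthetic' and 'inputs' must be given")
  if (!is.null(synthetic) && !is.null(seed))
    synthetic$seed <- seed
  if (z_threshold <= 0 || fold_threshold < 1 ||
      q_threshold <= 0 || q_threshold > 1 ||
      min_fraction < 0 || min_fraction >= 1 ||
      qpcr_fold_threshold < 1 || qpcr_alpha <= 0 || qpcr_alpha > 1)
    stop("threshold out of its documented range")
  structure(list(synthetic = synthetic, inputs = inputs,
                 mrna_norm = mrna_norm, mirna_norm = mirna_norm,
                 exo_mass_factors = exo_mass_factors,
                 z_threshold = z_threshold, center = center,
                 fold_threshold = fold_threshold,
                 q_threshold = q_threshold,
                 genomewide_fdr = genomewide_fdr,
                 correction = correction, strategy = strategy,
                 min_fraction = min_fraction, denominator = denominator,
                 coverage_filter = coverage_filter,
                 qpcr_fold_threshold = qpcr_fold_threshold,
                 qpcr_alpha = qpcr_alpha, out_dir = out_dir,
                 seed = if (is.null(seed) && !is.null(synthetic))
                   synthetic$seed else seed),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' The document may contain a \code{synthetic:} block (fields of
#' \code{\link{synthetic_config}}) or an \code{inputs:} block (fields as
#' in \code{\link{run_config}}), plus any top-level threshold keys;
#' unspecified keys keep their defaults.
#'
#' @param path path to a YAML file.
#' @return a \code{RunConfig}.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$synthetic) && !is.null(doc$inputs))
    stop("config must not contain both 'synthetic' and 'inputs' blocks")
  args <- doc
  args$synthetic <- if (!is.null(doc$synthetic))
    do.call(synthetic_config, doc$synthetic) else NULL
  for (k in c("mrna_norm", "mirna_norm"))
    if (!is.null(doc[[k]])) args[[k]] <- do.call(normalization_spec,
                                                 doc[[k]])
  known <- names(formals(run_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, args)
}

#' Read a sample-metadata table
#'
#' Tab-delimited with columns \code{sample}, \code{group},
#' \code{replicate}, \code{compartment}, \code{assay}.
#'
#' @param path path to the TSV.
#' @return data.frame usable as \code{sample_meta}.
#' @export
read_sample_meta <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read a qPCR Ct table
#'
#' Tab-delimited long format with columns \code{gene}, \code{group},
#' \code{replicate}, \code{ct}.
#'
#' @param path path to the TSV.
#' @param reference_gene endogenous control symbol.
#' @return a \code{\link{qpcr_dataset}}.
#' @export
read_qpcr_table <- function(path, reference_gene) {
  qpcr_dataset(utils::read.delim(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE),
               reference_gene = reference_gene)
}

#' Write a study to disk as plain-text tables
#'
#' Emits every component of a study (as produced by
#' \code{\link{generate_study}} or assembled from readers) as
#' tab-delimited files: expression tables plus sample metadata, the
#' target table in two-column form, the gene-ID map, the qPCR Ct table,
#' and — when present — the planted truth as JSON (metadata, not a
#' pipeline input).
#'
#' @param study list with elements as returned by
#'   \code{\link{generate_study}}.
#' @param dir output directory, created if needed.
#' @return invisibly, \code{dir}.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr_em <- function(em, stem) {
    tab <- data.frame(feature = rownames(em$signals), em$signals,
                      check.names = FALSE)
    utils::write.table(tab, file.path(dir, paste0(stem, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(em$sample_meta,
                       file.path(dir, paste0(stem, "_meta.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr_em(study$mrna, "mrna")
  wr_em(study$mirna_cell, "mirna_cell")
  wr_em(study$mirna_exo, "mirna_exo")
  ent <- study$targets$entries
  utils::write.table(
    data.frame(mirna = rep(names(ent), lengths(ent)),
               gene = unlist(ent, use.names = FALSE)),
    file.path(dir, "targets.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(symbol = names(study$id_map$ids),
               entrez = unname(study$id_map$ids)),
    file.path(dir, "id_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(study$qpcr))
    utils::write.table(study$qpcr$ct, file.path(dir, "qpcr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(study$truth))
    jsonlite::write_json(unclass(study$truth),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study written by \code{write_study}
#'
#' @param dir directory produced by \code{\link{write_study}}.
#' @param reference_gene qPCR reference gene (default GAPDH).
#' @return a study list (without the planted truth).
#' @export
read_study <- function(dir, reference_gene = "GAPDH") {
  rd_em <- function(stem) {
    meta <- read_sample_meta(file.path(dir, paste0(stem, "_meta.tsv")))
    read_expression_table(file.path(dir, paste0(stem, ".tsv")), meta)
  }
  qpcr_path <- file.path(dir, "qpcr.tsv")
  list(mrna = rd_em("mrna"),
       mirna_cell = rd_em("mirna_cell"),
       mirna_exo = rd_em("mirna_exo"),
       targets = read_target_table(file.path(dir, "targets.tsv"),
                                   dialect = "two_column"),
       id_map = read_gene_id_map(file.path(dir, "id_map.tsv")),
       qpcr = if (file.exists(qpcr_path))
         read_qpcr_table(qpcr_path, reference_gene) else NULL,
       truth = NULL)
}

load_study <- function(config) {
  if (!is.null(config$synthetic))
    return(generate_study(config$synthetic))
  inp <- config$inputs
  rd <- function(d) read_expression_table(d$path, read_sample_meta(d$meta))
  list(mrna = rd(inp$mrna),
       mirna_cell = rd(inp$mirna_cell),
       mirna_exo = rd(inp$mirna_exo),
       targets = read_target_table(inp$targets$path,
                                   dialect = inp$targets$dialect %||%
                                     "two_column"),
       id_map = read_gene_id_map(inp$id_map),
       qpcr = if (!is.null(inp$qpcr))
         read_qpcr_table(inp$qpcr$path,
                         inp$qpcr$reference_gene %||% "GAPDH") else NULL,
       truth = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full integrated analysis
#'
#' Executes the whole pipeline on a \code{\link{run_config}}: load or
#' generate the study; mass-correct (exosome chips, if factors are
#' supplied), floor and percentile-shift each matrix (75th percentile for
#' mRNA, 99th for miRNA); Z-score mRNA differential expression;
#' fold-change + paired-test + FDR miRNA differential expression per
#' compartment; coverage-filtered, direction-inverted target integration
#' in Entrez ID space; and, when qPCR data are present, candidate
#' confirmation. When \code{out_dir} is set, all DE tables, the
#' candidate report, the cardinality summary and run metadata are
#' written there. Identical config and seed give identical output.
#'
#' @param config a \code{RunConfig}.
#' @return list with the study, the three normalized matrices, the three
#'   \code{DEResult}s, the \code{CandidateSet}, the qPCR confirmation
#'   table (or NULL) and the config.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "RunConfig"))
  study <- load_study(config)

  exo_norm <- config$mirna_norm
  exo_norm$mass_correction_factors <- config$exo_mass_factors
  mrna_n <- normalize_chips(study$mrna, config$mrna_norm)
  mirna_cell_n <- normalize_chips(study$mirna_cell, config$mirna_norm)
  mirna_exo_n <- normalize_chips(study$mirna_exo, exo_norm)

  mrna_res <- mrna_de(mrna_n, z_threshold = config$z_threshold,
                      center = config$center)
  cell_res <- mirna_de(mirna_cell_n,
                       fold_threshold = config$fold_threshold,
                       q_threshold = config$q_threshold,
                       genomewide_fdr = config$genomewide_fdr,
                       correction = config$correction)
  exo_res <- mirna_de(mirna_exo_n,
                      fold_threshold = config$fold_threshold,
                      q_threshold = config$q_threshold,
                      genomewide_fdr = config$genomewide_fdr,
                      correction = config$correction)

  candidates <- integrate_candidates(
    mrna_res, cell_res, exo_res, study$targets, study$id_map,
    strategy = config$strategy, min_fraction = config$min_fraction,
    denominator = config$denominator,
    coverage_filter = config$coverage_filter)

  confirmation <- NULL
  if (!is.null(study$qpcr) &&
      (nrow(candidates$up_genes) || nrow(candidates$down_genes)))
    confirmation <- confirm_candidates(
      study$qpcr, candidates,
      fold_threshold = config$qpcr_fold_threshold,
      alpha = config$qpcr_alpha)

  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_de_table(mrna_res, file.path(dir, "de_mrna.tsv"))
    write_de_table(cell_res, file.path(dir, "de_mirna_cell.tsv"))
    write_de_table(exo_res, file.path(dir, "de_mirna_exosome.tsv"))
    write_candidate_report(
      candidates,
      de_summaries = list(mrna = mrna_res, mirna_cell = cell_res,
                          mirna_exosome = exo_res),
      dir = dir, seed = config$seed %||% NA)
    if (!is.null(confirmation))
      utils::write.table(confirmation,
                         file.path(dir, "qpcr_confirmation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(study = study, mrna_norm = mrna_n, mirna_cell_norm = mirna_cell_n,
       mirna_exo_norm = mirna_exo_n, mrna_de = mrna_res,
       cell_mirna_de = cell_res, exo_mirna_de = exo_res,
       candidates = candidates, confirmation = confirmation,
       config = config)
}
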