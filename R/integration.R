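#' miRNAs common to cell and exosome compartments
#'
#' Direction-stratified intersection of the DE miRNA sets from the two
#' compartments after identifier normalization: a miRNA must be called in
#' the same direction in both compartments to be retained. miRNAs
#' detected in both compartments are the most reliable array calls and
#' anchor the integration.
#'
#' @param cell_de,exo_de \code{DEResult} objects from
#'   \code{\link{mirna_de}} on the cellular and exosomal matrices.
#' @return list with elements \code{common_up} and \code{common_down}.
#' @export
common_mirnas <- function(cell_de, exo_de) {
  stopifnot(inherits(cell_de, "DEResult"), inherits(exo_de, "DEResult"))
  list(
    common_up = intersect(normalize_mirna_id(cell_de$up_set),
                          normalize_mirna_id(exo_de$up_set)),
    common_down = intersect(normalize_mirna_id(cell_de$down_set),
                            normalize_mirna_id(exo_de$down_set))
  )
}

#' Coverage-filtered target prediction with direction inversion
#'
#' Given a set of miRNAs moving in one direction, counts for every gene
#' how many of those miRNAs list it as a target, and keeps genes targeted
#' by more than \code{min_fraction} of the set (strict inequality; the
#' ">50% of miRNAs" rule by default). Because miRNAs repress their
#' targets, the retained genes are predicted to move in the opposite
#' direction.
#'
#' @param mirna_set nonempty character vector of miRNA identifiers.
#' @param direction direction of the source miRNAs, \code{"up"} or
#'   \code{"down"}.
#' @param table a \code{\link{target_table}}.
#' @param min_fraction coverage threshold (default 0.5, strict).
#' @param denominator \code{"all"} (default): every miRNA in the set
#'   counts toward the denominator, including those absent from the
#'   target table (an absent miRNA targets nothing); or
#'   \code{"in_table"}: only miRNAs present in the table count.
#' @param coverage_filter logical; if FALSE the coverage rule is skipped
#'   and the union of all targets qualifies.
#' @return a \code{CoverageSet}: source set, per-gene target counts,
#'   qualifying genes and the predicted (inverted) direction.
#' @export
coverage_targets <- function(mirna_set, direction = c("up", "down"),
                             table, min_fraction = 0.5,
                             denominator = c("all", "in_table"),
                             coverage_filter = TRUE) {
  direction <- match.arg(direction)
  denominator <- match.arg(denominator)
  stopifnot(inherits(table, "TargetTable"))
  if (!length(mirna_set))
    stop("empty miRNA set: coverage fraction is undefined")
  if (min_fraction < 0 || min_fraction >= 1)
    stop("min_fraction must lie in [0, 1)")
  mirna_set <- unique(normalize_mirna_id(mirna_set))
  hits <- table$entries[intersect(mirna_set, names(table$entries))]
  counts <- table(unlist(hits, use.names = FALSE))
  counts <- stats::setNames(as.integer(counts), names(counts))
  denom <- if (denominator == "all") length(mirna_set) else length(hits)
  qualifying <- if (!coverage_filter) {
    names(counts)
  } else if (denom == 0L) {
    character()
  } else {
    names(counts)[counts / denom > min_fraction]
  }
  structure(
    list(source_mirnas = mirna_set, direction = direction,
         predicted_direction = if (direction == "up") "down" else "up",
         predicted_genes = counts, denominator = denom,
         qualifying_genes = sort(qualifying),
         min_fraction = min_fraction,
         coverage_filter = coverage_filter),
    class = "CoverageSet")
}

#' @export
print.CoverageSet <- function(x, ...) {
  cat("CoverageSet: ", length(x$source_mirnas), " ", x$direction,
      " miRNAs -> ", length(x$qualifying_genes), " predicted ",
      x$predicted_direction, " genes (coverage > ",
      x$min_fraction * 100, "% of ", x$denominator, ")\n", sep = "")
  invisible(x)
}

#' Map gene symbols to Entrez IDs
#'
#' Symbols missing from the map are reported as unmapped and excluded
#' from downstream ID-space intersections.
#'
#' @param genes character vector of gene symbols.
#' @param id_map a \code{\link{gene_id_map}}.
#' @return list with \code{ids} (named integer vector, names are the
#'   mapped symbols) and \code{unmapped} (character vector).
#' @export
map_ids <- function(genes, id_map) {
  stopifnot(inherits(id_map, "GeneIdMap"))
  genes <- unique(normalize_gene_id(genes))
  hit <- genes %in% names(id_map$ids)
  list(ids = id_map$ids[genes[hit]], unmapped = genes[!hit])
}

#' Integrate observed and predicted differential mRNAs into candidates
#'
#' The integration step: predicted up-regulated mRNAs are derived from
#' down-regulated miRNAs (and vice versa) through the coverage filter,
#' then intersected with the observed DE mRNA sets in Entrez ID space.
#' Two intersection graphs are available:
#' \describe{
#'   \item{\code{common_mirna_first}}{(default) first intersect the cell
#'     and exosome DE miRNA sets per direction, then predict targets from
#'     each common set, then intersect with the observed mRNA set: up
#'     candidates = observed up mRNAs \eqn{\cap} predicted-up genes from
#'     the common down-miRNAs.}
#'   \item{\code{per_compartment}}{predict targets separately from the
#'     cell and the exosome miRNA sets and require a three-way
#'     intersection: observed up mRNAs \eqn{\cap} predicted-up-from-cell
#'     \eqn{\cap} predicted-up-from-exosome.}
#' }
#' Every intermediate cardinality is recorded; genes without an Entrez ID
#' drop out before any intersection.
#'
#' @param mrna_de \code{DEResult} from \code{\link{mrna_de}}.
#' @param cell_mirna_de,exo_mirna_de \code{DEResult} objects from
#'   \code{\link{mirna_de}}.
#' @param table a \code{\link{target_table}}.
#' @param id_map a \code{\link{gene_id_map}}.
#' @param strategy \code{"common_mirna_first"} or
#'   \code{"per_compartment"}.
#' @param min_fraction coverage threshold (default 0.5, strict >).
#' @param denominator,coverage_filter passed to
#'   \code{\link{coverage_targets}}.
#' @return a \code{CandidateSet}.
#' @export
integrate_candidates <- function(mrna_de, cell_mirna_de, exo_mirna_de,
                                 table, id_map,
                                 strategy = c("common_mirna_first",
                                              "per_compartment"),
                                 min_fraction = 0.5,
                                 denominator = c("all", "in_table"),
                                 coverage_filter = TRUE) {
  strategy <- match.arg(strategy)
  denominator <- match.arg(denominator)
  stopifnot(inherits(mrna_de, "DEResult"))

  mrna_up <- map_ids(mrna_de$up_set, id_map)
  mrna_down <- map_ids(mrna_de$down_set, id_map)
  card <- list(
    n_mrna_up = length(mrna_de$up_set),
    n_mrna_down = length(mrna_de$down_set),
    n_mrna_up_mapped = length(mrna_up$ids),
    n_mrna_down_mapped = length(mrna_down$ids),
    n_cell_mirna_up = length(cell_mirna_de$up_set),
    n_cell_mirna_down = length(cell_mirna_de$down_set),
    n_exo_mirna_up = length(exo_mirna_de$up_set),
    n_exo_mirna_down = length(exo_mirna_de$down_set)
  )

  cov_sets <- list()
  predict_ids <- function(mirnas, direction, label) {
    if (!length(mirnas))
      return(list(ids = integer(), cov = NULL))
    cov <- coverage_targets(mirnas, direction, table,
                            min_fraction = min_fraction,
                            denominator = denominator,
                            coverage_filter = coverage_filter)
    mapped <- map_ids(cov$qualifying_genes, id_map)
    cov_sets[[label]] <<- cov
    list(ids = mapped$ids, cov = cov)
  }

  if (strategy == "common_mirna_first") {
    common <- common_mirnas(cell_mirna_de, exo_mirna_de)
    card$n_common_mirna_up <- length(common$common_up)
    card$n_common_mirna_down <- length(common$common_down)
    pred_up <- predict_ids(common$common_down, "down", "common_down")
    pred_down <- predict_ids(common$common_up, "up", "common_up")
    card$n_predicted_up <- length(pred_up$ids)
    card$n_predicted_down <- length(pred_down$ids)
    up_ids <- intersect(mrna_up$ids, pred_up$ids)
    down_ids <- intersect(mrna_down$ids, pred_down$ids)
    provenance_up <- c("mrna_up", "predicted_up_from_common_down_mirnas")
    provenance_down <- c("mrna_down", "predicted_down_from_common_up_mirnas")
  } else {
    pred_up_cell <- predict_ids(cell_mirna_de$down_set, "down",
                                "cell_down")
    pred_up_exo <- predict_ids(exo_mirna_de$down_set, "down", "exo_down")
    pred_down_cell <- predict_ids(cell_mirna_de$up_set, "up", "cell_up")
    pred_down_exo <- predict_ids(exo_mirna_de$up_set, "up", "exo_up")
    card$n_predicted_up_cell <- length(pred_up_cell$ids)
    card$n_predicted_up_exo <- length(pred_up_exo$ids)
    card$n_predicted_down_cell <- length(pred_down_cell$ids)
    card$n_predicted_down_exo <- length(pred_down_exo$ids)
    up_ids <- intersect(intersect(mrna_up$ids, pred_up_cell$ids),
                        pred_up_exo$ids)
    down_ids <- intersect(intersect(mrna_down$ids, pred_down_cell$ids),
                          pred_down_exo$ids)
    provenance_up <- c("mrna_up", "predicted_up_from_cell_down_mirnas",
                       "predicted_up_from_exo_down_mirnas")
    provenance_down <- c("mrna_down", "predicted_down_from_cell_up_mirnas",
                         "predicted_down_from_exo_up_mirnas")
  }
  card$n_candidates_up <- length(up_ids)
  card$n_candidates_down <- length(down_ids)

  as_gene_df <- function(ids, all_map, provenance) {
    symbols <- names(all_map$ids)[match(ids, all_map$ids)]
    df <- data.frame(symbol = symbols, entrez = as.integer(ids),
                     provenance = rep(paste(provenance, collapse = ";"),
                                      length(ids)),
                     stringsAsFactors = FALSE)
    df <- df[order(df$symbol), , drop = FALSE]
    rownames(df) <- NULL
    df
  }

  structure(
    list(up_genes = as_gene_df(up_ids, mrna_up, provenance_up),
         down_genes = as_gene_df(down_ids, mrna_down, provenance_down),
         strategy = strategy, min_fraction = min_fraction,
         coverage_sets = cov_sets,
         unmapped = unique(c(mrna_up$unmapped, mrna_down$unmapped)),
         cardinalities = card),
    class = "CandidateSet")
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat("CandidateSet (", x$strategy, "): ", nrow(x$up_genes),
      " up, ", nrow(x$down_genes), " down candidate genes\n", sep = "")
  for (k in names(x$cardinalities))
    cat("  ", k, ": ", x$cardinalities[[k]], "\n", sep = "")
  invisible(x)
}
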