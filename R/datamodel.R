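#' Case-normalize gene symbols
#'
#' Gene symbols are compared upper-cased throughout the package, because
#' lists produced by different tools (array annotation, target prediction,
#' ID maps) disagree on case more often than on anything else.
#'
#' @param x character vector of gene symbols.
#' @return upper-cased, whitespace-trimmed symbols.
#' @export
normalize_gene_id <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Case-normalize miRNA identifiers
#'
#' Lower-cases the identifier and restores the conventional "miR"
#' capitalization of mature miRNA names (e.g. \code{"HSA-MIR-21-5P"}
#' becomes \code{"hsa-miR-21-5p"}); \code{"let"} family names stay
#' lower-case per miRBase convention.
#'
#' @param x character vector of miRNA identifiers.
#' @return normalized identifiers.
#' @export
normalize_mirna_id <- function(x) {
  s <- tolower(trimws(as.character(x)))
  gsub("\\bmir\\b", "miR", s, perl = TRUE)
}

#' Construct an ExpressionMatrix
#'
#' The package's container for one microarray experiment: a dense
#' features-by-samples signal matrix plus per-sample metadata. Signals are
#' linear-scale fluorescence unless \code{is_log2} is set (normalization
#' sets it).
#'
#' @param signals numeric matrix, features in rows (rownames are the
#'   feature identifiers), samples in columns.
#' @param sample_meta data.frame with one row per column of
#'   \code{signals} and columns \code{sample}, \code{group},
#'   \code{replicate} (positive integer, pairing key), \code{compartment}
#'   (\code{"cell"}, \code{"exosome"} or \code{"none"}) and \code{assay}
#'   (\code{"mRNA"} or \code{"miRNA"}).
#' @param is_log2 logical; are the stored values log2?
#' @param normalized logical; has chip normalization been applied?
#' @return an object of class \code{ExpressionMatrix}.
#' @export
expression_matrix <- function(signals, sample_meta, is_log2 = FALSE,
                              normalized = FALSE) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("'signals' must be a numeric matrix")
  if (is.null(rownames(signals)))
    stop("'signals' must have feature identifiers as rownames")
  if (nrow(signals) == 0L)
    stop("no features: the signal matrix has zero rows")
  required <- c("sample", "group", "replicate", "compartment", "assay")
  missing_cols <- setdiff(required, names(sample_meta))
  if (length(missing_cols))
    stop("sample_meta lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(sample_meta) != ncol(signals))
    stop("sample_meta has ", nrow(sample_meta), " rows but signals has ",
         ncol(signals), " columns")
  if (anyNA(signals) || any(!is.finite(signals)))
    stop("signals contain missing or non-finite values; ",
         "dense arrays are required (no imputation is performed)")

  key <- toupper(rownames(signals))
  if (anyDuplicated(key)) {
    dup <- rownames(signals)[duplicated(key)]
    stop("duplicate feature identifier(s): ",
         paste(unique(dup), collapse = ", "))
  }
  if (!is_log2 && any(signals < 0))
    stop("linear-scale signals must be non-negative")

  sample_meta$sample      <- as.character(sample_meta$sample)
  sample_meta$group       <- as.character(sample_meta$group)
  sample_meta$replicate   <- as.integer(sample_meta$replicate)
  sample_meta$compartment <- as.character(sample_meta$compartment)
  sample_meta$assay       <- as.character(sample_meta$assay)
  if (any(sample_meta$replicate < 1L) || anyNA(sample_meta$replicate))
    stop("replicate indices must be positive integers")
  bad_cmp <- setdiff(unique(sample_meta$compartment),
                     c("cell", "exosome", "none"))
  if (length(bad_cmp))
    stop("unknown compartment(s): ", paste(bad_cmp, collapse = ", "))
  bad_assay <- setdiff(unique(sample_meta$assay), c("mRNA", "miRNA"))
  if (length(bad_assay))
    stop("unknown assay type(s): ", paste(bad_assay, collapse = ", "))
  for (g in unique(sample_meta$group)) {
    reps <- sample_meta$replicate[sample_meta$group == g]
    if (anyDuplicated(reps))
      stop("replicate indices within group '", g, "' are not unique")
  }
  rownames(sample_meta) <- NULL
  colnames(signals) <- sample_meta$sample

  structure(
    list(signals = signals, sample_meta = sample_meta,
         is_log2 = is_log2, normalized = normalized),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix: ", nrow(x$signals), " features x ",
      ncol(x$signals), " samples\n", sep = "")
  cat("  assay: ", paste(unique(x$sample_meta$assay), collapse = "/"),
      "; compartment: ",
      paste(unique(x$sample_meta$compartment), collapse = "/"), "\n",
      sep = "")
  cat("  groups: ", paste(sprintf("%s (n=%d)",
      names(table(x$sample_meta$group)), table(x$sample_meta$group)),
      collapse = ", "), "\n", sep = "")
  cat("  scale: ", if (x$is_log2) "log2" else "linear",
      if (x$normalized) ", normalized" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$signals)

#' Construct a TargetTable
#'
#' Maps each miRNA identifier to the set of gene symbols it is predicted
#' to target. Identifiers are case-normalized and target sets
#' de-duplicated on construction.
#'
#' @param entries named list; names are miRNA identifiers, elements are
#'   character vectors of target gene symbols.
#' @param dialect provenance label, \code{"targetscan7"} or
#'   \code{"two_column"}.
#' @return an object of class \code{TargetTable}.
#' @export
target_table <- function(entries, dialect = "two_column") {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop("all TargetTable entries must be named by a miRNA identifier")
  ids <- normalize_mirna_id(names(entries))
  if (anyDuplicated(ids))
    stop("duplicate miRNA identifier(s) after normalization: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  entries <- lapply(entries, function(g) sort(unique(normalize_gene_id(g))))
  if (any(lengths(entries) == 0L))
    stop("every miRNA must have a non-empty target set")
  names(entries) <- ids
  structure(list(entries = entries, dialect = dialect),
            class = "TargetTable")
}

#' @export
print.TargetTable <- function(x, ...) {
  cat("TargetTable (", x$dialect, "): ", length(x$entries),
      " miRNAs, ", length(unique(unlist(x$entries))),
      " distinct target genes\n", sep = "")
  invisible(x)
}

#' Construct a GeneIdMap
#'
#' A one-to-one map from (upper-cased) gene symbols to Entrez Gene IDs.
#' Symbols with no ID are recorded as unmapped and are dropped from all
#' downstream ID-space set operations, mirroring how symbol-to-Entrez
#' conversion shrinks gene lists.
#'
#' @param ids named integer vector; names are gene symbols, values
#'   positive Entrez IDs.
#' @param unmapped character vector of symbols known to lack an ID.
#' @return an object of class \code{GeneIdMap}.
#' @export
gene_id_map <- function(ids, unmapped = character()) {
  if (length(ids) && is.null(names(ids)))
    stop("'ids' must be named by gene symbol")
  symbols <- normalize_gene_id(names(ids))
  ids <- as.integer(ids)
  if (anyNA(ids) || any(ids <= 0L))
    stop("Entrez IDs must be positive integers")
  if (anyDuplicated(symbols)) {
    dup <- unique(symbols[duplicated(symbols)])
    first <- ids[match(dup, symbols)]
    clash <- vapply(dup, function(s)
      length(unique(ids[symbols == s])) > 1L, logical(1))
    if (any(clash))
      stop("ambiguous mapping: symbol(s) ",
           paste(dup[clash], collapse = ", "),
           " map to more than one Entrez ID")
    keep <- !duplicated(symbols)
    symbols <- symbols[keep]; ids <- ids[keep]; first <- NULL
  }
  names(ids) <- symbols
  structure(list(ids = ids, unmapped = unique(normalize_gene_id(unmapped))),
            class = "GeneIdMap")
}

#' @export
print.GeneIdMap <- function(x, ...) {
  cat("GeneIdMap: ", length(x$ids), " mapped symbols, ",
      length(x$unmapped), " unmapped\n", sep = "")
  invisible(x)
}

#' Construct a QpcrDataset
#'
#' Raw Ct values (cycles) for a panel of genes measured in biological
#' replicates of each group, plus the reference gene used for
#' delta-Ct normalization.
#'
#' @param ct data.frame with columns \code{gene}, \code{group},
#'   \code{replicate} and \code{ct}.
#' @param reference_gene symbol of the endogenous control (e.g. GAPDH).
#' @return an object of class \code{QpcrDataset}.
#' @export
qpcr_dataset <- function(ct, reference_gene) {
  required <- c("gene", "group", "replicate", "ct")
  missing_cols <- setdiff(required, names(ct))
  if (length(missing_cols))
    stop("ct table lacks column(s): ", paste(missing_cols, collapse = ", "))
  ct$gene <- normalize_gene_id(ct$gene)
  ct$group <- as.character(ct$group)
  ct$replicate <- as.integer(ct$replicate)
  ct$ct <- as.numeric(ct$ct)
  reference_gene <- normalize_gene_id(reference_gene)
  if (anyNA(ct$ct) || any(!is.finite(ct$ct)))
    stop("Ct values must be finite")
  if (any(ct$ct <= 0 | ct$ct > 45))
    stop("Ct values must lie in (0, 45] cycles")
  if (anyDuplicated(ct[c("gene", "group", "replicate")]))
    stop("duplicate (gene, group, replicate) Ct entries")
  wells <- unique(ct[c("group", "replicate")])
  ref <- ct[ct$gene == reference_gene, c("group", "replicate")]
  missing_ref <- wells[!interaction(wells) %in% interaction(ref), ,
                       drop = FALSE]
  if (nrow(missing_ref))
    stop("reference gene '", reference_gene, "' missing in ",
         paste(sprintf("%s replicate %d", missing_ref$group,
                       missing_ref$replicate), collapse = "; "))
  rownames(ct) <- NULL
  structure(list(ct = ct, reference_gene = reference_gene),
            class = "QpcrDataset")
}

#' @export
print.QpcrDataset <- function(x, ...) {
  cat("QpcrDataset: ", length(unique(x$ct$gene)), " genes, groups ",
      paste(unique(x$ct$group), collapse = "/"),
      ", reference ", x$reference_gene, "\n", sep = "")
  invisible(x)
}
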