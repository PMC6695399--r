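#' Read a tab-delimited expression table
#'
#' Expects one header row of sample names and a first column of feature
#' identifiers; all remaining cells are numeric signals. The sample
#' metadata specification assigns group, replicate, compartment and assay
#' to each sample name in the header.
#'
#' @param path file path (or connection) to a tab-delimited table.
#' @param sample_meta data.frame with columns \code{sample},
#'   \code{group}, \code{replicate}, \code{compartment}, \code{assay};
#'   every header sample name must appear in its \code{sample} column.
#' @param is_log2 logical; set when the stored values are already log2
#'   (e.g. a re-export of normalized data).
#' @return an \code{\link{expression_matrix}}.
#' @export
read_expression_table <- function(path, sample_meta, is_log2 = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L)
    stop("no features: the file is empty")
  parse_expression_lines(lines, sample_meta, is_log2 = is_log2)
}

parse_expression_lines <- function(lines, sample_meta, is_log2 = FALSE) {
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  samples <- header[-1L]
  if (length(cells) < 2L)
    stop("no features: the table has a header but no data rows")
  ncols <- length(header)
  widths <- lengths(cells)
  if (any(widths != ncols)) {
    bad <- which(widths != ncols)[1L]
    stop("ragged row ", bad, ": expected ", ncols, " fields, found ",
         widths[bad])
  }
  missing_spec <- setdiff(samples, sample_meta$sample)
  if (length(missing_spec))
    stop("sample(s) in header missing from sample metadata: ",
         paste(missing_spec, collapse = ", "))

  body <- cells[-1L]
  feature_ids <- vapply(body, `[[`, character(1), 1L)
  signals <- matrix(NA_real_, nrow = length(body), ncol = ncols - 1L,
                    dimnames = list(feature_ids, samples))
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1L]
      stop("non-numeric value '", body[[i]][j + 1L], "' at row '",
           feature_ids[i], "', column '", samples[j], "'")
    }
    signals[i, ] <- vals
  }
  meta <- sample_meta[match(samples, sample_meta$sample), , drop = FALSE]
  expression_matrix(signals, meta, is_log2 = is_log2)
}

#' Read a GEO series-matrix file
#'
#' Parses the series-matrix dialect: metadata lines prefixed with
#' \code{"!"} are skipped, and the expression block between
#' \code{!series_matrix_table_begin} and \code{!series_matrix_table_end}
#' is read as a tab-delimited expression table. Quoted fields are
#' unquoted.
#'
#' @inheritParams read_expression_table
#' @return an \code{\link{expression_matrix}}.
#' @export
read_geo_series_matrix <- function(path, sample_meta, is_log2 = FALSE) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end   <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L)
    stop("missing '!series_matrix_table_begin' sentinel")
  if (length(end) != 1L || end <= begin)
    stop("missing '!series_matrix_table_end' sentinel")
  block <- lines[(begin + 1L):(end - 1L)]
  block <- gsub('"', "", block, fixed = TRUE)
  block <- block[nzchar(block)]
  if (length(block) < 1L)
    stop("no features: empty series-matrix data block")
  parse_expression_lines(block, sample_meta, is_log2 = is_log2)
}

#' Read a miRNA target-prediction table
#'
#' Two dialects are supported. \code{"two_column"}: a header line then
#' rows of (miRNA identifier, target gene symbol). \code{"targetscan7"}:
#' a TargetScan-7-style flat file with named columns for the miRNA (or
#' family) identifier, the gene symbol and a species tax ID; only human
#' rows (tax ID 9606) are retained. Duplicate (miRNA, gene) rows collapse
#' by set semantics.
#'
#' @param path path to the tab-delimited file.
#' @param dialect \code{"two_column"} or \code{"targetscan7"}.
#' @return a \code{\link{target_table}}.
#' @export
read_target_table <- function(path, dialect = c("two_column", "targetscan7")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE,
                           colClasses = "character")
  if (dialect == "two_column") {
    if (ncol(tab) < 2L)
      stop("two_column dialect needs at least 2 columns")
    mirna <- tab[[1L]]
    gene <- tab[[2L]]
  } else {
    nm <- tolower(gsub("[ ._]", "", names(tab)))
    pick <- function(candidates, what) {
      hit <- which(nm %in% candidates)
      if (!length(hit))
        stop("targetscan7 dialect: missing required column for ", what)
      hit[1L]
    }
    i_mir <- pick(c("mirna", "mirfamily", "mirbaseid"), "miRNA identifier")
    i_gene <- pick(c("genesymbol", "symbol"), "gene symbol")
    i_tax <- pick(c("speciesid", "taxid", "species"), "species tax ID")
    keep <- tab[[i_tax]] == "9606"
    mirna <- tab[[i_mir]][keep]
    gene <- tab[[i_gene]][keep]
  }
  mirna <- normalize_mirna_id(mirna)
  gene <- normalize_gene_id(gene)
  ok <- nzchar(mirna) & nzchar(gene)
  entries <- split(gene[ok], mirna[ok])
  target_table(entries, dialect = dialect)
}

#' Read a gene symbol to Entrez ID map
#'
#' Two-column tab-delimited file (symbol, Entrez ID), in the style of a
#' BioMart export. A header row is auto-detected by a non-numeric second
#' field. Rows with an empty ID are recorded as unmapped; a symbol mapped
#' to two distinct IDs is an error.
#'
#' @param path path to the file.
#' @return a \code{\link{gene_id_map}}.
#' @export
read_gene_id_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_id_map(integer()))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  second <- vapply(cells, function(x) if (length(x) >= 2L) x[2L] else "",
                   character(1))
  has_header <- nzchar(second[1L]) &&
    is.na(suppressWarnings(as.numeric(second[1L])))
  if (has_header) {
    cells <- cells[-1L]
    second <- second[-1L]
  }
  symbols <- vapply(cells, `[[`, character(1), 1L)
  unmapped <- symbols[!nzchar(second)]
  keep <- nzchar(second)
  ids <- suppressWarnings(as.integer(second[keep]))
  if (anyNA(ids))
    stop("non-integer Entrez ID for symbol(s): ",
         paste(symbols[keep][is.na(ids)], collapse = ", "))
  names(ids) <- symbols[keep]
  pairs <- unique(data.frame(symbol = normalize_gene_id(names(ids)),
                             id = ids))
  out <- pairs$id
  names(out) <- pairs$symbol
  gene_id_map(out, unmapped = unmapped)
}

#' Write the candidate report
#'
#' Emits three files into \code{dir}: \code{candidates.tsv} (one row per
#' candidate gene with direction, Entrez ID and provenance columns),
#' \code{summary.txt} (all intersection cardinalities of the run) and
#' \code{run_metadata.json} (strategy, thresholds, seed, versions).
#'
#' @param candidates a \code{CandidateSet} from
#'   \code{\link{integrate_candidates}}.
#' @param de_summaries optional named list of \code{DEResult} objects
#'   whose up/down counts are echoed into the summary.
#' @param dir output directory, created if needed.
#' @param seed seed recorded in the metadata (NA if none).
#' @return invisibly, the paths written.
#' @export
write_candidate_report <- function(candidates, de_summaries = list(),
                                   dir, seed = NA) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  stopifnot(inherits(candidates, "CandidateSet"))

  tab <- candidate_table(candidates)
  tsv <- file.path(dir, "candidates.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  txt <- file.path(dir, "summary.txt")
  lines <- c(
    sprintf("integration strategy: %s", candidates$strategy),
    sprintf("candidate genes up: %d", nrow(candidates$up_genes)),
    sprintf("candidate genes down: %d", nrow(candidates$down_genes)),
    vapply(names(candidates$cardinalities), function(k)
      sprintf("%s: %d", k, candidates$cardinalities[[k]]), character(1)),
    vapply(names(de_summaries), function(k)
      sprintf("%s: %d up, %d down", k,
              length(de_summaries[[k]]$up_set),
              length(de_summaries[[k]]$down_set)), character(1))
  )
  writeLines(lines, txt)

  meta <- list(
    strategy = candidates$strategy,
    min_fraction = candidates$min_fraction,
    seed = seed,
    cardinalities = candidates$cardinalities,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("intermiR")),
    rng_kind = "Mersenne-Twister",
    percentile_convention = "linear interpolation between closest ranks"
  )
  js <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(candidates = tsv, summary = txt, metadata = js))
}

candidate_table <- function(candidates) {
  bind <- function(df, direction) {
    if (!nrow(df)) return(NULL)
    cbind(direction = direction, df)
  }
  out <- rbind(bind(candidates$up_genes, "up"),
               bind(candidates$down_genes, "down"))
  if (is.null(out))
    out <- data.frame(direction = character(), symbol = character(),
                      entrez = integer())
  out
}
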