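#' Per-replicate delta-Ct values
#'
#' For every gene, group and replicate: the gene's Ct minus the reference
#' gene's Ct in the same well set. Higher delta-Ct means lower
#' expression.
#'
#' @param data a \code{\link{qpcr_dataset}}.
#' @return data.frame with columns \code{gene}, \code{group},
#'   \code{replicate}, \code{delta_ct}; the reference gene itself is
#'   excluded.
#' @export
delta_ct <- function(data) {
  stopifnot(inherits(data, "QpcrDataset"))
  ct <- data$ct
  ref <- ct[ct$gene == data$reference_gene, ]
  key <- function(df) paste(df$group, df$replicate, sep = "\r")
  ref_ct <- stats::setNames(ref$ct, key(ref))
  out <- ct[ct$gene != data$reference_gene, ]
  out$delta_ct <- out$ct - unname(ref_ct[key(out)])
  out[c("gene", "group", "replicate", "delta_ct")]
}

#' qPCR fold change between groups
#'
#' Relative quantification: fold = 2^(mean delta-Ct in group1 minus mean
#' delta-Ct in group2), so fold > 1 means higher expression in group2.
#'
#' @param dct data.frame from \code{\link{delta_ct}}.
#' @param group1,group2 group labels.
#' @return data.frame with one row per gene: mean delta-Ct per group and
#'   the fold change (group2 relative to group1).
#' @export
qpcr_fold_change <- function(dct, group1 = "substate1",
                             group2 = "substate2") {
  genes <- unique(dct$gene)
  mean_dct <- function(gene, group) {
    v <- dct$delta_ct[dct$gene == gene & dct$group == group]
    if (!length(v)) stop("gene '", gene, "' has no delta-Ct in group '",
                         group, "'")
    mean(v)
  }
  m1 <- vapply(genes, mean_dct, numeric(1), group = group1)
  m2 <- vapply(genes, mean_dct, numeric(1), group = group2)
  data.frame(gene = genes, mean_dct_group1 = unname(m1),
             mean_dct_group2 = unname(m2),
             fold_change = 2^(unname(m1) - unname(m2)),
             stringsAsFactors = FALSE)
}

#' Confirm biomarker candidates by qPCR
#'
#' The confirmation rule applied to each candidate gene: the fold change
#' (group2 vs group1) must reach \code{fold_threshold} in the candidate's
#' direction, and an unpaired two-tailed t-test across replicates must
#' give p below \code{alpha}. The test is run on per-replicate relative
#' expression values (2^-delta-Ct) by default, matching statistics done
#' on the expression scale; \code{scale = "delta_ct"} tests the delta-Ct
#' values instead. Significance tiers (by default p < 0.1, < 0.05,
#' < 0.01) are reported alongside the binary confirmed flag. Candidates
#' without qPCR measurements are flagged untested.
#'
#' @param data a \code{\link{qpcr_dataset}}.
#' @param candidates a \code{CandidateSet}, or a data.frame with columns
#'   \code{symbol} and \code{direction} (\code{"up"}/\code{"down"}).
#' @param fold_threshold linear fold-change requirement (default 1.5).
#' @param alpha significance level for confirmation (default 0.05).
#' @param tiers decreasing p-value cutoffs for the reported tiers.
#' @param group1,group2 group labels.
#' @param scale \code{"expression"} (default) or \code{"delta_ct"}.
#' @return data.frame with one row per candidate: fold change, p,
#'   tier, direction match and the \code{confirmed} flag.
#' @export
confirm_candidates <- function(data, candidates, fold_threshold = 1.5,
                               alpha = 0.05, tiers = c(0.1, 0.05, 0.01),
                               group1 = "substate1", group2 = "substate2",
                               scale = c("expression", "delta_ct")) {
  scale <- match.arg(scale)
  if (fold_threshold < 1)
    stop("fold_threshold must be >= 1")
  tiers <- sort(tiers, decreasing = TRUE)
  if (inherits(candidates, "CandidateSet")) {
    cand <- candidate_table(candidates)
    cand <- cand[c("symbol", "direction")]
  } else {
    cand <- candidates[c("symbol", "direction")]
  }
  cand$symbol <- normalize_gene_id(cand$symbol)

  dct <- delta_ct(data)
  fc <- qpcr_fold_change(dct, group1, group2)

  rows <- lapply(seq_len(nrow(cand)), function(i) {
    gene <- cand$symbol[i]
    direction <- cand$direction[i]
    if (!gene %in% dct$gene)
      return(data.frame(symbol = gene, direction = direction,
                        fold_change = NA_real_, p = NA_real_,
                        tier = "untested", direction_match = NA,
                        confirmed = NA, stringsAsFactors = FALSE))
    fold <- fc$fold_change[fc$gene == gene]
    v1 <- dct$delta_ct[dct$gene == gene & dct$group == group1]
    v2 <- dct$delta_ct[dct$gene == gene & dct$group == group2]
    if (scale == "expression") {
      v1 <- 2^(-v1); v2 <- 2^(-v2)
    }
    p <- stats::t.test(v2, v1, var.equal = TRUE)$p.value
    fold_pass <- abs(log2(fold)) >= log2(fold_threshold)
    direction_match <- (direction == "up" && fold > 1) ||
      (direction == "down" && fold < 1)
    tier <- "ns"
    for (cut in tiers) if (p < cut) tier <- sprintf("p<%g", cut)
    data.frame(symbol = gene, direction = direction, fold_change = fold,
               p = p, tier = tier, direction_match = direction_match,
               confirmed = fold_pass && direction_match && p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
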