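#' Per-feature log2 fold changes between two groups
#'
#' For each feature, the mean log2 signal over the second group's samples
#' minus the mean over the first group's. Positive values mean higher
#' expression in \code{group2}.
#'
#' @param x a normalized (\code{is_log2 = TRUE}) \code{ExpressionMatrix}.
#' @param group1,group2 group labels; fold change is group2 minus group1.
#' @return named numeric vector of log2 fold changes.
#' @export
log2_fold_changes <- function(x, group1 = "substate1",
                              group2 = "substate2") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!x$is_log2)
    stop("log2_fold_changes requires log2-scale (normalized) signals")
  i1 <- which(x$sample_meta$group == group1)
  i2 <- which(x$sample_meta$group == group2)
  if (!length(i1)) stop("no samples in group '", group1, "'")
  if (!length(i2)) stop("no samples in group '", group2, "'")
  rowMeans(x$signals[, i2, drop = FALSE]) -
    rowMeans(x$signals[, i1, drop = FALSE])
}

group_means <- function(x, group) {
  i <- which(x$sample_meta$group == group)
  rowMeans(x$signals[, i, drop = FALSE])
}

#' Z-score selection of differential features
#'
#' Standardizes the fold-change distribution itself: each feature's
#' log2 fold change is centered by the mean over all features and scaled
#' by the sample standard deviation (n - 1 denominator), and features
#' with |z| at or beyond the threshold are called up or down. This is the
#' mRNA-array branch, where few replicates preclude per-feature testing
#' and outlying fold changes relative to the array-wide distribution are
#' taken as significant.
#'
#' @param log2fc named numeric vector of per-feature log2 fold changes.
#' @param z_threshold call threshold on |z| (default 2).
#' @param center logical; center by the distribution mean (default TRUE).
#'   Uncentered scores divide the raw fold change by the sd.
#' @return a \code{DEResult}.
#' @export
zscore_select <- function(log2fc, z_threshold = 2, center = TRUE) {
  if (length(log2fc) < 3L)
    stop("Z-score selection needs at least 3 features")
  if (any(!is.finite(log2fc)))
    stop("non-finite log2 fold changes")
  if (z_threshold <= 0)
    stop("z_threshold must be > 0")
  mu <- if (center) mean(log2fc) else 0
  sigma <- stats::sd(log2fc)
  if (sigma == 0)
    stop("degenerate fold-change distribution: standard deviation is 0")
  z <- (log2fc - mu) / sigma
  call <- ifelse(z >= z_threshold, "up",
                 ifelse(z <= -z_threshold, "down", "neither"))
  tab <- data.frame(feature = names(log2fc), log2FC = unname(log2fc),
                    z = unname(z), call = unname(call),
                    stringsAsFactors = FALSE)
  de_result(tab, branch = "zscore",
            thresholds = list(z_threshold = z_threshold,
                              centered = center,
                              fc_mean = mu, fc_sd = sigma))
}

#' Row-wise paired t-tests
#'
#' For every feature, a two-sided paired t-test on log2 signals, pairing
#' the replicate with the same \code{replicate} index across the two
#' groups; differences are group2 minus group1. A feature whose paired
#' differences are all zero gets p = 1; nonzero differences with zero
#' variance get the p = 0 sentinel with a warning (the statistic is
#' infinite).
#'
#' @param x a normalized \code{ExpressionMatrix} with equal replicate
#'   counts in both groups.
#' @param group1,group2 group labels.
#' @return data.frame with columns \code{feature}, \code{mean_diff},
#'   \code{t_stat}, \code{p}.
#' @export
paired_ttest <- function(x, group1 = "substate1", group2 = "substate2") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!x$is_log2)
    stop("paired_ttest requires log2-scale (normalized) signals")
  m <- x$sample_meta
  i1 <- which(m$group == group1)
  i2 <- which(m$group == group2)
  if (length(i1) != length(i2) || length(i1) < 2L)
    stop("paired design requires equal replicate counts (>= 2) per group")
  r1 <- m$replicate[i1]
  r2 <- m$replicate[i2]
  if (!setequal(r1, r2))
    stop("unpairable samples: replicate indices differ between groups")
  i1 <- i1[order(r1)]
  i2 <- i2[order(r2)]
  d <- x$signals[, i2, drop = FALSE] - x$signals[, i1, drop = FALSE]
  n <- ncol(d)
  mean_d <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - mean_d)^2) / (n - 1L))
  t_stat <- mean_d / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  zero_var <- sd_d == 0
  all_zero <- zero_var & mean_d == 0
  degenerate <- zero_var & mean_d != 0
  p[all_zero] <- 1
  t_stat[all_zero] <- 0
  if (any(degenerate)) {
    warning(sum(degenerate), " feature(s) with zero-variance nonzero ",
            "paired differences; reporting p = 0 sentinel")
    p[degenerate] <- 0
  }
  data.frame(feature = rownames(x$signals), mean_diff = unname(mean_d),
             t_stat = unname(t_stat), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method \code{"BH"} (default) or \code{"bonferroni"}.
#' @return q-values, same length and order as \code{p}.
#' @export
bh_fdr <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' miRNA differential expression: fold filter, paired test, FDR
#'
#' The miRNA-array branch: features with an absolute fold change of at
#' least \code{fold_threshold} between the groups enter testing; a
#' two-sided paired t-test is run on that subset; q-values are computed
#' over the subset only (the fold filter precedes significance analysis);
#' features with q below \code{q_threshold} are called up or down by the
#' sign of the fold change.
#'
#' @param x a normalized miRNA \code{ExpressionMatrix}, paired design.
#' @param fold_threshold linear fold-change filter (default 2; features
#'   need |log2FC| >= log2(fold_threshold)).
#' @param q_threshold FDR call threshold (default 0.05).
#' @param group1,group2 group labels.
#' @param genomewide_fdr logical; correct over all features instead of
#'   the fold-passing subset (default FALSE).
#' @param correction \code{"BH"} or \code{"bonferroni"}.
#' @return a \code{DEResult}; features excluded by the fold filter carry
#'   NA statistics and call \code{"neither"}.
#' @export
mirna_de <- function(x, fold_threshold = 2, q_threshold = 0.05,
                     group1 = "substate1", group2 = "substate2",
                     genomewide_fdr = FALSE,
                     correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  if (fold_threshold < 1)
    stop("fold_threshold must be >= 1 (linear scale)")
  lfc <- log2_fold_changes(x, group1, group2)
  pass <- abs(lfc) >= log2(fold_threshold)
  test_set <- if (genomewide_fdr) rep(TRUE, length(lfc)) else pass
  if (!any(pass))
    warning("no features pass the ", fold_threshold,
            "-fold filter; returning an empty result")
  t_stat <- p <- q <- rep(NA_real_, length(lfc))
  if (any(test_set)) {
    sub <- x
    sub$signals <- x$signals[test_set, , drop = FALSE]
    tt <- paired_ttest(sub, group1, group2)
    t_stat[test_set] <- tt$t_stat
    p[test_set] <- tt$p
    q[test_set] <- bh_fdr(tt$p, correction)
  }
  call <- rep("neither", length(lfc))
  sig <- pass & !is.na(q) & q < q_threshold
  call[sig & lfc > 0] <- "up"
  call[sig & lfc < 0] <- "down"
  tab <- data.frame(
    feature = names(lfc),
    mean_substate1 = unname(group_means(x, group1)),
    mean_substate2 = unname(group_means(x, group2)),
    log2FC = unname(lfc),
    t_stat = t_stat, p = p, q = q, call = call,
    stringsAsFactors = FALSE)
  de_result(tab, branch = "paired_fold",
            thresholds = list(fold_threshold = fold_threshold,
                              q_threshold = q_threshold,
                              correction = correction,
                              genomewide_fdr = genomewide_fdr))
}

#' mRNA differential expression by Z-score
#'
#' Convenience wrapper: per-feature log2 fold changes on the normalized
#' matrix, then \code{\link{zscore_select}}.
#'
#' @inheritParams log2_fold_changes
#' @inheritParams zscore_select
#' @return a \code{DEResult}.
#' @export
mrna_de <- function(x, z_threshold = 2, group1 = "substate1",
                    group2 = "substate2", center = TRUE) {
  m1 <- group_means(x, group1)
  m2 <- group_means(x, group2)
  res <- zscore_select(log2_fold_changes(x, group1, group2),
                       z_threshold = z_threshold, center = center)
  res$table <- cbind(res$table[, "feature", drop = FALSE],
                     mean_substate1 = unname(m1),
                     mean_substate2 = unname(m2),
                     res$table[, c("log2FC", "z", "call")])
  res
}

de_result <- function(table, branch, thresholds) {
  stopifnot(is.data.frame(table), "call" %in% names(table))
  structure(
    list(table = table,
         up_set = table$feature[table$call == "up"],
         down_set = table$feature[table$call == "down"],
         branch = branch, thresholds = thresholds),
    class = "DEResult")
}

#' @export
print.DEResult <- function(x, ...) {
  cat("DEResult (", x$branch, "): ", nrow(x$table), " features, ",
      length(x$up_set), " up, ", length(x$down_set), " down\n", sep = "")
  thr <- x$thresholds
  cat("  thresholds: ",
      paste(sprintf("%s=%s", names(thr),
                    vapply(thr, function(v) format(v, digits = 4),
                           character(1))),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a DEResult table
#'
#' Serializes the per-feature table (fold change, statistic, p, q, call)
#' as tab-delimited text.
#'
#' @param x a \code{DEResult}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_de_table <- function(x, path) {
  stopifnot(inherits(x, "DEResult"))
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
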