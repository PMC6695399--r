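# Independent brute-force oracles used to cross-check the implementation.

# Benjamini-Hochberg by the explicit min-over-tails formula:
# q_i = min over all j with p_(j) >= p_i of p_(j) * m / rank(j), capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- ps * m / seq_len(m)
  q_sorted <- vapply(seq_len(m), function(i) min(1, adj[i:m]), numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Percentile by explicit sorting and linear interpolation between the
# closest ranks: h = (n - 1) * p + 1.
percentile_brute <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Coverage filter by gene-wise enumeration over the raw (miRNA, gene)
# pair list.
coverage_brute <- function(mirna_set, pairs, min_fraction = 0.5) {
  mirna_set <- unique(mirna_set)
  genes <- unique(pairs$gene)
  keep <- vapply(genes, function(g) {
    cnt <- sum(vapply(mirna_set, function(m)
      any(pairs$mirna == m & pairs$gene == g), logical(1)))
    cnt / length(mirna_set) > min_fraction
  }, logical(1))
  sort(genes[keep])
}

# Small ExpressionMatrix builder: `signals` features x (2 * r) with
# substate1 replicates first.
make_em <- function(signals, assay = "miRNA", compartment = "cell",
                    is_log2 = FALSE, normalized = FALSE) {
  r <- ncol(signals) / 2
  meta <- data.frame(
    sample = paste0("s", seq_len(ncol(signals))),
    group = rep(c("substate1", "substate2"), each = r),
    replicate = rep(seq_len(r), 2),
    compartment = compartment, assay = assay,
    stringsAsFactors = FALSE)
  expression_matrix(signals, meta, is_log2 = is_log2,
                    normalized = normalized)
}

# Labeled matrix from per-feature rows.
sig <- function(..., features = NULL) {
  m <- rbind(...)
  rownames(m) <- if (is.null(features))
    paste0("F", seq_len(nrow(m))) else features
  m
}

# Swap the substate labels of an ExpressionMatrix (for symmetry tests).
swap_groups <- function(em) {
  g <- em$sample_meta$group
  em$sample_meta$group <- ifelse(g == "substate1", "substate2",
                                 "substate1")
  em
}

# Tiny DEResult stub from explicit up/down sets.
de_stub <- function(up = character(), down = character()) {
  feats <- c(up, down)
  tab <- data.frame(feature = feats,
                    call = c(rep("up", length(up)),
                             rep("down", length(down))),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, up_set = up, down_set = down,
                 branch = "stub", thresholds = list()),
            class = "DEResult")
}
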