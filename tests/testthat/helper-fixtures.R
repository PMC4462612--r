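# Fixture builders and independent oracles shared across test files.
# Oracles deliberately use different code paths from the package
# (enumeration, double loops, stats::t.test) so agreement is evidence.

options(twinmeth.verbose = FALSE)

# ---- fixture builders ------------------------------------------------------

make_design <- function(n_c = 1L, n_d = 2L, n_h = 1L) {
  pid <- c(sprintf("C%d", seq_len(n_c)), sprintf("D%d", seq_len(n_d)),
           sprintf("H%d", seq_len(n_h)))
  grp <- rep(c("concordant", "discordant", "healthy"), c(n_c, n_d, n_h))
  twin_design(data.frame(
    sample_id = as.vector(rbind(paste0(pid, "_1"), paste0(pid, "_2"))),
    pair_id = rep(pid, each = 2L),
    group = rep(grp, each = 2L),
    affected = as.vector(rbind(grp != "healthy", grp == "concordant"))
  ))
}

make_beta <- function(values, design, probe_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(probe_ids)) probe_ids <- sprintf("cg%08d", seq_len(nrow(values)))
  beta_matrix(values, probe_ids = probe_ids, sample_ids = design$sample_id)
}

random_beta <- function(n_probes, design) {
  make_beta(matrix(runif(n_probes * nrow(design)), nrow = n_probes), design)
}

make_annotation <- function(probe_ids, gene = "GENE1", feature = "Body") {
  probe_annotation(data.frame(
    probe_id = probe_ids, chr = "chr1", pos = seq_along(probe_ids),
    gene = gene, feature = feature
  ))
}

# ---- oracles ---------------------------------------------------------------

# Rank scores by explicit beats-counting: score = (#strictly worse) plus the
# averaged tie positions (including self).
oracle_rank_scores <- function(values, better) {
  vapply(values, function(v) {
    worse <- if (better == "lower") sum(values > v) else sum(values < v)
    ties <- sum(values == v)
    worse + (ties + 1) / 2
  }, numeric(1L))
}

# Brute-force DMP ranking: stats::t.test per probe, oracle scores, explicit
# sort keys. Returns probe ids in rank order.
oracle_rank_dmps <- function(b, design) {
  pairs <- design_pairs(design)
  disc <- pairs[pairs$group == "discordant", ]
  m <- unclass(b)
  p <- numeric(nrow(m)); md <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    d <- m[i, disc$twin1] - m[i, disc$twin2]
    md[i] <- mean(d)
    # degenerate = numerically constant differences (limiting P values)
    p[i] <- if (stats::sd(d) <= sqrt(.Machine$double.eps) * max(abs(md[i]), 1)) {
      if (md[i] == 0) 1 else 0
    } else {
      stats::t.test(d)$p.value
    }
  }
  # same 12-decimal tie detection as the package contract
  p <- round(p, 12); ad <- round(abs(md), 12)
  comb <- oracle_rank_scores(p, "lower") + oracle_rank_scores(ad, "higher")
  rownames(m)[order(-comb, p, rownames(m))]
}

# Exact one-sided WMW P by enumerating all C(n1+n2, n1) group labelings.
oracle_wmw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- ustat(x, y)
  labelings <- utils::combn(length(pooled), n1)
  u_all <- apply(labelings, 2L, function(idx) ustat(pooled[idx], pooled[-idx]))
  mean(u_all >= u_obs - 1e-9)
}

# Hypergeometric upper-tail P by enumerating all C(N, n) draws.
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2L, function(d) sum(d <= K))  # items 1..K are "in set"
  mean(hits >= k)
}

# Benjamini-Hochberg step-up by the textbook formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
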