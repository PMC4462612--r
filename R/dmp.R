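# Differentially methylated probes (DMPs): rank-combination of paired-t
# P-values and mean intrapair beta differences over disease-discordant pairs.
#
# Per probe, a paired t-test contrasts affected vs unaffected co-twins of the
# discordant pairs; one rank score rewards small P-values, a second rewards
# large |mean delta-beta|; the scores are added and probes ranked from high
# to low combined score, so the top of the rank holds probes with both a low
# P and a relatively large methylation difference.

#' Paired t-test on affected vs unaffected co-twin values
#'
#' Classical paired t on the within-pair differences `affected - unaffected`,
#' `df = n - 1`, two-sided P. Degenerate inputs (zero variance of the
#' differences) are flagged: P is the limiting value 0 when the common
#' difference is non-zero and 1 when it is zero.
#'
#' @param affected,unaffected numeric vectors of beta values, paired by
#'   position (one entry per pair).
#' @return list with `t`, `p_value`, `mean_delta`, `df`, `degenerate`.
#' @export
paired_t_test <- function(affected, unaffected) {
  if (length(affected) != length(unaffected)) {
    tm_error("tm_validation_error", "affected/unaffected must pair up")
  }
  res <- paired_t_rows(matrix(affected - unaffected, nrow = 1L))
  list(t = res$t[1L], p_value = res$p_value[1L], mean_delta = res$mean_delta[1L],
       df = length(affected) - 1L, degenerate = res$degenerate[1L])
}

# Vectorised paired t over a probes x pairs matrix of within-pair
# differences. Returns one row of statistics per probe.
paired_t_rows <- function(diffs) {
  n <- ncol(diffs)
  if (n < 2L) {
    tm_error("tm_validation_error", "paired t-test needs >= 2 pairs")
  }
  m <- rowMeans(diffs)
  # sample sd of differences, guarded against tiny negative fp residue
  ss <- pmax(rowSums(diffs * diffs) - n * m * m, 0)
  sd <- sqrt(ss / (n - 1L))
  degenerate <- sd <= .Machine$double.eps^0.5 * pmax(abs(m), 1)
  t <- ifelse(degenerate, ifelse(m == 0, 0, sign(m) * Inf), m / (sd / sqrt(n)))
  p <- ifelse(degenerate, ifelse(m == 0, 1, 0),
              2 * stats::pt(-abs(t), df = n - 1L))
  data.frame(t = t, p_value = p, mean_delta = m, degenerate = degenerate)
}

#' Linear rank scores for probe prioritisation
#'
#' Maps `m` values to scores in `1..m`: the best value receives score `m`,
#' the worst 1, and ties receive the mean of the tied rank positions. With
#' `better = "lower"` small values score high (P-values); with
#' `better = "higher"` large values score high (|delta beta|).
#'
#' @param values finite numeric vector, one per probe.
#' @param better direction of merit, `"lower"` or `"higher"`.
#' @return numeric scores, same length as `values`.
#' @export
rank_scores <- function(values, better = c("lower", "higher")) {
  better <- match.arg(better)
  if (!length(values)) tm_error("tm_validation_error", "rank_scores: empty input")
  r <- rank(values, ties.method = "average")
  if (better == "lower") length(values) + 1 - r else r
}

#' Rank probes by combined P-value and effect-size scores
#'
#' Runs the full DMP procedure on the discordant pairs of the design:
#' per-probe paired t-test (affected minus unaffected), rank scores from the
#' P-values (`better = "lower"`) and from |mean delta-beta|
#' (`better = "higher"`), combined score = sum, probes sorted by combined
#' score descending. Equal combined scores break ties by smaller P, then
#' probe id, so output is deterministic.
#'
#' Probes with missing values in any discordant-pair sample are dropped
#' (with a logged count) before testing.
#'
#' @param b a [beta_matrix].
#' @param design a [twin_design] with >= 2 discordant pairs.
#' @param top_k how many top probes [top_dmps] should extract (stored in the
#'   result; default 10).
#' @return data.frame of class `dmp_result`, one row per probe, ordered by
#'   rank: columns `probe_id`, `p_value`, `mean_delta`, `t`, `degenerate`,
#'   `p_score`, `delta_score`, `combined_score`, `rank`.
#' @export
rank_dmps <- function(b, design, top_k = 10) {
  if (top_k < 1) tm_error("tm_validation_error", "top_k must be >= 1")
  pairs <- design_pairs(design)
  disc <- pairs[pairs$group == "discordant", ]
  if (nrow(disc) < 2L) {
    tm_error("tm_validation_error", "need >= 2 discordant pairs for DMP ranking")
  }
  used <- c(disc$twin1, disc$twin2)
  missing_samp <- setdiff(used, colnames(b))
  if (length(missing_samp)) {
    tm_error("tm_validation_error",
             paste("samples absent from beta matrix:", paste(missing_samp, collapse = ", ")))
  }
  bb <- filter_complete_probes(b, used)
  diffs <- unclass(bb)[, disc$twin1, drop = FALSE] -
    unclass(bb)[, disc$twin2, drop = FALSE]
  tt <- paired_t_rows(diffs)
  # ties are detected after rounding to 12 decimals (both quantities live in
  # [0,1]) so analytically equal P-values or |delta| are not split by
  # last-ulp floating-point noise
  p_r <- round(tt$p_value, 12)
  d_r <- round(abs(tt$mean_delta), 12)
  p_score <- rank_scores(p_r, better = "lower")
  delta_score <- rank_scores(d_r, better = "higher")
  res <- data.frame(
    probe_id = rownames(bb),
    p_value = tt$p_value,
    mean_delta = tt$mean_delta,
    t = tt$t,
    degenerate = tt$degenerate,
    p_score = p_score,
    delta_score = delta_score,
    combined_score = p_score + delta_score,
    stringsAsFactors = FALSE
  )
  ord <- order(-res$combined_score, p_r, res$probe_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "top_k") <- as.integer(top_k)
  attr(res, "n_pairs") <- nrow(disc)
  class(res) <- c("dmp_result", "data.frame")
  res
}

#' Extract the top-k ranked DMPs
#'
#' @param dmp a `dmp_result` from [rank_dmps].
#' @param k number of probes (default: the `top_k` stored in the result).
#' @return the first `k` rows.
#' @export
top_dmps <- function(dmp, k = attr(dmp, "top_k")) {
  utils::head(dmp, n = if (is.null(k)) 10L else k)
}

#' Join DMP results against probe annotation
#'
#' Produces a report with the columns of the study-style top table: probe,
#' P-value, mean delta-beta, coordinates, gene name(s), gene-region feature
#' category. Unannotated probes get empty fields.
#'
#' @param dmp a `dmp_result` (typically [top_dmps] output).
#' @param ann a [probe_annotation].
#' @return data.frame with annotation columns appended.
#' @export
annotate_dmps <- function(dmp, ann) {
  idx <- match(dmp$probe_id, ann$probe_id)
  out <- as.data.frame(dmp)
  out$chr <- ifelse(is.na(idx), "", ann$chr[idx])
  out$pos <- ann$pos[idx]
  out$gene <- ifelse(is.na(idx), "", ann$gene[idx])
  out$feature <- ifelse(is.na(idx), "", ann$feature[idx])
  out
}
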