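# Cross-group validation of top DMPs: are absolute intrapair differences in
# discordant pairs stochastically larger than in concordant and healthy
# pairs? One-sided Wilcoxon-Mann-Whitney per probe, exact in the small
# tie-free regime the 4/6/7-pair design lives in.

#' One-sided Wilcoxon–Mann–Whitney test
#'
#' Tests the alternative that `x` is stochastically greater than `y`.
#' The U statistic counts pairs `(x_i, y_j)` with `x_i > y_j` (ties count
#' one half). P is exact — from the null rank-sum distribution — when
#' `length(x) + length(y) <= max_exact` and the pooled sample is tie-free;
#' otherwise the normal approximation with continuity correction and
#' tie-corrected variance is used.
#'
#' @param x,y numeric samples, each non-empty.
#' @param max_exact largest pooled size for the exact path (default 13,
#'   covering the 6-vs-7 and 6-vs-4 splits of a 4/6/7-pair twin design).
#' @return list with `U`, `p_value`, `exact` (logical).
#' @export
wmw_one_sided <- function(x, y, max_exact = 13L) {
  if (!length(x) || !length(y)) {
    tm_error("tm_validation_error", "wmw_one_sided: empty sample")
  }
  m <- length(x); n <- length(y)
  gt <- outer(x, y, ">")
  eq <- outer(x, y, "==")
  U <- sum(gt) + 0.5 * sum(eq)
  pooled <- c(x, y)
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && (m + n) <= max_exact) {
    # exact: P(U >= u) under the null rank-sum distribution
    p <- stats::pwilcox(U - 1, m, n, lower.tail = FALSE)
    return(list(U = U, p_value = p, exact = TRUE))
  }
  mu <- m * n / 2
  tab <- table(pooled)
  N <- m + n
  tie_term <- sum(tab^3 - tab) / ((N) * (N - 1))
  sigma2 <- (m * n / 12) * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    # all values identical: no evidence either way
    return(list(U = U, p_value = 1, exact = FALSE))
  }
  z <- (U - 0.5 - mu) / sqrt(sigma2)
  list(U = U, p_value = stats::pnorm(z, lower.tail = FALSE), exact = FALSE)
}

#' Validate top DMPs against concordant and healthy pairs
#'
#' For each requested probe, per-pair absolute intrapair differences |Δβ|
#' are computed in all pairs of the design (orientation-free by the absolute
#' value), then two one-sided Wilcoxon–Mann–Whitney tests ask whether the
#' discordant-pair |Δβ| are larger than (a) the concordant-pair and (b) the
#' healthy-pair values. A probe is `validated` on a comparison when its
#' one-sided P falls below `alpha_level`.
#'
#' @param b a [beta_matrix].
#' @param design a [twin_design] with all three groups present.
#' @param probes character vector of probe ids to validate.
#' @param alpha_level significance level for the validated flags
#'   (default 0.05).
#' @return data.frame of class `dmp_validation`: per probe, the two U
#'   statistics and P-values, exactness flags, and the validated booleans.
#' @export
validate_dmps <- function(b, design, probes, alpha_level = 0.05) {
  groups_present <- unique(design$group)
  if (!all(TM_GROUPS %in% groups_present)) {
    tm_error("tm_validation_error",
             "validation needs concordant, discordant and healthy pairs")
  }
  adm <- abs_diff_matrix(b, design)
  absent <- setdiff(probes, rownames(adm))
  if (length(absent)) {
    tm_error("tm_validation_error",
             paste("probes absent from beta matrix:", paste(absent, collapse = ", ")))
  }
  pair_groups <- attr(adm, "pair_groups")
  rows <- lapply(probes, function(p) {
    v <- adm[p, ]
    d <- v[pair_groups == "discordant"]
    co <- v[pair_groups == "concordant"]
    h <- v[pair_groups == "healthy"]
    tc <- wmw_one_sided(d, co)
    th <- wmw_one_sided(d, h)
    data.frame(
      probe_id = p,
      u_vs_concordant = tc$U, p_vs_concordant = tc$p_value, exact_vs_concordant = tc$exact,
      u_vs_healthy = th$U, p_vs_healthy = th$p_value, exact_vs_healthy = th$exact,
      validated_vs_concordant = tc$p_value < alpha_level,
      validated_vs_healthy = th$p_value < alpha_level,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha_level") <- alpha_level
  class(out) <- c("dmp_validation", "data.frame")
  out
}
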