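# Beta computation from fluorescence intensities and per-analysis probe
# filtering.

#' Compute methylation beta values from intensities
#'
#' The methylation fraction of a CpG site is estimated as
#' \deqn{\beta = M / (M + U + \alpha)}
#' where `M` and `U` are the methylated and unmethylated fluorescence
#' intensities and `alpha` is a stabilising offset guarding against
#' near-zero total intensity (platform convention: 100).
#'
#' Vectorised over `M` and `U`. For `alpha > 0` the result is strictly below
#' 1 and strictly increasing in `M` / decreasing in `U`.
#'
#' @param M,U non-negative intensities (recycled to common length).
#' @param alpha non-negative offset, default 100.
#' @return beta values in `[0, 1)` (in `[0, 1]` when `alpha = 0`).
#' @examples
#' compute_beta(300, 100)        # 0.6
#' compute_beta(100, 100, alpha = 0)  # 0.5
#' @export
compute_beta <- function(M, U, alpha = 100) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE) || alpha < 0) {
    tm_error("tm_validation_error", "intensities and alpha must be non-negative")
  }
  tot <- M + U + alpha
  if (any(tot == 0, na.rm = TRUE)) {
    tm_error("tm_undefined_value_error", "M + U + alpha = 0: beta undefined")
  }
  M / tot
}

#' Logit (M-value) transform of beta values
#'
#' `log2(beta / (1 - beta))`, offered as an opt-in utility only; every
#' analysis in this package operates on the beta scale.
#'
#' @param beta values in (0, 1).
#' @param eps betas are clamped to `[eps, 1 - eps]` before the logit.
#' @return M-values.
#' @export
beta_to_mvalue <- function(beta, eps = 1e-6) {
  b <- clip01(beta, eps, 1 - eps)
  log2(b / (1 - b))
}

#' Restrict a beta matrix to samples and complete probes
#'
#' Subsets to the given samples and drops every probe with at least one
#' missing value among them (logging the count). Probes missing only in
#' non-selected samples are retained.
#'
#' @param b a [beta_matrix].
#' @param samples character vector of sample ids (default: all).
#' @return a [beta_matrix] restricted to `samples` and complete probes.
#' @export
filter_complete_probes <- function(b, samples = colnames(b)) {
  unknown <- setdiff(samples, colnames(b))
  if (length(unknown)) {
    tm_error("tm_validation_error",
             paste("unknown sample_id:", paste(unknown, collapse = ", ")))
  }
  sub <- unclass(b)[, samples, drop = FALSE]
  keep <- rowSums(is.na(sub)) == 0L
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    tm_log("dropped %d probe(s) with missing values among %d selected samples",
           n_drop, length(samples))
  }
  out <- sub[keep, , drop = FALSE]
  class(out) <- c("beta_matrix", class(out))
  out
}
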