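# Variably methylated probes (VMPs): absolute intrapair difference matrix ->
# per-group medians (the m x 3 matrix) -> inclusive 0.1 threshold ->
# group-exclusivity partition -> summaries.
#
# Medians are used as the per-group centrality measure because they are more
# robust to a single outlying pair than means; the Venn partition operates on
# the thresholded median indicator per group.

#' Absolute intrapair difference matrix
#'
#' One column per twin pair; the cell for probe p and pair q is
#' `|beta_twin1 - beta_twin2|`, invariant to the within-pair orientation.
#' Probes with missing values in any pair member are dropped with a logged
#' count.
#'
#' @param b a [beta_matrix].
#' @param design a [twin_design]; every pair member must be a column of `b`.
#' @return numeric matrix (probes x pairs) of class `abs_diff_matrix` with
#'   attribute `pair_groups` giving each pair's diagnostic group.
#' @export
abs_diff_matrix <- function(b, design) {
  pairs <- design_pairs(design)
  missing_samp <- setdiff(c(pairs$twin1, pairs$twin2), colnames(b))
  if (length(missing_samp)) {
    bad_pairs <- pairs$pair_id[pairs$twin1 %in% missing_samp |
                                 pairs$twin2 %in% missing_samp]
    tm_error("tm_validation_error", sprintf(
      "pair member(s) missing from beta matrix for pair(s): %s",
      paste(unique(bad_pairs), collapse = ", ")))
  }
  bb <- filter_complete_probes(b, c(pairs$twin1, pairs$twin2))
  m <- unclass(bb)
  out <- abs(m[, pairs$twin1, drop = FALSE] - m[, pairs$twin2, drop = FALSE])
  colnames(out) <- pairs$pair_id
  structure(out, pair_groups = pairs$group,
            class = c("abs_diff_matrix", class(out)))
}

#' Per-group medians of absolute intrapair differences
#'
#' Collapses the pair columns of an [abs_diff_matrix] to one median column
#' per diagnostic group, yielding the m x 3 matrix at the core of the VMP
#' procedure. Even group sizes average the two central order statistics.
#'
#' @param adm an [abs_diff_matrix].
#' @return numeric matrix (probes x 3) with columns
#'   `concordant, discordant, healthy`, class `group_median_matrix`.
#' @export
group_medians <- function(adm) {
  pair_groups <- attr(adm, "pair_groups")
  if (is.null(pair_groups)) {
    tm_error("tm_validation_error", "input lacks pair_groups; use abs_diff_matrix()")
  }
  cols <- lapply(TM_GROUPS, function(g) {
    sel <- which(pair_groups == g)
    if (!length(sel)) {
      tm_error("tm_validation_error", sprintf("group '%s' has no pairs", g))
    }
    row_medians(unclass(adm)[, sel, drop = FALSE])
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(rownames(adm), TM_GROUPS)
  structure(out, class = c("group_median_matrix", "matrix", "array"))
}

#' Classify probes by group-exclusive variability
#'
#' A probe is variable in a group when that group's median absolute
#' intrapair difference meets the threshold (inclusive `>=`, default 0.1).
#' The exclusivity label partitions probes into `concordant-only`,
#' `discordant-only`, `healthy-only`, `shared` (variable in two or more
#' groups) and `none`.
#'
#' @param gm a [group_medians] matrix.
#' @param threshold minimum median |Δβ| counted as variable; must be in
#'   (0, 1), default 0.1.
#' @return list of class `vmp_classification`:
#'   `classification` — data.frame with per-group indicator columns and the
#'   exclusivity label; `counts` — named counts of the 7 non-empty Venn
#'   regions plus `none`; `threshold`.
#' @export
classify_vmps <- function(gm, threshold = 0.1) {
  if (!(threshold > 0 && threshold < 1)) {
    tm_error("tm_validation_error", "threshold must lie in (0, 1)")
  }
  ind <- unclass(gm) >= threshold
  n_var <- rowSums(ind)
  excl <- rep("none", nrow(ind))
  excl[n_var >= 2L] <- "shared"
  excl[n_var == 1L & ind[, "concordant"]] <- "concordant-only"
  excl[n_var == 1L & ind[, "discordant"]] <- "discordant-only"
  excl[n_var == 1L & ind[, "healthy"]] <- "healthy-only"
  cls <- data.frame(
    probe_id = rownames(ind),
    variable_concordant = ind[, "concordant"],
    variable_discordant = ind[, "discordant"],
    variable_healthy = ind[, "healthy"],
    exclusivity = excl,
    stringsAsFactors = FALSE
  )
  rownames(cls) <- NULL
  counts <- c(
    "concordant-only" = sum(ind[, 1L] & !ind[, 2L] & !ind[, 3L]),
    "discordant-only" = sum(!ind[, 1L] & ind[, 2L] & !ind[, 3L]),
    "healthy-only" = sum(!ind[, 1L] & !ind[, 2L] & ind[, 3L]),
    "concordant+discordant" = sum(ind[, 1L] & ind[, 2L] & !ind[, 3L]),
    "concordant+healthy" = sum(ind[, 1L] & !ind[, 2L] & ind[, 3L]),
    "discordant+healthy" = sum(!ind[, 1L] & ind[, 2L] & ind[, 3L]),
    "all-three" = sum(ind[, 1L] & ind[, 2L] & ind[, 3L]),
    "none" = sum(n_var == 0L)
  )
  structure(list(classification = cls, counts = counts, threshold = threshold),
            class = "vmp_classification")
}

#' Fraction of intrapair differences at or above the threshold
#'
#' The proportion of cells of the absolute intrapair difference matrix that
#' meet the (inclusive) threshold, reported with numerator and denominator.
#'
#' @param adm an [abs_diff_matrix].
#' @param threshold inclusive cutoff, default 0.1.
#' @return list with `fraction`, `numerator`, `denominator`.
#' @export
exceedance_fraction <- function(adm, threshold = 0.1) {
  if (!length(adm)) tm_error("tm_validation_error", "empty difference matrix")
  num <- sum(unclass(adm) >= threshold)
  den <- length(adm)
  list(fraction = num / den, numerator = num, denominator = den)
}

#' Feature-category percentages per exclusive VMP group
#'
#' For each group-exclusive probe set, the percentage of probe-to-category
#' assignments falling in each gene-region feature category. A probe with
#' several distinct categories contributes one count per distinct category
#' (duplicates within a probe collapse); probes without annotation are
#' counted as `unannotated` and logged. Percentages sum to 100 per group.
#'
#' @param vmp a [classify_vmps] result.
#' @param ann a [probe_annotation].
#' @return data.frame with columns `exclusivity`, `feature`, `count`,
#'   `percent`.
#' @export
feature_category_summary <- function(vmp, ann) {
  cls <- vmp$classification
  groups <- c("concordant-only", "discordant-only", "healthy-only")
  out <- list()
  for (g in groups) {
    probes <- cls$probe_id[cls$exclusivity == g]
    if (!length(probes)) next
    idx <- match(probes, ann$probe_id)
    n_unann <- sum(is.na(idx))
    feats <- character(0)
    if (any(!is.na(idx))) {
      lst <- split_multi(ann$feature[idx[!is.na(idx)]])
      empty <- lengths(lst) == 0L
      n_unann <- n_unann + sum(empty)
      feats <- unlist(lst[!empty], use.names = FALSE)
    }
    if (n_unann > 0L) {
      tm_log("%s: %d probe(s) without annotation counted as 'unannotated'",
             g, n_unann)
      feats <- c(feats, rep("unannotated", n_unann))
    }
    tab <- table(feats)
    out[[g]] <- data.frame(
      exclusivity = g,
      feature = names(tab),
      count = as.integer(tab),
      percent = 100 * as.integer(tab) / sum(tab),
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(exclusivity = character(0), feature = character(0),
               count = integer(0), percent = numeric(0))
  }
  rownames(res) <- NULL
  res
}
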