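# Gene-set over-representation analysis (ORA). This module is a transparent,
# reproducible stand-in for GUI/service-based pathway analysis: one-sided
# hypergeometric tail P per gene set against a user-supplied GMT collection,
# Benjamini-Hochberg adjustment across sets. Results carry metadata declaring
# the substitution; specific pathway tables from network tools are not
# claimed reproducible.

#' Map probes to the genes they annotate
#'
#' Union of gene names over the given probes, deduplicated and sorted.
#' Probes without annotation (or with empty gene fields) are dropped with a
#' logged count.
#'
#' @param probes character vector of probe ids.
#' @param ann a [probe_annotation].
#' @return sorted character vector of gene symbols.
#' @export
map_probes_to_genes <- function(probes, ann) {
  if (!length(probes)) return(character(0))
  idx <- match(probes, ann$probe_id)
  n_unann <- sum(is.na(idx))
  genes <- character(0)
  if (any(!is.na(idx))) {
    lst <- split_multi(ann$gene[idx[!is.na(idx)]])
    n_unann <- n_unann + sum(lengths(lst) == 0L)
    genes <- unlist(lst, use.names = FALSE)
  }
  if (n_unann > 0L) tm_log("%d probe(s) without gene annotation dropped", n_unann)
  sort(unique(genes))
}

#' Hypergeometric over-representation of a gene list in gene sets
#'
#' For each set S, with universe size N, set size K = |S ∩ universe| and
#' query size n = |query ∩ universe|, the P-value is the upper tail
#' P(X >= k) for X ~ Hypergeometric(N, K, n) at the observed overlap k.
#' P-values are Benjamini-Hochberg adjusted across all sets and results are
#' sorted by P ascending.
#'
#' Query genes outside the universe are dropped (logged); each set is
#' intersected with the universe before testing.
#'
#' @param query character vector of gene symbols.
#' @param sets a [gene_set_collection].
#' @param universe background gene vector; defaults to the collection's
#'   stored universe.
#' @return data.frame of class `enrichment_result`: `set_name`,
#'   `overlap_count`, `set_size`, `query_size`, `universe_size`, `p_value`,
#'   `fdr`, `overlapping_genes` (semicolon-joined), ordered by `p_value`.
#' @export
hypergeometric_enrichment <- function(query, sets, universe = attr(sets, "universe")) {
  if (is.null(universe) || !length(universe)) {
    tm_error("tm_validation_error", "enrichment requires a non-empty universe")
  }
  universe <- unique(as.character(universe))
  q0 <- unique(as.character(query))
  q <- intersect(q0, universe)
  n_out <- length(q0) - length(q)
  if (n_out > 0L) tm_log("%d query gene(s) outside universe dropped", n_out)
  if (!length(q)) {
    tm_error("tm_validation_error", "query empty after intersecting with universe")
  }
  N <- length(universe)
  n <- length(q)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- intersect(q, s)
    k <- length(ov)
    K <- length(s)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, set_size = K,
               query_size = n, universe_size = N, p_value = p,
               overlapping_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name),
             c("set_name", "overlap_count", "set_size", "query_size",
               "universe_size", "p_value", "fdr", "overlapping_genes")]
  rownames(out) <- NULL
  attr(out, "method") <- "hypergeometric ORA (stand-in for network-based pathway analysis)"
  class(out) <- c("enrichment_result", "data.frame")
  out
}
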