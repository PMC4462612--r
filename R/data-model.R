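# Domain containers: beta matrix, twin design, probe annotation, gene sets.
# All are light S3 wrappers over base containers (matrix / data.frame / list)
# in the style of limma's plain-matrix idiom, with total validation at
# construction time.

TM_GROUPS <- c("concordant", "discordant", "healthy")

# Closed vocabulary of UCSC gene-region feature categories, canonical spelling.
TM_FEATURES <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR",
                 "intergenic")

#' Construct a validated beta-value matrix
#'
#' A beta matrix is a plain numeric matrix of methylation fractions with
#' probes as rows and samples as columns. Values must lie in \[0, 1\];
#' missing values are represented as `NA`.
#'
#' @param values numeric matrix (probes x samples).
#' @param probe_ids,sample_ids optional identifiers; default to existing
#'   dimnames.
#' @return the matrix with class `beta_matrix` prepended.
#' @examples
#' b <- beta_matrix(matrix(0.5, 2, 4,
#'   dimnames = list(c("cg01", "cg02"), paste0("s", 1:4))))
#' @export
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    tm_error("tm_validation_error", "beta matrix values must be a numeric matrix")
  }
  if (is.null(probe_ids) || is.null(sample_ids)) {
    tm_error("tm_validation_error", "beta matrix needs probe and sample identifiers")
  }
  rownames(values) <- as.character(probe_ids)
  colnames(values) <- as.character(sample_ids)
  validate_beta_matrix(values)
  class(values) <- c("beta_matrix", class(values))
  values
}

#' @rdname beta_matrix
#' @param b object to validate.
#' @export
validate_beta_matrix <- function(b) {
  if (anyDuplicated(rownames(b))) {
    dup <- rownames(b)[duplicated(rownames(b))][1L]
    tm_error("tm_validation_error", sprintf("duplicate probe_id '%s'", dup))
  }
  if (anyDuplicated(colnames(b))) {
    dup <- colnames(b)[duplicated(colnames(b))][1L]
    tm_error("tm_validation_error", sprintf("duplicate sample_id '%s'", dup))
  }
  bad <- which(!is.na(b) & (b < 0 | b > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    tm_error("tm_validation_error", sprintf(
      "beta value %g outside [0,1] at probe '%s', sample '%s'",
      b[i, j], rownames(b)[i], colnames(b)[j]))
  }
  invisible(b)
}

#' Construct a validated twin design
#'
#' A twin design assigns each sample to a twin pair, a diagnostic group
#' (`concordant`, `discordant` or `healthy`) and an affected status.
#' Invariants enforced: every pair has exactly two members sharing one group;
#' discordant pairs have exactly one affected member, concordant pairs two,
#' healthy pairs none.
#'
#' @param samples data.frame with columns `sample_id`, `pair_id`, `group`,
#'   `affected`.
#' @return data.frame of class `twin_design`.
#' @export
twin_design <- function(samples) {
  need <- c("sample_id", "pair_id", "group", "affected")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    tm_error("tm_validation_error",
             paste("twin design missing columns:", paste(miss, collapse = ", ")))
  }
  d <- data.frame(
    sample_id = as.character(samples$sample_id),
    pair_id = as.character(samples$pair_id),
    group = as.character(samples$group),
    affected = as.logical(samples$affected),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(d$sample_id)) {
    tm_error("tm_validation_error", "duplicate sample_id in twin design")
  }
  bad_grp <- setdiff(unique(d$group), TM_GROUPS)
  if (length(bad_grp)) {
    tm_error("tm_validation_error",
             sprintf("unknown group label '%s' (expected %s)",
                     bad_grp[1L], paste(TM_GROUPS, collapse = "/")))
  }
  if (anyNA(d$affected)) {
    tm_error("tm_validation_error", "affected flags must be TRUE/FALSE")
  }
  for (pid in unique(d$pair_id)) {
    rows <- d[d$pair_id == pid, ]
    if (nrow(rows) != 2L) {
      tm_error("tm_validation_error",
               sprintf("pair '%s' has %d members (expected 2)", pid, nrow(rows)))
    }
    if (length(unique(rows$group)) != 1L) {
      tm_error("tm_validation_error",
               sprintf("pair '%s' members assigned to different groups", pid))
    }
    n_aff <- sum(rows$affected)
    want <- switch(rows$group[1L], concordant = 2L, discordant = 1L, healthy = 0L)
    if (n_aff != want) {
      tm_error("tm_validation_error", sprintf(
        "pair '%s' (%s) has %d affected members (expected %d)",
        pid, rows$group[1L], n_aff, want))
    }
  }
  class(d) <- c("twin_design", "data.frame")
  d
}

#' Pairs of a twin design
#'
#' One row per pair with group and member sample ids. In discordant pairs
#' `twin1` is the affected co-twin; elsewhere member order follows the sheet
#' (arbitrary-but-fixed; all downstream uses are orientation-invariant via
#' absolute differences).
#'
#' @param design a [twin_design].
#' @return data.frame with columns `pair_id`, `group`, `twin1`, `twin2`.
#' @export
design_pairs <- function(design) {
  pid <- unique(design$pair_id)
  out <- lapply(pid, function(p) {
    rows <- design[design$pair_id == p, ]
    if (rows$group[1L] == "discordant") {
      rows <- rows[order(!rows$affected), ]  # affected first
    }
    data.frame(pair_id = p, group = rows$group[1L],
               twin1 = rows$sample_id[1L], twin2 = rows$sample_id[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Construct a validated probe annotation table
#'
#' @param ann data.frame with columns `probe_id`, `chr`, `pos`, `gene`,
#'   `feature`. `gene` and `feature` may hold semicolon-separated multi-values;
#'   feature tokens are normalised to the canonical UCSC vocabulary
#'   (TSS1500, TSS200, 5'UTR, 1stExon, Body, 3'UTR, intergenic).
#' @return data.frame of class `probe_annotation`.
#' @export
probe_annotation <- function(ann) {
  need <- c("probe_id", "chr", "pos", "gene", "feature")
  miss <- setdiff(need, names(ann))
  if (length(miss)) {
    tm_error("tm_validation_error",
             paste("annotation missing columns:", paste(miss, collapse = ", ")))
  }
  a <- data.frame(
    probe_id = as.character(ann$probe_id),
    chr = as.character(ann$chr),
    pos = suppressWarnings(as.integer(ann$pos)),
    gene = as.character(ann$gene),
    feature = vapply(as.character(ann$feature), normalize_features, character(1L),
                     USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(a$probe_id)) {
    tm_error("tm_validation_error", "duplicate probe_id in annotation")
  }
  has_chr <- !is.na(a$chr) & nzchar(a$chr)
  if (any(has_chr & (is.na(a$pos) | a$pos < 1L))) {
    bad <- a$probe_id[which(has_chr & (is.na(a$pos) | a$pos < 1L))[1L]]
    tm_error("tm_validation_error",
             sprintf("probe '%s': position must be a 1-based coordinate", bad))
  }
  class(a) <- c("probe_annotation", "data.frame")
  a
}

# Normalise a semicolon-separated feature string to canonical deduplicated
# vocabulary ("Body; body" -> "Body"). Empty input stays empty.
normalize_features <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return("")
  toks <- trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
  toks <- toks[nzchar(toks)]
  canon <- vapply(toks, normalize_feature_token, character(1L), USE.NAMES = FALSE)
  paste(unique(canon), collapse = ";")
}

normalize_feature_token <- function(tok) {
  key <- gsub("[^a-z0-9']", "", tolower(gsub("′", "'", tok)))
  canon <- c(
    "tss1500" = "TSS1500", "tss200" = "TSS200",
    "5'utr" = "5'UTR", "5utr" = "5'UTR",
    "1stexon" = "1stExon", "firstexon" = "1stExon", "1exon" = "1stExon",
    "body" = "Body", "genebody" = "Body",
    "3'utr" = "3'UTR", "3utr" = "3'UTR",
    "intergenic" = "intergenic"
  )
  if (!key %in% names(canon)) {
    tm_error("tm_validation_error",
             sprintf("unknown gene-region feature category '%s'", tok))
  }
  unname(canon[key])
}

# Split "A;B" annotation cells into character vectors, dropping empties.
split_multi <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) unique(trimws(v[nzchar(trimws(v))])))
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (unique non-empty names;
#'   members deduplicated).
#' @param universe optional explicit background gene vector.
#' @return list of class `gene_set_collection` with attribute `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    tm_error("tm_validation_error", "gene sets must be named")
  }
  if (anyDuplicated(names(sets))) {
    tm_error("tm_validation_error", "duplicate gene-set names")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) {
    tm_error("tm_validation_error", "empty gene set not allowed")
  }
  structure(sets, universe = if (!is.null(universe)) unique(as.character(universe)),
            class = "gene_set_collection")
}
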