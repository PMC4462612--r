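# Readers and writers for the package's plain-text interchange formats:
# beta matrix (TSV), sample sheet (CSV), probe annotation (CSV), gene sets
# (GMT). data.table does the heavy lifting so a 473k x 34 matrix loads in
# seconds; all validation funnels through the constructors in data-model.R.

#' Read a beta-value matrix from TSV
#'
#' Expects a header row `probe_id<TAB>sample...` and one row per probe.
#' Cells equal to `missing_token` become `NA`; any other non-numeric cell is
#' a parse error naming the offending probe and sample.
#'
#' @param path TSV file path.
#' @param missing_token string encoding missing values (default `"NA"`).
#' @return a [beta_matrix].
#' @export
read_beta_matrix <- function(path, missing_token = "NA") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE,
                          na.strings = NULL, colClasses = "character",
                          showProgress = FALSE)
  if (ncol(dt) < 2L) {
    tm_error("tm_parse_error", sprintf("'%s': expected probe_id plus >=1 sample column", path))
  }
  probe_ids <- dt[[1L]]
  sample_ids <- names(dt)[-1L]
  vals <- matrix(NA_real_, nrow = length(probe_ids), ncol = length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- dt[[j + 1L]]
    is_miss <- col == missing_token
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is_miss & is.na(num))
    if (length(bad)) {
      tm_error("tm_parse_error", sprintf(
        "'%s': non-numeric cell '%s' at probe '%s', sample '%s'",
        path, col[bad[1L]], probe_ids[bad[1L]], sample_ids[j]))
    }
    num[is_miss] <- NA_real_
    vals[, j] <- num
  }
  beta_matrix(vals, probe_ids = probe_ids, sample_ids = sample_ids)
}

#' Write a beta-value matrix to TSV
#'
#' @param b a [beta_matrix].
#' @param path output path.
#' @param missing_token token used for `NA` cells.
#' @export
write_beta_matrix <- function(b, path, missing_token = "NA") {
  dt <- data.table::data.table(probe_id = rownames(b))
  m <- unclass(b)
  for (s in colnames(b)) dt[[s]] <- m[, s]
  data.table::fwrite(dt, path, sep = "\t", na = missing_token, quote = FALSE)
  invisible(path)
}

#' Read a twin-design sample sheet from CSV
#'
#' The sheet must contain exactly the columns `sample_id`, `pair_id`,
#' `group` and `affected`; it is the single source of group and affected
#' labels (beta-matrix columns are joined on `sample_id`, order-free).
#'
#' @param path CSV file path.
#' @return a [twin_design].
#' @export
read_twin_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  twin_design(df)
}

#' @rdname read_twin_design
#' @param design a [twin_design] to write.
#' @export
write_twin_design <- function(design, path) {
  utils::write.csv(as.data.frame(design)[, c("sample_id", "pair_id", "group", "affected")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a probe annotation table from CSV
#'
#' Columns: `probe_id, chr, pos, gene, feature`; `gene` and `feature` may be
#' semicolon-separated multi-values. Feature tokens are normalised to the
#' canonical UCSC vocabulary.
#'
#' @param path CSV file path.
#' @return a [probe_annotation].
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(probe_id = "character", chr = "character",
                                       gene = "character", feature = "character"))
  probe_annotation(df)
}

#' @rdname read_probe_annotation
#' @param ann a [probe_annotation] to write.
#' @export
write_probe_annotation <- function(ann, path) {
  utils::write.csv(as.data.frame(ann), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: per line, set name, description, then tab-separated members.
#' Duplicate members within a set are deduplicated. Lines with fewer than
#' three fields raise a parse error with the line number.
#'
#' @param path GMT file path.
#' @return a [gene_set_collection].
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    tm_log("GMT file '%s' is empty: returning empty collection", path)
    return(structure(list(), universe = NULL, class = "gene_set_collection"))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      tm_error("tm_parse_error",
               sprintf("'%s' line %d: GMT line needs >=3 tab-separated fields", path, i))
    }
    sets[[fields[1L]]] <- unique(fields[-(1:2)])
  }
  gene_set_collection(sets)
}

#' @rdname read_gene_sets
#' @param sets a [gene_set_collection] to write.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
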