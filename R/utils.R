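# Internal helpers: typed conditions, logging, vectorised row statistics.

tm_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "twinmeth_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

tm_log <- function(fmt, ...) {
  if (isTRUE(getOption("twinmeth.verbose", TRUE))) {
    message("[twinmeth] ", sprintf(fmt, ...))
  }
  invisible(NULL)
}

#' Row-wise sort of a numeric matrix
#'
#' Returns a matrix whose rows hold the sorted values of the corresponding
#' input rows. Vectorised (single `order()` call) so it stays fast for
#' hundreds of thousands of probes with a handful of columns.
#'
#' @param m numeric matrix, no NAs.
#' @return matrix of the same dimension, each row ascending.
#' @keywords internal
#' @noRd
row_sort <- function(m) {
  if (ncol(m) == 1L) return(m)
  matrix(m[order(row(m), m)], ncol = ncol(m), byrow = TRUE,
         dimnames = list(rownames(m), NULL))
}

# Row medians without per-row median() calls; even widths average the two
# central order statistics.
row_medians <- function(m) {
  k <- ncol(m)
  if (k == 1L) return(as.vector(m))
  s <- row_sort(m)
  if (k %% 2L == 1L) {
    s[, (k + 1L) %/% 2L]
  } else {
    (s[, k %/% 2L] + s[, k %/% 2L + 1L]) / 2
  }
}

# Clip to [lo, hi].
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)
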