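# Internal index arithmetic. All flattenings in the package use row-major
# (last-axis-fastest) enumeration; this is the single place that defines it.

#' @noRd
rowmajor_rank <- function(idx, dims) {
  # idx: integer vector (1-based) or matrix with one multi-index per row
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1L)
  stopifnot(ncol(idx) == length(dims))
  mult <- rev(cumprod(rev(c(dims[-1L], 1L))))
  as.integer((idx - 1L) %*% mult + 1L)
}

#' @noRd
rowmajor_unrank <- function(r, dims) {
  # inverse of rowmajor_rank; returns a matrix with one multi-index per row
  r0 <- r - 1L
  d <- length(dims)
  out <- matrix(0L, nrow = length(r), ncol = d)
  mult <- rev(cumprod(rev(c(dims[-1L], 1L))))
  for (j in seq_len(d)) {
    out[, j] <- as.integer(r0 %/% mult[j])
    r0 <- r0 %% mult[j]
  }
  out + 1L
}

#' @noRd
rowmajor_grid <- function(dims) {
  # all multi-indices of `dims` in row-major order (last axis fastest)
  rowmajor_unrank(seq_len(prod(dims)), dims)
}

#' @noRd
join_labels <- function(label_matrix, sep = "|") {
  apply(label_matrix, 1L, paste, collapse = sep)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop2 <- function(...) stop(..., call. = FALSE)
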