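#' Construct a data tensor
#'
#' A data tensor is a complete, finite, multi-indexed array of measurements
#' with named axes and unique labels along each axis. Completeness is a hard
#' requirement of the clustering method: every combination of axis labels
#' must carry a value, and no imputation is performed.
#'
#' @param values a numeric array of order `length(axes)`.
#' @param axes a named list; element `i` is the character vector of labels of
#'   axis `i`, with `length(axes[[i]]) == dim(values)[i]`.
#' @return an object of class `data_tensor` with fields `values`, `axes` and
#'   `shape`.
#' @export
data_tensor <- function(values, axes) {
  if (!is.array(values) && length(values) == 1L) values <- array(values, dim = 1L)
  if (!is.numeric(values)) stop2("tensor values must be numeric")
  if (is.null(names(axes)) || any(names(axes) == "")) {
    stop2("every axis must be named")
  }
  shape <- dim(values) %||% length(values)
  if (length(axes) != length(shape)) {
    stop2("number of axes (", length(axes), ") does not match tensor order (",
          length(shape), ")")
  }
  for (i in seq_along(axes)) {
    lab <- as.character(axes[[i]])
    if (length(lab) != shape[i]) {
      stop2("axis '", names(axes)[i], "' has ", length(lab),
            " labels but extent ", shape[i])
    }
    if (anyDuplicated(lab)) {
      stop2("axis '", names(axes)[i], "' has duplicated labels")
    }
    axes[[i]] <- lab
  }
  if (!all(is.finite(values))) {
    stop2("tensor is not complete: non-finite entries present")
  }
  dimnames(values) <- axes
  structure(list(values = values, axes = axes, shape = as.integer(shape)),
            class = "data_tensor")
}

#' @export
dim.data_tensor <- function(x) x$shape

#' @export
print.data_tensor <- function(x, ...) {
  cat("data_tensor of order", length(x$shape), "with shape",
      paste(x$shape, collapse = " x "), "\n")
  cat("axes:", paste(names(x$axes), collapse = ", "), "\n")
  invisible(x)
}

#' Load a data tensor from a long-format table
#'
#' Reads a delimited text file (or a data frame) with one measurement per row
#' and turns it into a complete [data_tensor()]. The table must contain one
#' column per axis plus a numeric value column, and every combination of axis
#' labels must appear exactly once.
#'
#' @param x a file path, a connection, or a data frame.
#' @param axes character vector of axis (column) names, in tensor order.
#' @param value name of the value column.
#' @param sep field separator when reading from a file (default `","`).
#' @return a [data_tensor()] whose axis labels appear in order of first
#'   occurrence in the table.
#' @export
load_long_table <- function(x, axes, value = "value", sep = ",") {
  df <- if (is.data.frame(x)) {
    x
  } else {
    utils::read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE, colClasses = "character")
  }
  missing_cols <- setdiff(c(axes, value), names(df))
  if (length(missing_cols)) {
    stop2("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  vals <- suppressWarnings(as.numeric(df[[value]]))
  bad <- which(!is.finite(vals))
  if (length(bad)) {
    stop2("non-numeric or non-finite value in row ", bad[1L],
          " ('", df[[value]][bad[1L]], "')")
  }
  labels <- lapply(axes, function(a) unique(as.character(df[[a]])))
  names(labels) <- axes
  shape <- vapply(labels, length, 1L)
  n_expected <- prod(shape)
  # row-major rank of each table row in the label space
  idx <- vapply(seq_along(axes), function(i) {
    match(as.character(df[[axes[i]]]), labels[[i]])
  }, integer(nrow(df)))
  if (nrow(df) == 1L) idx <- matrix(idx, nrow = 1L)
  ranks <- rowmajor_rank(idx, shape)
  dup <- anyDuplicated(ranks)
  if (dup) {
    tup <- vapply(seq_along(axes), function(i) as.character(df[[axes[i]]])[dup],
                  character(1L))
    stop2("duplicate combination (", paste(tup, collapse = ", "), ")")
  }
  if (nrow(df) < n_expected) {
    absent <- setdiff(seq_len(n_expected), ranks)[1L]
    tup <- rowmajor_unrank(absent, shape)
    lab <- vapply(seq_along(axes), function(i) labels[[i]][tup[1L, i]],
                  character(1L))
    stop2("incomplete tensor: missing combination (",
          paste(lab, collapse = ", "), ")")
  }
  arr_rowmajor <- numeric(n_expected)
  arr_rowmajor[ranks] <- vals
  # row-major filled vector -> column-major array via reversed dims + aperm
  h <- length(shape)
  arr <- array(arr_rowmajor, dim = rev(shape))
  arr <- aperm(arr, h:1)
  data_tensor(arr, labels)
}

#' Look up a tensor entry by axis labels
#'
#' @param Z a [data_tensor()].
#' @param ... one label per axis, in axis order (or a single character vector).
#' @return the scalar value stored at that label combination.
#' @export
tensor_entry <- function(Z, ...) {
  lab <- c(...)
  if (length(lab) != length(Z$shape)) stop2("need one label per axis")
  idx <- vapply(seq_along(lab), function(i) {
    j <- match(as.character(lab[i]), Z$axes[[i]])
    if (is.na(j)) stop2("unknown label '", lab[i], "' on axis '",
                        names(Z$axes)[i], "'")
    j
  }, 1L)
  unname(Z$values[matrix(idx, nrow = 1L)])
}

#' Flatten a data tensor into an experiments-by-measurements matrix
#'
#' The first `d` axes index the experiments (rows) and the remaining axes are
#' vectorized into the columns. Rows and columns are enumerated in row-major
#' (last-axis-fastest) order, which fixes the correspondence between the
#' similarity matrix and the similarity tensor.
#'
#' @param Z a [data_tensor()].
#' @param d number of leading axes that index experiments, `1 <= d < order`.
#' @return an object of class `flat_matrix` with fields `values` (the
#'   `N1 x N2` matrix), `row_index` / `col_index` (integer multi-index
#'   matrices), `row_labels` / `col_labels`, `dims_row`, `dims_col` and `d`.
#' @export
flatten_tensor <- function(Z, d) {
  h <- length(Z$shape)
  if (!(d >= 1L && d < h)) stop2("d must satisfy 1 <= d < ", h)
  dims_row <- Z$shape[seq_len(d)]
  dims_col <- Z$shape[(d + 1L):h]
  n1 <- prod(dims_row)
  n2 <- prod(dims_col)
  B <- aperm(Z$values, c(rev(seq_len(d)), rev((d + 1L):h)))
  dim(B) <- c(n1, n2)
  row_index <- rowmajor_grid(dims_row)
  col_index <- rowmajor_grid(dims_col)
  row_lab_mat <- vapply(seq_len(d), function(i) Z$axes[[i]][row_index[, i]],
                        character(n1))
  if (n1 == 1L) row_lab_mat <- matrix(row_lab_mat, nrow = 1L)
  col_lab_mat <- vapply(seq_len(h - d), function(i) {
    Z$axes[[d + i]][col_index[, i]]
  }, character(n2))
  if (n2 == 1L) col_lab_mat <- matrix(col_lab_mat, nrow = 1L)
  row_labels <- join_labels(row_lab_mat)
  col_labels <- join_labels(col_lab_mat)
  dimnames(B) <- list(row_labels, col_labels)
  structure(list(values = B, row_index = row_index, col_index = col_index,
                 row_labels = row_labels, col_labels = col_labels,
                 dims_row = as.integer(dims_row),
                 dims_col = as.integer(dims_col), d = as.integer(d),
                 axes_row = names(Z$axes)[seq_len(d)]),
            class = "flat_matrix")
}

#' Normalize the rows of a flattened tensor
#'
#' @param M a `flat_matrix` from [flatten_tensor()].
#' @param method `"unit-l2"` (each row scaled to Euclidean norm 1, the
#'   default), `"max1"` (each row divided by its maximum absolute entry) or
#'   `"none"`.
#' @return a `flat_matrix` with normalized rows.
#' @export
normalize_rows <- function(M, method = c("unit-l2", "max1", "none")) {
  method <- match.arg(method)
  if (method == "none") return(M)
  V <- M$values
  scale <- switch(method,
                  "unit-l2" = sqrt(rowSums(V^2)),
                  "max1"    = apply(abs(V), 1L, max))
  zero <- which(scale == 0)
  if (length(zero)) {
    stop2("all-zero row for experiment (", M$row_labels[zero[1L]],
          "); cannot normalize")
  }
  M$values <- V / scale
  M
}

#' Cosine similarity between the rows of a flattened tensor
#'
#' Entry (r, s) is the cosine of the angle between experiment rows r and s.
#' The result is symmetric with unit diagonal; for non-negative data all
#' entries lie in `[0, 1]`.
#'
#' @param M a `flat_matrix`.
#' @return an object of class `similarity_matrix` with fields `values`
#'   (`N1 x N1`), `index` (integer multi-index matrix of the experiments),
#'   `labels` and `dims` (the experiment grid extents).
#' @export
cosine_similarity <- function(M) {
  V <- M$values
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0)) {
    stop2("all-zero row for experiment (",
          M$row_labels[which(nrm == 0)[1L]], ")")
  }
  U <- V / nrm
  S <- tcrossprod(U)
  S <- (S + t(S)) / 2          # enforce exact symmetry
  diag(S) <- 1
  dimnames(S) <- list(M$row_labels, M$row_labels)
  structure(list(values = S, index = M$row_index, labels = M$row_labels,
                 dims = M$dims_row),
            class = "similarity_matrix")
}

#' Reverse-flatten a similarity matrix into a similarity tensor
#'
#' @param S_mat a `similarity_matrix` (or a plain symmetric matrix).
#' @param dims experiment grid extents `(n_1, ..., n_d)` with
#'   `prod(dims) == nrow`.
#' @return an object of class `similarity_tensor`: field `values` is an array
#'   of shape `(dims, dims)` with
#'   `values[i, j] == S_mat[rank(i), rank(j)]` under row-major ranking.
#' @export
unflatten_similarity <- function(S_mat, dims = NULL) {
  if (inherits(S_mat, "similarity_matrix")) {
    dims <- dims %||% S_mat$dims
    V <- S_mat$values
  } else {
    V <- S_mat
  }
  if (is.null(dims)) stop2("dims must be supplied")
  dims <- as.integer(dims)
  n1 <- prod(dims)
  if (nrow(V) != n1 || ncol(V) != n1) {
    stop2("matrix is ", nrow(V), " x ", ncol(V),
          " but prod(dims) = ", n1)
  }
  d <- length(dims)
  A <- V
  dim(A) <- c(rev(dims), rev(dims))
  perm <- c(rev(seq_len(d)), rev(d + seq_len(d)))  # self-inverse
  S <- aperm(A, perm)
  structure(list(values = S, dims = dims), class = "similarity_tensor")
}

#' Flatten a similarity tensor back into a similarity matrix
#'
#' Inverse of [unflatten_similarity()]; the round trip is the identity.
#'
#' @param S a `similarity_tensor`.
#' @return a plain `N1 x N1` numeric matrix.
#' @export
flatten_similarity <- function(S) {
  dims <- S$dims
  d <- length(dims)
  perm <- c(rev(seq_len(d)), rev(d + seq_len(d)))
  B <- aperm(S$values, perm)
  dim(B) <- c(prod(dims), prod(dims))
  B
}

#' Within-group heterogeneity score
#'
#' Summarizes the within-group variation of a set of experiments as the mean,
#' over unordered distinct pairs in the subset, of one minus their cosine
#' similarity. The score is 0 when all pairwise similarities are 1 (complete
#' homogeneity) and 1 when they are all 0 (complete heterogeneity).
#' Self-pairs are excluded: self-similarity is identically 1 and would only
#' dilute the statistic.
#'
#' @param S_mat a `similarity_matrix` built from non-negative data.
#' @param subset integer indices (or labels) of at least two experiments.
#' @return a scalar in `[0, 1]`.
#' @export
heterogeneity_score <- function(S_mat, subset) {
  V <- if (inherits(S_mat, "similarity_matrix")) S_mat$values else S_mat
  if (is.character(subset)) subset <- match(subset, rownames(V))
  if (anyNA(subset)) stop2("unknown experiment label in subset")
  if (length(subset) < 2L) {
    stop2("subset must contain at least two experiments")
  }
  sub <- V[subset, subset, drop = FALSE]
  if (any(sub < 0)) {
    stop2("negative similarities present; the heterogeneity score is ",
          "defined for non-negative data (normalize non-negative ",
          "measurements first)")
  }
  pairs <- sub[upper.tri(sub)]
  mean(1 - pairs)
}

#' Write a similarity matrix to CSV
#'
#' Multi-index labels are joined by `"|"` and used as row and column headers.
#'
#' @param S_mat a `similarity_matrix`.
#' @param path output file path.
#' @export
write_similarity_csv <- function(S_mat, path) {
  utils::write.csv(as.data.frame(S_mat$values), path, row.names = TRUE)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity_csv()]
#'
#' @param path CSV path.
#' @param dims experiment grid extents `(n_1, ..., n_d)`.
#' @return a `similarity_matrix`.
#' @export
read_similarity_csv <- function(path, dims) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  V <- as.matrix(df)
  dims <- as.integer(dims)
  if (nrow(V) != prod(dims)) {
    stop2("similarity matrix has ", nrow(V), " rows, expected ", prod(dims))
  }
  structure(list(values = V, index = rowmajor_grid(dims),
                 labels = rownames(V), dims = dims),
            class = "similarity_matrix")
}
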