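#' Construct a rectangular partition of an experiment grid
#'
#' A rectangular partition splits an `n1 x n2` grid (for example cell lines
#' by ligands) into clusters each of which is a full Cartesian product of a
#' row subset and a column subset. Rows and columns need not be contiguous:
#' no ordering of the grid is assumed. Clusters are stored in canonical
#' order (by their lexicographically smallest member cell, row-major) so
#' that decoded partitions are deterministic and comparable.
#'
#' @param grid_shape integer pair `(n1, n2)`.
#' @param clusters list of clusters, each a list with integer fields `rows`
#'   and `cols`.
#' @param row_labels,col_labels optional label vectors for the grid axes.
#' @return an object of class `rect_partition`.
#' @export
rect_partition <- function(grid_shape, clusters,
                           row_labels = NULL, col_labels = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1L))
  clusters <- lapply(clusters, function(cl) {
    list(rows = sort(unique(as.integer(cl$rows))),
         cols = sort(unique(as.integer(cl$cols))))
  })
  clusters <- Filter(function(cl) length(cl$rows) && length(cl$cols), clusters)
  P <- structure(list(grid_shape = grid_shape, clusters = clusters,
                      row_labels = row_labels %||% paste0("r", seq_len(grid_shape[1L])),
                      col_labels = col_labels %||% paste0("c", seq_len(grid_shape[2L]))),
                 class = "rect_partition")
  rep_ <- validate_partition(P)
  if (!rep_$valid) {
    stop2("invalid rectangular partition: ",
          paste(rep_$violations, collapse = "; "))
  }
  canonicalize_partition(P)
}

#' @export
print.rect_partition <- function(x, ...) {
  cat("rect_partition on a", x$grid_shape[1L], "x", x$grid_shape[2L],
      "grid with", length(x$clusters), "cluster(s)\n")
  for (k in seq_along(x$clusters)) {
    cl <- x$clusters[[k]]
    cat(sprintf("  [%d] rows {%s} x cols {%s}\n", k,
                paste(cl$rows, collapse = ","),
                paste(cl$cols, collapse = ",")))
  }
  invisible(x)
}

#' @noRd
canonicalize_partition <- function(P) {
  if (!length(P$clusters)) return(P)
  n2 <- P$grid_shape[2L]
  first_cell <- vapply(P$clusters, function(cl) {
    (min(cl$rows) - 1L) * n2 + min(cl$cols)
  }, 1L)
  P$clusters <- P$clusters[order(first_cell)]
  P
}

#' Cluster membership of every grid cell
#'
#' @param P a `rect_partition`.
#' @return an `n1 x n2` integer matrix of cluster ids (canonical order).
#' @export
partition_membership <- function(P) {
  M <- matrix(NA_integer_, P$grid_shape[1L], P$grid_shape[2L])
  for (k in seq_along(P$clusters)) {
    cl <- P$clusters[[k]]
    M[cl$rows, cl$cols] <- k
  }
  M
}

#' Validate a rectangular partition
#'
#' Produces a report rather than an error, listing every violated invariant:
#' cluster overlap, coverage gaps, or (when built from a membership matrix)
#' classes that are not full Cartesian products.
#'
#' @param P a `rect_partition` (possibly not yet validated).
#' @return a list with fields `valid` (logical) and `violations` (character).
#' @export
validate_partition <- function(P) {
  n1 <- P$grid_shape[1L]; n2 <- P$grid_shape[2L]
  cover <- matrix(0L, n1, n2)
  viol <- character(0)
  for (k in seq_along(P$clusters)) {
    cl <- P$clusters[[k]]
    if (!length(cl$rows) || !length(cl$cols)) {
      viol <- c(viol, sprintf("cluster %d is empty", k)); next
    }
    if (any(cl$rows < 1L | cl$rows > n1) || any(cl$cols < 1L | cl$cols > n2)) {
      viol <- c(viol, sprintf("cluster %d indexes outside the grid", k)); next
    }
    cover[cl$rows, cl$cols] <- cover[cl$rows, cl$cols] + 1L
  }
  if (any(cover > 1L)) {
    w <- which(cover > 1L, arr.ind = TRUE)[1L, ]
    viol <- c(viol, sprintf("overlap at cell (%d,%d)", w[1L], w[2L]))
  }
  if (any(cover == 0L)) {
    w <- which(cover == 0L, arr.ind = TRUE)[1L, ]
    viol <- c(viol, sprintf("coverage gap at cell (%d,%d)", w[1L], w[2L]))
  }
  list(valid = !length(viol), violations = viol)
}

#' Membership matrix to partition, enforcing rectangularity
#'
#' @param M an `n1 x n2` matrix of cluster ids.
#' @return a `rect_partition`; errors if some class is not a full Cartesian
#'   product of its row and column sets.
#' @export
membership_to_partition <- function(M) {
  ids <- sort(unique(as.vector(M)))
  clusters <- lapply(ids, function(id) {
    w <- which(M == id, arr.ind = TRUE)
    rows <- sort(unique(w[, 1L])); cols <- sort(unique(w[, 2L]))
    if (nrow(w) != length(rows) * length(cols)) {
      stop2("class ", id, " is not rectangular: its cells {",
            paste(sprintf("(%d,%d)", w[, 1L], w[, 2L]), collapse = ","),
            "} differ from rows {", paste(rows, collapse = ","),
            "} x cols {", paste(cols, collapse = ","), "}")
    }
    list(rows = rows, cols = cols)
  })
  rect_partition(dim(M), clusters)
}

#' Encode a partition as a Boolean pairwise-distance tensor
#'
#' The entry at multi-indices `(i1,i2,j1,j2)` is 0 when cells `(i1,i2)` and
#' `(j1,j2)` share a cluster and 1 otherwise. The result satisfies the
#' reflexivity/symmetry/transitivity inequalities of an equivalence relation
#' and the three rectangularity constraint families.
#'
#' @param P a `rect_partition`.
#' @return a Boolean (0/1) array of shape `(n1, n2, n1, n2)`.
#' @export
partition_to_x <- function(P) {
  M <- partition_membership(P)
  n1 <- nrow(M); n2 <- ncol(M)
  v <- as.vector(M)                       # column-major cell order
  same <- outer(v, v, "==")
  x <- 1 - same
  dim(x) <- c(n1, n2, n1, n2)
  x
}

#' Decode a Boolean pairwise-distance tensor into a partition
#'
#' Verifies the equivalence-relation conditions (reflexivity, symmetry,
#' transitivity) and then extracts the equivalence classes of
#' `i ~ j  <=>  x[i,j] == 0`; each class must be a full Cartesian product of
#' its rows and columns, otherwise the rectangularity constraints are
#' breached and an error is raised.
#'
#' @param x a 0/1 array of shape `(n1, n2, n1, n2)`.
#' @return a `rect_partition`.
#' @export
x_to_partition <- function(x) {
  dm <- dim(x)
  if (length(dm) != 4L || dm[1L] != dm[3L] || dm[2L] != dm[4L]) {
    stop2("x must have shape (n1, n2, n1, n2)")
  }
  n1 <- dm[1L]; n2 <- dm[2L]; n <- n1 * n2
  Xf <- x
  dim(Xf) <- c(n, n)                      # column-major cell order
  if (any(diag(Xf) != 0)) stop2("reflexivity violated: x[i,i] != 0")
  if (any(Xf != t(Xf))) stop2("symmetry violated: x[i,j] != x[j,i]")
  same <- Xf == 0
  # transitivity: the 'same cluster' relation must be transitive
  closure <- (same %*% same) > 0
  bad <- which(closure & !same, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    k <- which(same[i, ] & same[, j])[1L]
    stop2("transitivity violated for triple (", i, ", ", k, ", ", j,
          ") in column-major cell order")
  }
  comp <- integer(n); cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[same[i, ]] <- cid
    }
  }
  M <- matrix(comp, n1, n2)
  membership_to_partition(M)
}

#' Encode a partition as a one-hot assignment tensor
#'
#' @param P a `rect_partition`.
#' @param m number of cluster slices, at least the number of clusters in `P`
#'   (extra slices are left all-zero).
#' @return a 0/1 array `y` of shape `(n1, n2, m)` with
#'   `sum_k y[i1,i2,k] == 1` for every cell; satisfies
#'   `1 - x[i, j] == sum_k y[i, k] * y[j, k]` with `x = partition_to_x(P)`.
#' @export
partition_to_y <- function(P, m = length(P$clusters)) {
  nc <- length(P$clusters)
  if (m < nc) stop2("m = ", m, " is smaller than the cluster count ", nc)
  n1 <- P$grid_shape[1L]; n2 <- P$grid_shape[2L]
  y <- array(0, dim = c(n1, n2, m))
  for (k in seq_len(nc)) {
    cl <- P$clusters[[k]]
    y[cl$rows, cl$cols, k] <- 1
  }
  y
}

#' Decode an assignment tensor into a rectangular partition
#'
#' Non-empty slices become clusters; every non-empty slice must be the 0/1
#' outer product of a row and a column indicator. All-zero slices are
#' dropped.
#'
#' @param y a 0/1 array of shape `(n1, n2, m)` with unit cell sums.
#' @return a `rect_partition`.
#' @export
y_to_partition <- function(y) {
  dm <- dim(y)
  if (length(dm) != 3L) stop2("y must have shape (n1, n2, m)")
  cellsum <- apply(y, c(1L, 2L), sum)
  if (any(cellsum != 1)) {
    w <- which(cellsum != 1, arr.ind = TRUE)[1L, ]
    stop2("unique-assignment violated at cell (", w[1L], ",", w[2L], ")")
  }
  clusters <- list()
  for (k in seq_len(dm[3L])) {
    sl <- y[, , k, drop = FALSE]; dim(sl) <- dm[1:2]
    if (!any(sl != 0)) next
    rows <- which(rowSums(sl) > 0); cols <- which(colSums(sl) > 0)
    if (!all(sl[rows, cols] == 1)) {
      stop2("slice ", k, " is not an outer-product (rectangular) pattern")
    }
    clusters[[length(clusters) + 1L]] <- list(rows = rows, cols = cols)
  }
  rect_partition(dm[1:2], clusters)
}

#' Enumerate every rectangular partition of a small grid
#'
#' Exhaustive oracle used to certify optimality of the integer programs on
#' small instances. Cells are assigned in row-major order by a recursive
#' search that prunes assignments already incompatible with the
#' Cartesian-product requirement; each completed assignment is validated.
#'
#' @param n1,n2 grid extents with `n1 * n2 <= 12`.
#' @return a list of `rect_partition` objects in canonical enumeration order
#'   (restricted-growth order of the membership strings), without duplicates.
#' @export
enumerate_rectangular_partitions <- function(n1, n2) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 * n2 > 12L) {
    stop2("grid has ", n1 * n2, " cells; the exhaustive oracle is limited ",
          "to 12 to guard against combinatorial explosion")
  }
  key <- paste0(n1, "x", n2)
  cached <- .partition_cache[[key]]
  if (!is.null(cached)) return(cached)
  cells <- rowmajor_grid(c(n1, n2))
  n <- nrow(cells)
  out <- list()
  assign_cell <- function(t, memb, k_used) {
    if (t > n) {
      M <- matrix(NA_integer_, n1, n2)
      M[cells] <- memb
      P <- try(membership_to_partition(M), silent = TRUE)
      if (!inherits(P, "try-error")) out[[length(out) + 1L]] <<- P
      return(invisible(NULL))
    }
    i <- cells[t, 1L]; j <- cells[t, 2L]
    for (k in seq_len(min(k_used + 1L, n))) {
      if (rect_feasible(cells, memb, t, k)) {
        memb[t] <- k
        assign_cell(t + 1L, memb, max(k_used, k))
      }
    }
  }
  assign_cell(1L, integer(n), 0L)
  .partition_cache[[key]] <- out
  out
}

# Incremental Cartesian-product feasibility of assigning cell t (row-major
# order) to cluster k, given assignments memb[1:(t-1)].
#' @noRd
rect_feasible <- function(cells, memb, t, k) {
  i <- cells[t, 1L]; j <- cells[t, 2L]
  prev <- seq_len(t - 1L)
  if (!length(prev)) return(TRUE)
  pm <- memb[prev]
  pi_ <- cells[prev, 1L]; pj <- cells[prev, 2L]
  ink <- pm == k
  # cells sharing cluster k's rows/columns with the new cell must be in k
  if (any(ink)) {
    krows <- unique(pi_[ink]); kcols <- unique(pj[ink])
    if (any(pj == j & pi_ %in% krows & !ink)) return(FALSE)
    if (any(pi_ == i & pj %in% kcols & !ink)) return(FALSE)
    # and the new cell must not create a hole: previously assigned cells at
    # (rows of k) x (cols of k) are already consistent by induction
  }
  # the new cell must not sit inside the span of a different cluster
  for (kk in unique(pm)) {
    if (kk == k) next
    sel <- pm == kk
    if (i %in% pi_[sel] && j %in% pj[sel]) return(FALSE)
  }
  TRUE
}

.partition_cache <- new.env(parent = emptyenv())

#' Naive enumeration of rectangular partitions (test-only cross-check)
#'
#' Generates every set partition of the grid cells (restricted growth
#' strings) and keeps those whose classes are Cartesian products. Slower
#' than [enumerate_rectangular_partitions()]; retained as an independent
#' correctness check.
#'
#' @param n1,n2 grid extents with `n1 * n2 <= 9`.
#' @return a list of `rect_partition` objects.
#' @export
enumerate_rectangular_partitions_naive <- function(n1, n2) {
  n <- n1 * n2
  if (n > 9L) stop2("naive enumeration limited to 9 cells")
  cells <- rowmajor_grid(c(n1, n2))
  out <- list()
  rgs <- function(t, memb, k_used) {
    if (t > n) {
      M <- matrix(NA_integer_, n1, n2)
      M[cells] <- memb
      P <- try(membership_to_partition(M), silent = TRUE)
      if (!inherits(P, "try-error")) out[[length(out) + 1L]] <<- P
      return(invisible(NULL))
    }
    for (k in seq_len(k_used + 1L)) {
      memb[t] <- k
      rgs(t + 1L, memb, max(k_used, k))
    }
  }
  rgs(1L, integer(n), 0L)
  out
}

#' Rand index between two partitions of the same grid
#'
#' Fraction of unordered cell pairs on which the two partitions agree
#' (both together or both apart); 1 means identical partitions.
#'
#' @param P1,P2 `rect_partition` objects on the same grid.
#' @return a scalar in `[0, 1]`.
#' @export
rand_index <- function(P1, P2) {
  stopifnot(all(P1$grid_shape == P2$grid_shape))
  a <- as.vector(partition_membership(P1))
  b <- as.vector(partition_membership(P2))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

#' Export a partition to JSON
#'
#' Clusters are written as `{cluster_id: {rows: [...], cols: [...]}}` using
#' axis labels.
#'
#' @param P a `rect_partition`.
#' @param path output path.
#' @export
write_partition_json <- function(P, path) {
  obj <- stats::setNames(lapply(P$clusters, function(cl) {
    list(rows = P$row_labels[cl$rows], cols = P$col_labels[cl$cols])
  }), paste0("cluster_", seq_along(P$clusters)))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Partition I/O as a long CSV
#'
#' Columns `row_label`, `col_label`, `cluster_id`, one row per grid cell.
#' This is also the schema accepted for externally produced seed
#' clusterings (which need not be rectangular; use [read_assignment_csv()]
#' for those).
#'
#' @param P a `rect_partition`.
#' @param path output path.
#' @export
write_partition_csv <- function(P, path) {
  M <- partition_membership(P)
  g <- rowmajor_grid(P$grid_shape)
  df <- data.frame(row_label = P$row_labels[g[, 1L]],
                   col_label = P$col_labels[g[, 2L]],
                   cluster_id = M[g])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a rectangular partition from CSV
#'
#' @param path CSV with columns `row_label`, `col_label`, `cluster_id`.
#' @return a `rect_partition`.
#' @export
read_partition_csv <- function(path) {
  y <- read_assignment_csv(path)
  P <- y_to_partition(y$y)
  P$row_labels <- y$row_labels
  P$col_labels <- y$col_labels
  P
}

#' Read a (possibly non-rectangular) hard clustering from CSV
#'
#' @param path CSV with columns `row_label`, `col_label`, `cluster_id`.
#' @return a list with the 0/1 assignment array `y` of shape `(n1, n2, m)`
#'   and the grid labels.
#' @export
read_assignment_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("row_label", "col_label", "cluster_id")
  if (!all(need %in% names(df))) {
    stop2("partition CSV needs columns ", paste(need, collapse = ", "))
  }
  rl <- unique(as.character(df$row_label))
  cl <- unique(as.character(df$col_label))
  ids <- sort(unique(df$cluster_id))
  y <- array(0, dim = c(length(rl), length(cl), length(ids)))
  i <- match(as.character(df$row_label), rl)
  j <- match(as.character(df$col_label), cl)
  k <- match(df$cluster_id, ids)
  y[cbind(i, j, k)] <- 1
  list(y = y, row_labels = rl, col_labels = cl, cluster_ids = ids)
}
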