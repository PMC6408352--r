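# Exact integer programming for rectangular clustering.
#
# Two programs are supported:
#   * direct:  maximize <S, 1-X> + lambda * <1, X> over Boolean pairwise
#     "different cluster" tensors X constrained to encode an equivalence
#     relation (reflexivity / symmetry / transitivity) whose classes are
#     rectangles (three rectangularity constraint families);
#   * refine:  maximize <W, Y> over one-hot assignment tensors Y whose
#     slices are rectangular patterns, i.e. the nearest rectangular
#     clustering to a seed clustering W, in the metric of unchanged
#     assignments.
#
# The solver is an exact 0/1 branch-and-bound with a certified optimum
# (gap 0). Constraints are handled in two interchangeable modes: the
# default "structural" mode never materializes constraint rows (the row
# families are enforced combinatorially during the search, playing the role
# of lazily generated rows), while "matrix" mode materializes the
# deduplicated row system and solves generically over the Boolean
# variables. Both modes return the same certified optimum; matrix mode is
# restricted to small grids.

#' Build the direct clustering integer program
#'
#' One Boolean variable is created per unordered pair of distinct grid
#' cells; reflexivity and symmetry are eliminated structurally. The
#' objective in these variables equals
#' `<S, 1-X> + lambda * <1, X>` up to no constant (the diagonal
#' self-similarity terms are included in the reported offset).
#'
#' @param S a `similarity_tensor` over a 2-axis experiment grid (order 4),
#'   or a plain array of shape `(n1, n2, n1, n2)`.
#' @param lambda non-negative regularizer weighting the number of
#'   between-cluster pairs; larger values yield more clusters.
#' @return an object of class `integer_program` (kind `"direct"`).
#' @export
build_direct_program <- function(S, lambda = 0.5) {
  if (is.array(S) && !inherits(S, "similarity_tensor")) {
    dm <- dim(S)
    if (length(dm) != 4L) stop2("S must be an order-4 similarity tensor")
    S <- structure(list(values = S, dims = dm[1:2]), class = "similarity_tensor")
  }
  if (length(S$dims) != 2L) {
    stop2("the clustering programs operate on a 2-axis experiment grid")
  }
  if (lambda < 0) stop2("lambda must be non-negative")
  Sf <- flatten_similarity(S)            # row-major cell order
  if (max(abs(Sf - t(Sf))) > 1e-9) {
    stop2("similarity tensor is not symmetric in its multi-index pairs")
  }
  Sf <- (Sf + t(Sf)) / 2
  n1 <- S$dims[1L]; n2 <- S$dims[2L]; n <- n1 * n2
  structure(list(kind = "direct", grid_shape = c(n1, n2), n_cells = n,
                 S = Sf, lambda = lambda,
                 n_vars = n * (n - 1L) / 2L,
                 offset = sum(diag(Sf))),
            class = "integer_program")
}

#' Build the refinement integer program from a seed clustering
#'
#' @param W a 0/1 array of shape `(n1, n2, m)`: the seed (possibly
#'   non-rectangular) hard clustering, one slice per cluster, every cell
#'   assigned to exactly one slice. `m` is taken from `W`.
#' @return an object of class `integer_program` (kind `"refine"`) whose
#'   objective counts the assignments left unchanged.
#' @export
build_refine_program <- function(W) {
  dm <- dim(W)
  if (length(dm) != 3L) stop2("W must have shape (n1, n2, m)")
  cellsum <- apply(W, c(1L, 2L), sum)
  if (any(cellsum != 1)) {
    w <- which(cellsum != 1, arr.ind = TRUE)[1L, ]
    stop2("W is not a hard assignment: cell (", w[1L], ",", w[2L],
          ") has slice sum ", cellsum[w[1L], w[2L]])
  }
  structure(list(kind = "refine", grid_shape = dm[1:2], n_cells = prod(dm[1:2]),
                 m = dm[3L], W = W, n_vars = prod(dm)),
            class = "integer_program")
}

#' @export
print.integer_program <- function(x, ...) {
  cat("integer_program (", x$kind, ") on a ", x$grid_shape[1L], " x ",
      x$grid_shape[2L], " grid: ", x$n_vars, " Boolean variables, ",
      ip_row_count(x, "built"), " constraint rows as built (",
      format(ip_row_count(x, "paper"), big.mark = ","),
      " as literally written)\n", sep = "")
  invisible(x)
}

#' Constraint-system row counts
#'
#' Closed-form row counts of the constraint matrix, computed without
#' materialization. Two conventions are reported. `"paper"` counts every
#' family over ordered index tuples as literally written: with `n = n1*n2`
#' cells, reflexivity contributes `n` rows, symmetry `n(n-1)`, transitivity
#' `n(n-1)(n-2)`, the rectangularity swap equalities `n^2` and the two
#' rectangularity inequality families `n^2` each (direct program); the
#' refinement program has `n` unique-assignment rows plus
#' `n1^2 * n2^2 * m` interpretability rows. `"built"` counts the
#' deduplicated rows actually materialized in matrix mode: transitivity
#' `3 * choose(n, 3)`, swap equalities `n1*n2*(n1-1)*(n2-1)/4`, inequality
#' families `2 * n1*(n1-1)*n2*(n2-1)`; refinement
#' `n + n1*(n1-1)*n2*(n2-1)*m`.
#'
#' @param program an `integer_program`.
#' @param convention `"paper"` or `"built"`.
#' @return total row count (double, to avoid integer overflow).
#' @export
ip_row_count <- function(program, convention = c("paper", "built")) {
  convention <- match.arg(convention)
  n1 <- as.double(program$grid_shape[1L]); n2 <- as.double(program$grid_shape[2L])
  n <- n1 * n2
  if (program$kind == "direct") {
    if (convention == "paper") {
      n + n * (n - 1) + n * (n - 1) * (n - 2) + n^2 + 2 * n^2
    } else {
      3 * choose(n, 3) + n1 * n2 * (n1 - 1) * (n2 - 1) / 4 +
        2 * n1 * (n1 - 1) * n2 * (n2 - 1)
    }
  } else {
    m <- as.double(program$m)
    if (convention == "paper") {
      n + n1^2 * n2^2 * m
    } else {
      n + n1 * (n1 - 1) * n2 * (n2 - 1) * m
    }
  }
}

# ---------------------------------------------------------------------------
# Row materialization (matrix mode, LP export). Variables:
#   direct: x[p,q] for unordered cell pairs p < q in row-major cell rank;
#   refine: y[i,j,r] in cell-major (row-major cells) then slice order.
# Rows are triplet lists (var ids, coefficients) with two-sided bounds.

#' @noRd
pair_id <- function(p, q, n) {
  # unordered pair (p<q) -> variable index, row-major pair enumeration
  lo <- pmin(p, q); hi <- pmax(p, q)
  as.integer((lo - 1L) * n - lo * (lo - 1L) / 2 + (hi - lo))
}

#' Materialize the constraint rows of an integer program
#'
#' Builds the deduplicated constraint system (the sparse matrix `V` with
#' bounds `b_l`, `b_u`) explicitly. Intended for small grids: matrix mode
#' solving, LP export and cross-checking the closed-form row counts.
#'
#' @param program an `integer_program`.
#' @param max_cells guard on grid size (default 30 cells).
#' @return a list with `vars` (variable names), `rows` (list of named
#'   coefficient vectors, names = variable indices), `lower`, `upper`,
#'   `obj` (objective coefficients) and `offset`.
#' @export
ip_constraints <- function(program, max_cells = 30L) {
  if (program$n_cells > max_cells) {
    stop2("refusing to materialize rows for ", program$n_cells,
          " cells (> ", max_cells, "); use the structural solver mode")
  }
  n1 <- program$grid_shape[1L]; n2 <- program$grid_shape[2L]
  n <- n1 * n2
  cells <- rowmajor_grid(c(n1, n2))
  rk <- function(i, j) (i - 1L) * n2 + j    # row-major cell rank
  rows <- list(); lower <- numeric(0); upper <- numeric(0)
  add_row <- function(ids, coefs, lo, up) {
    r <- stats::setNames(coefs, ids)
    rows[[length(rows) + 1L]] <<- r
    lower[length(rows)] <<- lo
    upper[length(rows)] <<- up
  }
  if (program$kind == "direct") {
    vars <- character(program$n_vars)
    for (p in seq_len(n - 1L)) for (q in (p + 1L):n) {
      vars[pair_id(p, q, n)] <- sprintf("x_%s_%s",
        paste(cells[p, ], collapse = "."), paste(cells[q, ], collapse = "."))
    }
    # transitivity, three orientations per unordered triple
    if (n >= 3L) {
      trip <- utils::combn(n, 3L)
      for (t in seq_len(ncol(trip))) {
        p <- trip[1L, t]; q <- trip[2L, t]; r <- trip[3L, t]
        pq <- pair_id(p, q, n); qr <- pair_id(q, r, n); pr <- pair_id(p, r, n)
        add_row(c(pq, qr, pr), c(1, 1, -1), 0, 2)
        add_row(c(pq, pr, qr), c(1, 1, -1), 0, 2)
        add_row(c(pr, qr, pq), c(1, 1, -1), 0, 2)
      }
    }
    # rectangularity swap equalities: x[(i1,i2),(j1,j2)] == x[(i1,j2),(j1,i2)]
    for (p in seq_len(n - 1L)) for (q in (p + 1L):n) {
      a <- cells[p, ]; b <- cells[q, ]
      if (a[1L] == b[1L] || a[2L] == b[2L]) next
      ps <- rk(a[1L], b[2L]); qs <- rk(b[1L], a[2L])
      v1 <- pair_id(p, q, n); v2 <- pair_id(ps, qs, n)
      if (v1 < v2) add_row(c(v1, v2), c(1, -1), 0, 0)
    }
    # rectangularity inequalities: 0 <= x[i,(j1,j2)] - x[i,(j1,i2)] <= 1
    # and 0 <= x[i,(j1,j2)] - x[i,(i1,j2)] <= 1, over i1 != j1, i2 != j2
    for (p in seq_len(n)) for (q in seq_len(n)) {
      a <- cells[p, ]; b <- cells[q, ]
      if (a[1L] == b[1L] || a[2L] == b[2L]) next
      v_ab <- pair_id(p, q, n)
      add_row(c(v_ab, pair_id(p, rk(b[1L], a[2L]), n)), c(1, -1), 0, 1)
      add_row(c(v_ab, pair_id(p, rk(a[1L], b[2L]), n)), c(1, -1), 0, 1)
    }
    obj <- numeric(program$n_vars)
    for (p in seq_len(n - 1L)) for (q in (p + 1L):n) {
      obj[pair_id(p, q, n)] <- 2 * (program$lambda - program$S[p, q])
    }
    list(vars = vars, rows = rows, lower = lower, upper = upper,
         obj = obj, offset = sum(program$S))
  } else {
    m <- program$m
    yid <- function(cell, r) (r - 1L) * n + cell
    vars <- character(program$n_vars)
    for (r in seq_len(m)) for (cell in seq_len(n)) {
      vars[yid(cell, r)] <- sprintf("y_%s_%d",
        paste(cells[cell, ], collapse = "."), r)
    }
    for (cell in seq_len(n)) {
      add_row(vapply(seq_len(m), yid, 1L, cell = cell), rep(1, m), 1, 1)
    }
    # -1 <= y[i,k,r] + y[j,l,r] - y[i,l,r] <= 1 over i != j, k != l
    for (r in seq_len(m)) {
      for (i in seq_len(n1)) for (j in seq_len(n1)) {
        if (i == j) next
        for (k in seq_len(n2)) for (l in seq_len(n2)) {
          if (k == l) next
          add_row(c(yid(rk(i, k), r), yid(rk(j, l), r), yid(rk(i, l), r)),
                  c(1, 1, -1), -1, 1)
        }
      }
    }
    obj <- numeric(program$n_vars)
    Wf <- program$W
    for (r in seq_len(m)) {
      slice <- Wf[, , r]
      obj[yid(seq_len(n), r)] <- slice[cells]
    }
    list(vars = vars, rows = rows, lower = lower, upper = upper,
         obj = obj, offset = 0)
  }
}

#' Export an integer program as an LP-format file
#'
#' Writes the materialized program in CPLEX LP text format for inspection
#' by standard MILP tooling. Small grids only.
#'
#' @param program an `integer_program`.
#' @param path output path.
#' @export
write_lp <- function(program, path) {
  cs <- ip_constraints(program)
  term <- function(coef, var) {
    sprintf("%s %g %s", if (coef >= 0) "+" else "-", abs(coef), var)
  }
  obj_terms <- paste(mapply(term, cs$obj[cs$obj != 0],
                            cs$vars[cs$obj != 0]), collapse = " ")
  lines <- c("Maximize", paste(" obj:", obj_terms), "Subject To")
  for (r in seq_along(cs$rows)) {
    row <- cs$rows[[r]]
    expr <- paste(mapply(term, row, cs$vars[as.integer(names(row))]),
                  collapse = " ")
    if (cs$lower[r] == cs$upper[r]) {
      lines <- c(lines, sprintf(" c%d: %s = %g", r, expr, cs$lower[r]))
    } else {
      lines <- c(lines, sprintf(" c%da: %s >= %g", r, expr, cs$lower[r]),
                 sprintf(" c%db: %s <= %g", r, expr, cs$upper[r]))
    }
  }
  lines <- c(lines, "Binary", paste(" ", cs$vars), "End")
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Solvers

#' Solve an integer program to certified optimality
#'
#' Exact 0/1 branch-and-bound. `status == "optimal"` certifies a global
#' optimum (gap 0). The search is deterministic given the program and
#' options. In `"structural"` mode (the default, and the only mode for
#' large grids) the equivalence and rectangularity row families are
#' enforced combinatorially without ever materializing them; `"matrix"`
#' mode materializes the full deduplicated row system and solves
#' generically, and is available as an independent cross-check on small
#' grids.
#'
#' @param program an `integer_program` from [build_direct_program()] or
#'   [build_refine_program()].
#' @param options list with optional fields `mode`
#'   (`"auto"`, `"structural"`, `"matrix"`), `time_limit` (seconds) and
#'   `seed` (recorded in the result; the search itself is deterministic).
#' @return an object of class `solve_result`: fields `status`
#'   (`"optimal"` or `"limit"`), `objective_value`, `gap`, `assignment`
#'   (named Boolean variable values), `membership` (grid matrix of cluster
#'   ids), `solver_log`, `mode`, `n_nodes`.
#' @export
solve_ip <- function(program, options = list()) {
  mode <- options$mode %||% "auto"
  time_limit <- options$time_limit %||% Inf
  seed <- options$seed %||% 0L
  if (mode == "auto") mode <- "structural"
  t0 <- Sys.time()
  res <- if (mode == "matrix") {
    solve_matrix_mode(program, time_limit)
  } else if (program$kind == "direct") {
    solve_direct_structural(program, time_limit)
  } else {
    solve_refine_structural(program, time_limit)
  }
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res$mode <- mode
  res$seed <- seed
  res$solver_log <- sprintf(
    "%s branch-and-bound (%s mode): %d nodes, %.3fs, status=%s, objective=%g, gap=%g",
    program$kind, mode, res$n_nodes, elapsed, res$status,
    res$objective_value, res$gap)
  class(res) <- "solve_result"
  res
}

#' @export
print.solve_result <- function(x, ...) {
  cat(x$solver_log, "\n")
  invisible(x)
}

#' @noRd
solve_direct_structural <- function(program, time_limit = Inf) {
  n1 <- program$grid_shape[1L]; n2 <- program$grid_shape[2L]
  n <- program$n_cells
  S <- program$S; lam <- program$lambda
  cells <- rowmajor_grid(c(n1, n2))
  # pair contribution when both endpoints decided: 2*s (same) or 2*lambda
  # (different); admissible bound for undecided pairs: the pairwise max.
  best_pair <- matrix(0, n, n)
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u != v) best_pair[u, v] <- max(2 * S[u, v], 2 * lam)
  }
  contrib_suffix <- numeric(n + 1L)
  for (t in n:1) {
    contrib_suffix[t] <- contrib_suffix[t + 1L] +
      if (t > 1L) sum(best_pair[seq_len(t - 1L), t]) else 0
  }
  st <- new.env(parent = emptyenv())
  st$best_val <- -Inf; st$best_memb <- NULL; st$nodes <- 0L
  st$deadline <- if (is.finite(time_limit)) Sys.time() + time_limit else NULL
  st$timed_out <- FALSE
  dfs <- function(t, memb, k_used, val) {
    st$nodes <- st$nodes + 1L
    if (!is.null(st$deadline) && st$nodes %% 2048L == 0L &&
        Sys.time() > st$deadline) {
      st$timed_out <- TRUE
      return(invisible(NULL))
    }
    if (t > n) {
      if (val > st$best_val) {
        st$best_val <- val; st$best_memb <- memb
      }
      return(invisible(NULL))
    }
    if (val + contrib_suffix[t] <= st$best_val) return(invisible(NULL))
    for (k in seq_len(k_used + 1L)) {
      if (st$timed_out) return(invisible(NULL))
      if (!rect_feasible(cells, memb, t, k)) next
      add <- 0
      if (t > 1L) {
        same <- memb[seq_len(t - 1L)] == k
        add <- sum(ifelse(same, 2 * S[seq_len(t - 1L), t], 2 * lam))
      }
      memb[t] <- k
      dfs(t + 1L, memb, max(k_used, k), val + add)
      memb[t] <- 0L
    }
  }
  dfs(1L, integer(n), 0L, 0)
  finish_direct(program, st, cells)
}

#' @noRd
finish_direct <- function(program, st, cells) {
  n <- program$n_cells
  obj <- st$best_val + program$offset
  memb <- st$best_memb
  M <- matrix(NA_integer_, program$grid_shape[1L], program$grid_shape[2L])
  M[cells] <- memb
  x <- numeric(n * (n - 1L) / 2L)
  names(x) <- character(length(x))
  idx <- 1L
  for (p in seq_len(n - 1L)) for (q in (p + 1L):n) {
    x[idx] <- as.numeric(memb[p] != memb[q])
    names(x)[idx] <- sprintf("x_%s_%s",
      paste(cells[p, ], collapse = "."), paste(cells[q, ], collapse = "."))
    idx <- idx + 1L
  }
  list(status = if (st$timed_out) "limit" else "optimal",
       objective_value = obj,
       gap = if (st$timed_out) Inf else 0,
       assignment = x, membership = M, n_nodes = st$nodes)
}

#' @noRd
solve_refine_structural <- function(program, time_limit = Inf) {
  n1 <- program$grid_shape[1L]; n2 <- program$grid_shape[2L]
  n <- program$n_cells; m <- program$m
  cells <- rowmajor_grid(c(n1, n2))
  Wc <- matrix(0, n, m)                   # agreement weight of cell x slice
  for (r in seq_len(m)) Wc[, r] <- program$W[, , r][cells]
  cellmax_suffix <- c(rev(cumsum(rev(apply(Wc, 1L, max)))), 0)
  slice_order <- t(apply(Wc, 1L, function(w) order(-w)))  # try likely slices first
  st <- new.env(parent = emptyenv())
  st$best_val <- -Inf; st$best_memb <- NULL; st$nodes <- 0L
  st$deadline <- if (is.finite(time_limit)) Sys.time() + time_limit else NULL
  st$timed_out <- FALSE
  dfs <- function(t, memb, val) {
    st$nodes <- st$nodes + 1L
    if (!is.null(st$deadline) && st$nodes %% 2048L == 0L &&
        Sys.time() > st$deadline) {
      st$timed_out <- TRUE
      return(invisible(NULL))
    }
    if (t > n) {
      if (val > st$best_val) {
        st$best_val <- val; st$best_memb <- memb
      }
      return(invisible(NULL))
    }
    if (val + cellmax_suffix[t] <= st$best_val) return(invisible(NULL))
    for (r in slice_order[t, ]) {
      if (st$timed_out) return(invisible(NULL))
      if (!rect_feasible(cells, memb, t, r)) next
      memb[t] <- r
      dfs(t + 1L, memb, val + Wc[t, r])
      memb[t] <- 0L
    }
  }
  dfs(1L, integer(n), 0)
  memb <- st$best_memb
  M <- matrix(NA_integer_, n1, n2)
  M[cells] <- memb
  y <- numeric(n * m)
  names(y) <- as.vector(vapply(seq_len(m), function(r) {
    sprintf("y_%s_%d", apply(cells, 1L, paste, collapse = "."), r)
  }, character(n)))
  y[(memb - 1L) * n + seq_len(n)] <- 1
  list(status = if (st$timed_out) "limit" else "optimal",
       objective_value = st$best_val,
       gap = if (st$timed_out) Inf else 0,
       assignment = y, membership = M, n_nodes = st$nodes)
}

# Generic 0/1 branch-and-bound over materialized rows: depth-first in
# variable order, feasibility pruning per row from partial min/max
# activity, optimistic bound from positive objective coefficients.
#' @noRd
solve_matrix_mode <- function(program, time_limit = Inf) {
  cs <- ip_constraints(program)
  nv <- length(cs$obj)
  row_ids <- lapply(cs$rows, function(r) as.integer(names(r)))
  row_coef <- lapply(cs$rows, as.numeric)
  # rows indexed by their largest variable: checked as soon as complete
  last_var <- vapply(row_ids, max, 1L)
  rows_by_last <- split(seq_along(cs$rows), factor(last_var, levels = seq_len(nv)))
  pos_suffix <- c(rev(cumsum(rev(pmax(cs$obj, 0)))), 0)
  st <- new.env(parent = emptyenv())
  st$best_val <- -Inf; st$best_assign <- NULL; st$nodes <- 0L
  st$deadline <- if (is.finite(time_limit)) Sys.time() + time_limit else NULL
  st$timed_out <- FALSE
  feasible_partial <- function(assign, v) {
    for (ri in rows_by_last[[v]]) {
      act <- sum(row_coef[[ri]] * assign[row_ids[[ri]]])
      if (act < cs$lower[ri] || act > cs$upper[ri]) return(FALSE)
    }
    TRUE
  }
  dfs <- function(v, assign, val) {
    st$nodes <- st$nodes + 1L
    if (!is.null(st$deadline) && st$nodes %% 2048L == 0L &&
        Sys.time() > st$deadline) {
      st$timed_out <- TRUE
      return(invisible(NULL))
    }
    if (v > nv) {
      if (val > st$best_val) {
        st$best_val <- val; st$best_assign <- assign
      }
      return(invisible(NULL))
    }
    if (val + pos_suffix[v] <= st$best_val) return(invisible(NULL))
    for (b in c(0, 1)) {
      if (st$timed_out) return(invisible(NULL))
      assign[v] <- b
      if (feasible_partial(assign, v)) {
        dfs(v + 1L, assign, val + b * cs$obj[v])
      }
    }
    assign[v] <- NA_real_
  }
  dfs(1L, rep(NA_real_, nv), 0)
  assign <- st$best_assign
  names(assign) <- cs$vars
  memb <- decode_membership_from_assignment(program, assign)
  list(status = if (st$timed_out) "limit" else "optimal",
       objective_value = st$best_val + cs$offset,
       gap = if (st$timed_out) Inf else 0,
       assignment = assign, membership = memb, n_nodes = st$nodes)
}

#' @noRd
decode_membership_from_assignment <- function(program, assign) {
  n1 <- program$grid_shape[1L]; n2 <- program$grid_shape[2L]
  n <- n1 * n2
  cells <- rowmajor_grid(c(n1, n2))
  M <- matrix(NA_integer_, n1, n2)
  if (program$kind == "direct") {
    same <- diag(TRUE, n)
    idx <- 1L
    for (p in seq_len(n - 1L)) for (q in (p + 1L):n) {
      same[p, q] <- same[q, p] <- assign[idx] == 0
      idx <- idx + 1L
    }
    comp <- integer(n); cid <- 0L
    for (i in seq_len(n)) {
      if (comp[i] == 0L) { cid <- cid + 1L; comp[same[i, ]] <- cid }
    }
    M[cells] <- comp
  } else {
    m <- program$m
    memb <- integer(n)
    for (r in seq_len(m)) {
      sel <- assign[(r - 1L) * n + seq_len(n)] == 1
      memb[sel] <- r
    }
    M[cells] <- memb
  }
  M
}

#' Decode a direct-program solution into a rectangular partition
#'
#' Expands the pair variables into the full Boolean distance tensor and
#' decodes it with [x_to_partition()], which re-verifies every constraint
#' family; a violation indicates an internal solver/build inconsistency.
#'
#' @param result a `solve_result` with `status == "optimal"`.
#' @param grid_shape integer pair `(n1, n2)`.
#' @return a `rect_partition` (canonical labels).
#' @export
decode_direct <- function(result, grid_shape) {
  if (result$status != "optimal") {
    stop2("cannot decode a non-certified solution (status = ",
          result$status, ")")
  }
  M <- result$membership
  n1 <- grid_shape[1L]; n2 <- grid_shape[2L]
  stopifnot(nrow(M) == n1, ncol(M) == n2)
  x <- array(0, c(n1, n2, n1, n2))
  v <- as.vector(M)
  samef <- outer(v, v, "==")
  x[] <- 1 - samef
  x_to_partition(x)
}

#' Decode a refinement-program solution into a rectangular partition
#'
#' Reassembles Y from the solution, checks every non-empty slice is an
#' outer-product (rank-1 0/1) pattern, and drops empty slices.
#'
#' @param result a `solve_result` with `status == "optimal"`.
#' @param grid_shape integer pair `(n1, n2)`.
#' @param m number of slices of the program.
#' @return a `rect_partition`.
#' @export
decode_refine <- function(result, grid_shape, m) {
  if (result$status != "optimal") {
    stop2("cannot decode a non-certified solution (status = ",
          result$status, ")")
  }
  n1 <- grid_shape[1L]; n2 <- grid_shape[2L]
  M <- result$membership
  y <- array(0, c(n1, n2, m))
  for (r in seq_len(m)) y[, , r][M == r] <- 1
  y_to_partition(y)
}

#' Evaluate the direct objective for a given partition
#'
#' Computes `<S, 1-X> + lambda * <1, X>` exactly via [partition_to_x()].
#' Diagonal self-similarity terms are included; they are constant across
#' partitions and immaterial to the argmax.
#'
#' @param S a `similarity_tensor` (or order-4 array).
#' @param P a `rect_partition`.
#' @param lambda non-negative regularizer.
#' @return the objective value.
#' @export
objective_direct <- function(S, P, lambda) {
  V <- if (inherits(S, "similarity_tensor")) S$values else S
  if (!all(dim(V)[1:2] == P$grid_shape)) {
    stop2("similarity tensor shape ", paste(dim(V), collapse = "x"),
          " does not match grid ", paste(P$grid_shape, collapse = "x"))
  }
  x <- partition_to_x(P)
  sum(V * (1 - x)) + lambda * sum(x)
}

#' Evaluate the refinement objective (agreement) for a given partition
#'
#' Maximizes `<W, Y>` over the assignment of the partition's clusters to
#' the `m` slices of `W` (injective; clusters keep their identity).
#'
#' @param W a 0/1 seed assignment array `(n1, n2, m)`.
#' @param P a `rect_partition`.
#' @return the best achievable number of unchanged assignments.
#' @export
objective_refine <- function(W, P) {
  m <- dim(W)[3L]
  cl <- P$clusters
  if (length(cl) > m) return(-Inf)
  A <- matrix(0, length(cl), m)
  for (k in seq_along(cl)) {
    for (r in seq_len(m)) {
      A[k, r] <- sum(W[cl[[k]]$rows, cl[[k]]$cols, r])
    }
  }
  best_injective_sum(A)
}

# maximum-weight injective assignment of rows to columns (small sizes)
#' @noRd
best_injective_sum <- function(A) {
  nr <- nrow(A); nc <- ncol(A)
  if (nr == 0L) return(0)
  rec <- function(k, used) {
    if (k > nr) return(0)
    best <- -Inf
    for (r in seq_len(nc)) {
      if (used[r]) next
      used[r] <- TRUE
      best <- max(best, A[k, r] + rec(k + 1L, used))
      used[r] <- FALSE
    }
    best
  }
  rec(1L, logical(nc))
}

#' Brute-force optimum of the direct program (oracle)
#'
#' Exhaustively scores every rectangular partition of the grid with
#' [objective_direct()]. Independent of the branch-and-bound solver; used
#' to certify it on small instances. Ties are broken by enumeration order.
#'
#' @param S a `similarity_tensor` (or order-4 array).
#' @param lambda non-negative regularizer.
#' @return a list with `partition` and `objective`.
#' @export
brute_force_direct <- function(S, lambda) {
  V <- if (inherits(S, "similarity_tensor")) S$values else S
  dm <- dim(V)
  parts <- enumerate_rectangular_partitions(dm[1L], dm[2L])
  scores <- vapply(parts, function(P) objective_direct(V, P, lambda), 1)
  best <- which.max(scores)
  list(partition = parts[[best]], objective = scores[best])
}

#' Brute-force optimum of the refinement program (oracle)
#'
#' @param W a 0/1 seed assignment array `(n1, n2, m)`.
#' @return a list with `partition` and `agreement`.
#' @export
brute_force_refine <- function(W) {
  dm <- dim(W)
  m <- dm[3L]
  parts <- enumerate_rectangular_partitions(dm[1L], dm[2L])
  parts <- Filter(function(P) length(P$clusters) <= m, parts)
  scores <- vapply(parts, function(P) objective_refine(W, P), 1)
  best <- which.max(scores)
  list(partition = parts[[best]], agreement = scores[best])
}
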