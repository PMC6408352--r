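# Synthetic benchmark data: complete tensors with planted rectangular
# cluster structure whose blocks share a response mechanism. Each cluster
# carries one crosstalk model; every cell in a cluster shows that model's
# time course up to a cell-specific amplitude, plus additive truncated
# Gaussian noise. Amplitude heterogeneity is a pure scalar on the whole
# response vector, so unit-l2 row normalization removes it exactly and
# within-cluster cosine similarity is 1 in the noise-free limit.

#' Sample a random rectangular partition
#'
#' Grows a partition by repeatedly splitting the row set or the column set
#' of a randomly chosen cluster into two arbitrary non-empty subsets
#' (subsets need not be contiguous, so disconnected rectangles arise),
#' until exactly `m` non-empty clusters exist. Deterministic per seed.
#'
#' @param n1,n2 grid extents.
#' @param m number of clusters, `1 <= m <= n1 * n2`.
#' @param seed RNG seed.
#' @return a validated `rect_partition`.
#' @export
sample_rectangular_partition <- function(n1, n2, m, seed = 0L) {
  n1 <- as.integer(n1); n2 <- as.integer(n2); m <- as.integer(m)
  if (m < 1L || m > n1 * n2) {
    stop2("m must be between 1 and n1*n2 = ", n1 * n2)
  }
  withr::with_seed(seed, {
    clusters <- list(list(rows = seq_len(n1), cols = seq_len(n2)))
    while (length(clusters) < m) {
      splittable <- which(vapply(clusters, function(cl) {
        length(cl$rows) > 1L || length(cl$cols) > 1L
      }, logical(1L)))
      idx <- splittable[sample.int(length(splittable), 1L)]
      cl <- clusters[[idx]]
      axes <- c(if (length(cl$rows) > 1L) "rows", if (length(cl$cols) > 1L) "cols")
      ax <- if (length(axes) == 1L) axes else axes[sample.int(2L, 1L)]
      set <- cl[[ax]]
      repeat {
        take <- as.logical(stats::rbinom(length(set), 1L, 0.5))
        if (any(take) && !all(take)) break
      }
      a <- cl; b <- cl
      a[[ax]] <- set[take]; b[[ax]] <- set[!take]
      clusters[[idx]] <- a
      clusters[[length(clusters) + 1L]] <- b
    }
    rect_partition(c(n1, n2), clusters)
  })
}

#' Default planted-mechanism library
#'
#' Up to five mechanistically distinct crosstalk models with fixed
#' parameters, chosen for well-separated response shapes over the default
#' design (times 10/30/90 minutes, doses 1/0.2): a fast transient
#' pERK-only response, a slow pAKT-only ramp, a sustained dual response, a
#' fast transient pAKT-only response and a slow pERK-only ramp. All
#' pairwise cosine similarities of the noise-free response vectors are
#' below 0.66.
#'
#' @param m number of mechanisms needed (`<= 5`).
#' @return a list of `list(model =, params =)` entries.
#' @export
default_mechanisms <- function(m) {
  lib <- list(
    list(model = model_spec(c("R->E" = "activation")),
         params = c(dR = 0.3, dE = 0.25, dA = 0.05, k_R_E = 3)),
    list(model = model_spec(c("R->A" = "activation")),
         params = c(dR = 0.003, dE = 0.02, dA = 0.003, k_R_A = 0.03)),
    list(model = model_spec(c("R->E" = "activation", "R->A" = "activation")),
         params = c(dR = 0.005, dE = 0.02, dA = 0.02,
                    k_R_E = 0.2, k_R_A = 0.2)),
    list(model = model_spec(c("R->A" = "activation")),
         params = c(dR = 0.4, dE = 0.05, dA = 0.3, k_R_A = 4)),
    list(model = model_spec(c("R->E" = "activation")),
         params = c(dR = 0.004, dE = 0.004, dA = 0.02, k_R_E = 0.03)))
  if (m > length(lib)) {
    stop2("default mechanism library has ", length(lib),
          " entries; supply mechanisms explicitly for m = ", m)
  }
  lib[seq_len(m)]
}

#' Assemble a synthetic ground truth
#'
#' @param partition a `rect_partition`.
#' @param mechanisms list of `list(model =, params =)`, one per cluster
#'   (default: [default_mechanisms()]).
#' @param noise_sigma additive noise standard deviation (`>= 0`).
#' @param seed RNG seed controlling amplitudes and noise draws.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(partition, mechanisms = NULL,
                            noise_sigma = 0, seed = 0L) {
  if (is.null(mechanisms)) {
    mechanisms <- default_mechanisms(length(partition$clusters))
  }
  if (length(mechanisms) != length(partition$clusters)) {
    stop2("need one mechanism per cluster (", length(partition$clusters),
          "), got ", length(mechanisms))
  }
  if (noise_sigma < 0) stop2("noise_sigma must be non-negative")
  structure(list(partition = partition, mechanisms = mechanisms,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Generate a complete synthetic data tensor with planted clusters
#'
#' Every grid cell's measurements are its cluster's simulated mechanism
#' time course, scaled by a cell-specific amplitude drawn uniformly from
#' `amplitude_range`, plus additive Gaussian noise truncated at zero.
#' Noise is drawn once per seed and scaled by `noise_sigma`, so increasing
#' sigma on a fixed seed degrades the same realization monotonically.
#'
#' @param truth a `synthetic_truth`.
#' @param doses named dose scales (default `c("1" = 1, "0.2" = 0.2)`).
#' @param times observation times in minutes (default `c(10, 30, 90)`).
#' @param amplitude_range cell-specific multiplicative amplitude range.
#' @return a complete, non-negative [data_tensor()] of order 5 with axes
#'   `cell_line, ligand, dose, time, protein`.
#' @export
generate_dataset <- function(truth,
                             doses = c("1" = 1, "0.2" = 0.2),
                             times = c(10, 30, 90),
                             amplitude_range = c(0.7, 1.3)) {
  P <- truth$partition
  n1 <- P$grid_shape[1L]; n2 <- P$grid_shape[2L]
  nd <- length(doses); nt <- length(times); np <- 2L
  curves <- lapply(seq_along(truth$mechanisms), function(k) {
    mech <- truth$mechanisms[[k]]
    tr <- try(simulate_model(mech$model, mech$params, times, doses),
              silent = TRUE)
    if (inherits(tr, "try-error")) {
      stop2("simulation failed for the mechanism of cluster ", k, ": ",
            model_id(mech$model))
    }
    tr$values
  })
  M <- partition_membership(P)
  vals <- array(0, dim = c(n1, n2, nd, nt, np))
  withr::with_seed(truth$seed, {
    amp <- matrix(stats::runif(n1 * n2, amplitude_range[1L],
                               amplitude_range[2L]), n1, n2)
    noise <- array(stats::rnorm(length(vals)), dim = dim(vals))
  })
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    vals[i, j, , , ] <- amp[i, j] * curves[[M[i, j]]] +
      truth$noise_sigma * noise[i, j, , , ]
  }
  vals <- pmax(vals, 0)
  data_tensor(vals, list(
    cell_line = sprintf("CL%02d", seq_len(n1)),
    ligand = sprintf("LG%02d", seq_len(n2)),
    dose = names(doses),
    time = as.character(times),
    protein = c("pERK", "pAKT")))
}

#' Planted-separation regularizer
#'
#' For a similarity matrix with a known planted partition, returns the
#' midpoint between the largest between-cluster and the smallest
#' within-cluster similarity. When the two are separated, any lambda in
#' that open interval makes the planted partition the unique optimum of
#' the direct program, so the midpoint is the principled choice for
#' recovery experiments.
#'
#' @param S_mat a `similarity_matrix` over the partition's grid.
#' @param P the planted `rect_partition`.
#' @return a list with `lambda`, `max_between`, `min_within` and
#'   `separated` (logical).
#' @export
separation_lambda <- function(S_mat, P) {
  V <- S_mat$values
  memb <- as.vector(t(partition_membership(P)))  # row-major cell order
  same <- outer(memb, memb, "==")
  ut <- upper.tri(V)
  min_within <- suppressWarnings(min(V[ut & same]))
  max_between <- suppressWarnings(max(V[ut & !same]))
  list(lambda = (max_between + min_within) / 2,
       max_between = max_between, min_within = min_within,
       separated = is.finite(min_within) && is.finite(max_between) &&
         max_between < min_within)
}
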