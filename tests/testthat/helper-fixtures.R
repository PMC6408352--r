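# Shared fixture builders. Everything is generated in code; no data files.

# long-format data frame covering a full label grid, values 1..N in
# row-major order (last axis fastest)
make_long_df <- function(shape, axes = paste0("ax", seq_along(shape))) {
  labels <- lapply(seq_along(shape), function(i) {
    paste0(substr(axes[i], 1, 1), seq_len(shape[i]))
  })
  g <- expand.grid(rev(labels), stringsAsFactors = FALSE)[, rev(seq_along(shape)), drop = FALSE]
  names(g) <- axes
  g$value <- seq_len(nrow(g))
  g
}

random_tensor <- function(shape, seed = 1) {
  withr::with_seed(seed, {
    vals <- array(runif(prod(shape), 0.1, 1), dim = shape)
  })
  labels <- lapply(seq_along(shape), function(i) paste0("x", i, "_", seq_len(shape[i])))
  names(labels) <- paste0("axis", seq_along(shape))
  data_tensor(vals, labels)
}

# similarity matrix with given values, cells of an n1 x n2 grid in
# row-major order
sim_matrix <- function(V, dims) {
  structure(list(values = V, index = recticluster:::rowmajor_grid(dims),
                 labels = paste0("e", seq_len(nrow(V))), dims = as.integer(dims)),
            class = "similarity_matrix")
}

# 2x2 orthogonal-row-profiles similarity: 1 within grid rows, 0 across
orthogonal_rows_S <- function() {
  V <- matrix(0, 4, 4); diag(V) <- 1
  V[1, 2] <- V[2, 1] <- 1   # cells (1,1),(1,2)
  V[3, 4] <- V[4, 3] <- 1   # cells (2,1),(2,2)
  unflatten_similarity(V, c(2, 2))
}

random_similarity_tensor <- function(dims, seed) {
  n <- prod(dims)
  withr::with_seed(seed, {
    V <- matrix(runif(n * n), n)
  })
  V <- (V + t(V)) / 2
  diag(V) <- 1
  unflatten_similarity(V, dims)
}

make_cluster_response <- function(values, times = c(10, 30, 90),
                                  doses = c("1" = 1, "0.2" = 0.2)) {
  structure(list(values = values, times = times, doses = doses,
                 observables = c("pERK", "pAKT"), n = length(values),
                 n_cells = 1L),
            class = "cluster_response")
}

# noise-free response of a model at given parameters
model_response <- function(model, params, times = c(10, 30, 90),
                           doses = c("1" = 1, "0.2" = 0.2), sigma = 0,
                           noise_seed = 0) {
  v <- simulate_model(model, params, times, doses)$values
  if (sigma > 0) {
    v <- pmax(v + withr::with_seed(noise_seed,
      array(stats::rnorm(length(v), 0, sigma), dim = dim(v))), 0)
  }
  make_cluster_response(v, times, doses)
}

# check every equivalence + rectangularity constraint family on an X tensor
x_constraints_ok <- function(x) {
  dm <- dim(x)
  n1 <- dm[1L]; n2 <- dm[2L]; n <- n1 * n2
  Xf <- x; dim(Xf) <- c(n, n)
  if (any(diag(Xf) != 0)) return("reflexivity")
  if (any(Xf != t(Xf))) return("symmetry")
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    v <- -Xf[i, k] + Xf[i, j] + Xf[j, k]
    if (v < 0 || v > 2) return("transitivity")
  }
  for (i1 in seq_len(n1)) for (i2 in seq_len(n2)) {
    for (j1 in seq_len(n1)) for (j2 in seq_len(n2)) {
      if (x[i1, i2, j1, j2] != x[i1, j2, j1, i2]) return("swap equality")
      d1 <- x[i1, i2, j1, j2] - x[i1, i2, j1, i2]
      if (d1 < 0 || d1 > 1) return("row inequality")
      d2 <- x[i1, i2, j1, j2] - x[i1, i2, i1, j2]
      if (d2 < 0 || d2 > 1) return("column inequality")
    }
  }
  TRUE
}

# the fixed parameter-recovery battery: identifiable designs (see the
# methods vignette for the rationale)
recovery_battery <- function() {
  list(
    list(c("R->E" = "activation", "R->A" = "activation"),
         c(dR = 0.02, dE = 0.05, dA = 0.03, k_R_E = 0.06, k_R_A = 0.04)),
    list(c("R->E" = "activation", "R->A" = "activation"),
         c(dR = 0.01, dE = 0.10, dA = 0.05, k_R_E = 0.05, k_R_A = 0.08)),
    list(c("R->E" = "activation", "R->A" = "activation"),
         c(dR = 0.05, dE = 0.02, dA = 0.02, k_R_E = 0.03, k_R_A = 0.10)),
    list(c("R->E" = "activation", "R->A" = "activation"),
         c(dR = 0.03, dE = 0.06, dA = 0.08, k_R_E = 0.12, k_R_A = 0.03)),
    list(c("R->E" = "activation", "R->A" = "activation"),
         c(dR = 0.10, dE = 0.04, dA = 0.06, k_R_E = 0.08, k_R_A = 0.12)),
    list(c("R->E" = "activation", "R->A" = "activation"),
         c(dR = 0.02, dE = 0.08, dA = 0.02, k_R_E = 0.04, k_R_A = 0.06)),
    list(c("R->E" = "activation"),
         c(dR = 0.05, dE = 0.08, dA = 0.05, k_R_E = 0.04)),
    list(c("R->A" = "activation"),
         c(dR = 0.06, dE = 0.05, dA = 0.04, k_R_A = 0.03)),
    list(c("R->A" = "activation"),
         c(dR = 0.03, dE = 0.05, dA = 0.12, k_R_A = 0.05)),
    list(c("R->E" = "activation", "E->A" = "activation"),
         c(dR = 0.04, dE = 0.03, dA = 0.06, k_R_E = 0.08, k_E_A = 0.1)))
}

# candidate pool for the model-selection experiments: distinct pathway
# hypotheses (no strict supersets of the generating model; see vignette)
selection_pool <- function() {
  lapply(list(
    c("R->A" = "activation"),                       # generating model
    c("R->E" = "activation"),
    c("R->E" = "activation", "R->A" = "activation"),
    c("R->E" = "activation", "E->A" = "activation"),
    c("R->A" = "activation", "A->E" = "activation")), model_spec)
}

selection_truth_params <- function() {
  c(dR = 0.003, dE = 0.02, dA = 0.003, k_R_A = 0.03)
}

# noise-free fits must reach the residual floor; restart with a shifted
# seed (deterministically) until they do
fit_to_floor <- function(model, resp, seed, floor = 1e-8, attempts = 3L) {
  fit <- NULL
  for (attempt in seq_len(attempts) - 1L) {
    cand <- fit_model(model, resp, options = list(
      bounds = c(1e-3, 10), seed = seed + 1000L * attempt))
    if (is.null(fit) || cand$rss < fit$rss) fit <- cand
    if (fit$rss < floor) break
  }
  fit
}

# light but adequate fit options for the selection experiments
selection_fit_options <- function() {
  list(bounds = c(1e-3, 10), rounds = 3L, samples = 40L,
       first_round_factor = 4L, polish_starts = 2L, polish_iter = 100L)
}
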