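#' Mean response of a cluster
#'
#' Averages the normalized measurements over a cluster's grid cells,
#' per (dose, time, observable) combination, producing the target data for
#' model fitting.
#'
#' @param Z a [data_tensor()] of order 5: grid row axis, grid column axis,
#'   dose, time, observable (in that order).
#' @param P a `rect_partition` of the first two axes.
#' @param cluster_id cluster index (canonical order).
#' @param dose_scales,times numeric values of the dose and time axes;
#'   by default parsed from the axis labels.
#' @return an object of class `cluster_response` with fields `values`
#'   (array `(n_doses, n_times, n_obs)`), `times`, `doses` (named scales),
#'   `observables`, `n` (total scalar data points) and `n_cells`.
#' @export
mean_response <- function(Z, P, cluster_id, dose_scales = NULL, times = NULL) {
  if (length(Z$shape) != 5L) {
    stop2("mean_response expects an order-5 tensor ",
          "(grid rows, grid cols, dose, time, observable)")
  }
  if (cluster_id < 1L || cluster_id > length(P$clusters)) {
    stop2("no cluster ", cluster_id, " in the partition")
  }
  cl <- P$clusters[[cluster_id]]
  sub <- Z$values[cl$rows, cl$cols, , , , drop = FALSE]
  vals <- apply(sub, c(3L, 4L, 5L), mean)
  dose_labels <- Z$axes[[3L]]
  if (is.null(dose_scales)) {
    dose_scales <- suppressWarnings(as.numeric(dose_labels))
    if (anyNA(dose_scales)) {
      stop2("dose labels are not numeric; supply dose_scales")
    }
  }
  if (is.null(times)) {
    times <- suppressWarnings(as.numeric(Z$axes[[4L]]))
    if (anyNA(times)) stop2("time labels are not numeric; supply times")
  }
  structure(list(values = vals, times = times,
                 doses = stats::setNames(dose_scales, dose_labels),
                 observables = Z$axes[[5L]],
                 n = length(vals),
                 n_cells = length(cl$rows) * length(cl$cols)),
            class = "cluster_response")
}

#' Small-sample corrected Akaike information criterion
#'
#' Gaussian-likelihood form with the error variance profiled out:
#' `n * log(max(rss, floor) / n) + 2k + 2k(k+1)/(n - k - 1)`. Lower is
#' better; the correction term penalizes parameter-rich models relative to
#' the number of data points.
#'
#' @param rss residual sum of squares (non-negative).
#' @param n number of scalar data points.
#' @param k number of fitted parameters; requires `n - k - 1 >= 1`.
#' @param floor lower guard on `rss` so a perfect fit stays finite.
#' @return the AICc value.
#' @export
aicc_score <- function(rss, n, k, floor = 1e-12) {
  if (n - k - 1 < 1) {
    stop2("AICc undefined for n = ", n, ", k = ", k,
          " (n - k - 1 = ", n - k - 1, " < 1); ",
          "the model should have been filtered out")
  }
  if (rss < 0) stop2("rss must be non-negative")
  n * log(max(rss, floor) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a crosstalk model to a cluster response
#'
#' Minimizes the residual sum of squares between the simulated and
#' observed (dose, time, observable) values by squeeze-and-breathe Monte
#' Carlo search: iterated rounds of log-uniform sampling inside a moving
#' box, selection of the elite fits, contraction of the box around the
#' elites ("squeeze", geometric with an elite-spread floor) with one
#' scheduled re-expansion around the incumbent ("breathe"), finished by
#' box-constrained Levenberg-Marquardt polishing from the best distinct
#' elites. The search is reproducible bit-for-bit given the seed; a
#' global optimum is not claimed.
#'
#' @param model a `model_spec` (must leave `n - k - 1 >= 1` on this data).
#' @param data a `cluster_response`.
#' @param options list overriding any of: `bounds` (`c(1e-3, 1e3)`,
#'   log-uniform sampling range for every parameter), `rounds` (10),
#'   `samples` (200 per round; the first, exploratory round draws
#'   `first_round_factor` (4) times as many), `elite_frac` (0.1),
#'   `contract` (0.5), `breathe_at` (round 6), `polish_starts` (8),
#'   `polish_iter` (250 Levenberg-Marquardt iterations per start), `seed`
#'   (0), `init` (`"zero"` or `"first-observation"` initial pERK/pAKT
#'   levels), `rtol`/`atol` integrator tolerances.
#' @return an object of class `fit_result`: `model`, `params`, `rss`, `k`,
#'   `aicc`, `n_evals`, `seed`.
#' @export
fit_model <- function(model, data, options = list()) {
  o <- utils::modifyList(list(bounds = c(1e-3, 1e3), rounds = 10L,
                              samples = 200L, elite_frac = 0.1,
                              contract = 0.5, breathe_at = 6L,
                              first_round_factor = 4L,
                              polish_starts = 8L,
                              polish_iter = 250L, seed = 0L,
                              init = "zero", rtol = 1e-6, atol = 1e-8),
                         options)
  pn <- model_parameters(model)
  k <- length(pn)
  n <- data$n
  if (n - k - 1 < 1) {
    stop2("model has k = ", k, " parameters for n = ", n,
          " data points; AICc undefined (apply identifiability_filter)")
  }
  init <- if (identical(o$init, "first-observation")) {
    c(E = mean(data$values[, 1L, 1L]), A = mean(data$values[, 1L, 2L]))
  } else {
    c(E = 0, A = 0)
  }
  n_evals <- 0L
  obs <- data$values
  resid <- function(logth) {
    n_evals <<- n_evals + 1L
    th <- stats::setNames(10^logth, pn)
    sim <- try(suppressWarnings(
      simulate_model(model, th, data$times, data$doses,
                     init = init, rtol = o$rtol, atol = o$atol)),
      silent = TRUE)
    if (inherits(sim, "try-error")) return(rep(1e3, length(obs)))
    as.vector(sim$values - obs)
  }
  loss <- function(logth) sum(resid(logth)^2)
  lo0 <- rep(log10(o$bounds[1L]), k)
  hi0 <- rep(log10(o$bounds[2L]), k)
  best <- NULL; best_rss <- Inf
  fail_rss <- 1e6 * length(obs)          # rss assigned to failed integrations
  withr::with_seed(o$seed, {
    half <- (hi0 - lo0) / 2
    centre <- (lo0 + hi0) / 2
    elites <- NULL
    for (round in seq_len(o$rounds)) {
      lo <- pmax(lo0, centre - half)
      hi <- pmin(hi0, centre + half)
      ns <- if (round == 1L) o$samples * o$first_round_factor else o$samples
      X <- matrix(stats::runif(ns * k), ncol = k)
      X <- sweep(sweep(X, 2L, hi - lo, "*"), 2L, lo, "+")
      if (!is.null(best)) X <- rbind(best, X)
      rss <- apply(X, 1L, loss)
      if (round == 1L && all(rss >= fail_rss)) {
        stop2("model unfittable on data: every sampled parameter vector ",
              "failed to integrate")
      }
      ord <- order(rss)
      keep <- ord[seq_len(min(3L, length(ord)))]
      elites <- rbind(elites, cbind(rss[keep], X[keep, , drop = FALSE]))
      if (rss[ord[1L]] < best_rss) {
        best_rss <- rss[ord[1L]]
        best <- X[ord[1L], ]
      }
      # squeeze: recentre on the round's elites, contract geometrically but
      # never below the elite spread; one scheduled breathe re-expands
      # around the incumbent to escape a bad basin
      n_elite <- max(2L, ceiling(o$elite_frac * ns))
      el <- X[ord[seq_len(min(n_elite, length(ord)))], , drop = FALSE]
      centre <- colMeans(el)
      half <- pmax(o$contract * half, 2.5 * apply(el, 2L, stats::sd))
      if (round == o$breathe_at) {
        centre <- best
        half <- (hi0 - lo0) / 4
      }
    }
    # polish: box-constrained Levenberg-Marquardt from the best distinct
    # elite starts accumulated over all rounds
    elites <- elites[order(elites[, 1L]), , drop = FALSE]
    starts <- unique(round(elites[, -1L, drop = FALSE], 6L))
    starts <- starts[seq_len(min(o$polish_starts, nrow(starts))), , drop = FALSE]
    for (s in seq_len(nrow(starts))) {
      pol <- try(suppressWarnings(minpack.lm::nls.lm(
        starts[s, ], fn = resid, lower = lo0, upper = hi0,
        control = minpack.lm::nls.lm.control(maxiter = o$polish_iter,
                                             ptol = 1e-13, ftol = 1e-15))),
        silent = TRUE)
      if (inherits(pol, "try-error")) next
      v <- sum(pol$fvec^2)
      if (v < best_rss) {
        best_rss <- v
        best <- pol$par
      }
    }
  })
  structure(list(model = model,
                 params = stats::setNames(10^best, pn),
                 rss = best_rss, k = k,
                 aicc = aicc_score(best_rss, n, k),
                 n_evals = n_evals, seed = o$seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:", model_id(x$model), "\n")
  cat(sprintf("  rss = %.6g, k = %d, AICc = %.4f (%d evaluations)\n",
              x$rss, x$k, x$aicc, x$n_evals))
  invisible(x)
}

#' Rank fitted models by AICc
#'
#' @param fits list of `fit_result` objects on the same data.
#' @param top how many models to keep in the report table (default 4).
#' @return an object of class `model_ranking`: `table` is a data frame
#'   (rank, model, k, rss, aicc, delta_aicc) in ascending AICc order, ties
#'   broken by smaller `k` then input (canonical pool) order; `fits` holds
#'   all fits in ranked order.
#' @export
rank_models <- function(fits, top = 4L) {
  if (!length(fits)) stop2("no fits to rank")
  aicc <- vapply(fits, function(f) f$aicc, 1)
  kk <- vapply(fits, function(f) as.integer(f$k), 1L)
  ord <- order(aicc, kk, seq_along(fits))
  fits <- fits[ord]
  tab <- data.frame(
    rank = seq_along(fits),
    model = vapply(fits, function(f) model_id(f$model), character(1L)),
    k = vapply(fits, function(f) as.integer(f$k), 1L),
    rss = vapply(fits, function(f) f$rss, 1),
    aicc = vapply(fits, function(f) f$aicc, 1))
  tab$delta_aicc <- tab$aicc - tab$aicc[1L]
  structure(list(table = utils::head(tab, top), fits = fits),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
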