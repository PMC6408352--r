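# Candidate crosstalk models. Three molecular species: receptor (R), pERK
# (E) and pAKT (A). R and the two readouts are linked by six ordered
# interactions (R->E, R->A, E->A, A->E, E->R, A->R), each of which can be
# an activation, an inhibition, or absent. pERK and pAKT are observed; the
# receptor is latent and is set by the applied ligand dose.

.species_pairs <- c("R->E", "R->A", "E->A", "A->E", "E->R", "A->R")
.sign_levels <- c("none", "activation", "inhibition")

#' Construct a crosstalk model specification
#'
#' @param interactions named character vector over the six ordered species
#'   pairs `R->E, R->A, E->A, A->E, E->R, A->R`, each `"activation"`,
#'   `"inhibition"` or `"none"` (missing pairs default to `"none"`).
#' @param kinetics `"mass_action"` or `"michaelis_menten"` (activation
#'   kinetics; rate constants are per unit time, Michaelis constants in the
#'   normalized concentration units of the data).
#' @param inhibition_mechanism `"blocking"` (inhibitor attenuates the
#'   activation flux into its target) or `"removal"` (inhibitor actively
#'   removes/dephosphorylates its target).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(interactions = character(),
                       kinetics = c("mass_action", "michaelis_menten"),
                       inhibition_mechanism = c("blocking", "removal")) {
  kinetics <- match.arg(kinetics)
  inhibition_mechanism <- match.arg(inhibition_mechanism)
  full <- stats::setNames(rep("none", 6L), .species_pairs)
  if (length(interactions)) {
    bad <- setdiff(names(interactions), .species_pairs)
    if (length(bad)) stop2("unknown interaction pair(s): ",
                           paste(bad, collapse = ", "))
    bad <- setdiff(interactions, .sign_levels)
    if (length(bad)) stop2("unknown interaction sign(s): ",
                           paste(bad, collapse = ", "))
    full[names(interactions)] <- interactions
  }
  structure(list(interactions = full, kinetics = kinetics,
                 inhibition_mechanism = inhibition_mechanism),
            class = "model_spec")
}

#' Short identifier of a model specification
#'
#' @param model a `model_spec`.
#' @return a string such as `"R>E:+ R>A:0 E>A:- A>E:0 E>R:0 A>R:0 [ma/block]"`.
#' @export
model_id <- function(model) {
  code <- c(none = "0", activation = "+", inhibition = "-")
  kin <- c(mass_action = "ma", michaelis_menten = "mm")
  inh <- c(blocking = "block", removal = "remove")
  paste0(paste(sprintf("%s:%s", sub("->", ">", .species_pairs),
                       code[model$interactions]), collapse = " "),
         " [", kin[model$kinetics], "/", inh[model$inhibition_mechanism], "]")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", model_id(x), "\n")
  cat("parameters (", length(model_parameters(x)), "): ",
      paste(model_parameters(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Parameter names of a model
#'
#' Every model carries three basal decay rates (`dR`, `dE`, `dA`). Each
#' activation edge adds one rate constant under mass action (`k_U_T`) or a
#' maximal rate and Michaelis constant under Michaelis-Menten (`V_U_T`,
#' `K_U_T`); each inhibition edge adds one constant (`Ki_U_T` for blocking,
#' `kr_U_T` for removal). The count is deterministic from the spec.
#'
#' @param model a `model_spec`.
#' @return character vector of parameter names, in canonical order.
#' @export
model_parameters <- function(model) {
  out <- c("dR", "dE", "dA")
  for (pair in .species_pairs) {
    sgn <- model$interactions[[pair]]
    if (sgn == "none") next
    uv <- strsplit(pair, "->", fixed = TRUE)[[1L]]
    tag <- paste(uv[1L], uv[2L], sep = "_")
    out <- c(out, if (sgn == "activation") {
      if (model$kinetics == "mass_action") paste0("k_", tag)
      else c(paste0("V_", tag), paste0("K_", tag))
    } else {
      if (model$inhibition_mechanism == "blocking") paste0("Ki_", tag)
      else paste0("kr_", tag)
    })
  }
  out
}

#' Enumerate the candidate model pool
#'
#' The default pool assigns each of the six ordered species pairs one of
#' three signs (activation, inhibition, none), for `3^6 = 729` model
#' specifications, all under one kinetic convention and one inhibition
#' mechanism. Enumeration is deterministic (signs vary fastest over the
#' last pair) and duplicate-free. The biologically motivated requirement
#' that the receptor phosphorylates ERK and/or AKT is applied by the
#' separate `receptor_edge_filter` flag, which drops specs whose `R->E`
#' and `R->A` are both `"none"`.
#'
#' @param pairs the interaction pairs to vary (default all six).
#' @param kinetics,inhibition_mechanism conventions shared by the pool.
#' @param receptor_edge_filter drop models with no receptor output edge.
#' @return a list of `model_spec` objects.
#' @export
enumerate_models <- function(pairs = .species_pairs,
                             kinetics = "mass_action",
                             inhibition_mechanism = "blocking",
                             receptor_edge_filter = FALSE) {
  grids <- rep(list(.sign_levels), length(pairs))
  names(grids) <- pairs
  combos <- expand.grid(rev(grids), stringsAsFactors = FALSE)[, rev(seq_along(pairs)), drop = FALSE]
  names(combos) <- pairs
  pool <- lapply(seq_len(nrow(combos)), function(i) {
    model_spec(unlist(combos[i, , drop = FALSE]),
               kinetics = kinetics,
               inhibition_mechanism = inhibition_mechanism)
  })
  if (receptor_edge_filter) {
    pool <- Filter(function(mdl) {
      mdl$interactions[["R->E"]] != "none" ||
        mdl$interactions[["R->A"]] != "none"
    }, pool)
  }
  pool
}

#' Parameter-count identifiability filter
#'
#' Practical surrogate for a symbolic structural-identifiability analysis:
#' retains models whose parameter count `k` leaves the small-sample AIC
#' well defined (`n - k - 1 >= 1` for `n` data points), optionally also
#' requiring full numerical rank of the trajectory sensitivity matrix at a
#' reference parameter point. A user-supplied whitelist of model ids
#' reproduces any externally derived selection exactly.
#'
#' @param models list of `model_spec`.
#' @param data_shape integer vector `(n_timepoints, n_doses, n_observables)`.
#' @param whitelist optional character vector of [model_id()] strings;
#'   when given, exactly those models are retained, in input order.
#' @param sensitivity_screen logical; additionally require the numerical
#'   sensitivity matrix at the reference point (all parameters 1) to have
#'   rank `k`.
#' @param times,doses reference design for the sensitivity screen.
#' @return the filtered list of `model_spec`.
#' @export
identifiability_filter <- function(models, data_shape,
                                   whitelist = NULL,
                                   sensitivity_screen = FALSE,
                                   times = c(10, 30, 90),
                                   doses = c(1, 0.2)) {
  if (!is.null(whitelist)) {
    ids <- vapply(models, model_id, character(1L))
    return(models[ids %in% whitelist])
  }
  n <- prod(data_shape)
  keep <- vapply(models, function(mdl) {
    k <- length(model_parameters(mdl))
    n - k - 1 >= 1
  }, logical(1L))
  models <- models[keep]
  if (sensitivity_screen) {
    models <- Filter(function(mdl) {
      sensitivity_rank_full(mdl, times, doses)
    }, models)
  }
  models
}

#' @noRd
sensitivity_rank_full <- function(model, times, doses, h = 1e-4) {
  pn <- model_parameters(model)
  theta <- stats::setNames(rep(1, length(pn)), pn)
  base <- try(as.vector(simulate_model(model, theta, times, doses)$values),
              silent = TRUE)
  if (inherits(base, "try-error")) return(FALSE)
  J <- vapply(pn, function(p) {
    th <- theta; th[p] <- th[p] * (1 + h)
    up <- try(as.vector(simulate_model(model, th, times, doses)$values),
              silent = TRUE)
    if (inherits(up, "try-error")) return(rep(NA_real_, length(base)))
    (up - base) / (theta[p] * h)
  }, numeric(length(base)))
  if (anyNA(J)) return(FALSE)
  qr(J, tol = 1e-7)$rank == length(pn)
}

#' Simulate a crosstalk model
#'
#' Integrates the model from `t = 0` with the receptor set to the dose
#' scale (`R(0) = dose`, basal receptor decay `dR`) and returns the pERK
#' and pAKT levels at the requested times for every dose. Activation of a
#' target T by a source U follows `k * U * (T_tot - T)` (mass action) or
#' `V * U * (T_tot - T) / (K + T_tot - T)` (Michaelis-Menten), with the
#' phospho-protein totals fixed at 1 (normalized data) and the receptor
#' total at its dose scale. Blocking inhibition multiplies the activation
#' flux into the target by `1 / (1 + I / Ki)`; removal inhibition adds
#' `-kr * I * T`. Every species additionally decays at its basal rate.
#'
#' @param model a `model_spec`.
#' @param params named positive parameter vector covering
#'   [model_parameters()].
#' @param times strictly increasing positive observation times.
#' @param doses numeric dose scales (optionally named; names become dose
#'   labels).
#' @param init initial `c(E, A)` levels (default both 0).
#' @param rtol,atol integrator tolerances (stiff-capable `lsoda`).
#' @return an object of class `trajectory`: field `values` is an array of
#'   shape `(n_doses, n_times, 2)` (`pERK`, `pAKT`), plus `times`, `doses`.
#'   Integration failure or blow-up raises an error naming the parameter
#'   vector; callers treat it as infinite loss.
#' @export
simulate_model <- function(model, params, times, doses,
                           init = c(E = 0, A = 0),
                           rtol = 1e-8, atol = 1e-10) {
  if (any(diff(times) <= 0)) stop2("times must be strictly increasing")
  if (any(params <= 0)) stop2("parameters must be positive")
  pn <- model_parameters(model)
  miss <- setdiff(pn, names(params))
  if (length(miss)) stop2("missing parameter(s): ", paste(miss, collapse = ", "))
  p <- unname(params[pn])
  rhs <- build_rhs(model)
  dose_labels <- names(doses) %||% as.character(doses)
  nd <- length(doses)
  tgrid <- sort(unique(c(0, times)))
  # all doses integrated as one stacked (independent-copies) system
  y0 <- as.vector(rbind(as.numeric(doses), unname(init[1L]), unname(init[2L])))
  # capture.output: the Fortran integrator prints diagnostics on failure;
  # failures are converted to errors here, so the chatter is redundant
  chatter <- utils::capture.output(
    sol <- try(deSolve::ode(y = y0, times = tgrid, func = rhs,
                            parms = list(p = p, Rtot = as.numeric(doses),
                                         nd = nd),
                            method = "lsoda", rtol = rtol, atol = atol),
               silent = TRUE),
    type = "output")
  if (inherits(sol, "try-error") || nrow(sol) < length(tgrid) ||
      anyNA(sol) || any(!is.finite(sol))) {
    stop2("integration failed for parameters (",
          paste(sprintf("%s=%.3g", pn, p), collapse = ", "), ")")
  }
  sel <- match(times, sol[, 1L])
  out <- array(NA_real_, dim = c(nd, length(times), 2L),
               dimnames = list(dose_labels, as.character(times),
                               c("pERK", "pAKT")))
  for (di in seq_len(nd)) {
    E <- sol[sel, 1L + (di - 1L) * 3L + 2L]
    A <- sol[sel, 1L + (di - 1L) * 3L + 3L]
    if (any(c(E, A) < -1e-7)) {
      stop2("negative trajectory for parameters (",
            paste(sprintf("%s=%.3g", pn, p), collapse = ", "), ")")
    }
    out[di, , 1L] <- pmax(E, 0)
    out[di, , 2L] <- pmax(A, 0)
  }
  structure(list(values = out, times = times,
                 doses = stats::setNames(as.numeric(doses), dose_labels)),
            class = "trajectory")
}

# Compile the model structure into an ODE right-hand side closure. Edge
# terms are precompiled to integer indices into the canonical parameter
# vector so the inner function does no name lookups; the closure
# integrates independent copies of the system, one per dose, in a single
# stacked state vector (R1,E1,A1,R2,E2,A2,...). Compiled closures are
# cached per model structure.
#' @noRd
build_rhs <- function(model) {
  key <- model_id(model)
  cached <- .rhs_cache[[key]]
  if (!is.null(cached)) return(cached)
  pn <- model_parameters(model)
  pidx <- function(name) match(name, pn)
  sp <- c("R", "E", "A")
  struct <- lapply(sp, function(target) {
    act <- list(); blk <- list(); rem <- list()
    for (pair in .species_pairs) {
      uv <- strsplit(pair, "->", fixed = TRUE)[[1L]]
      if (uv[2L] != target) next
      sgn <- model$interactions[[pair]]
      if (sgn == "none") next
      u <- match(uv[1L], sp)
      tag <- paste(uv[1L], uv[2L], sep = "_")
      if (sgn == "activation") {
        act[[length(act) + 1L]] <- if (model$kinetics == "mass_action") {
          c(u, pidx(paste0("k_", tag)), NA_integer_)
        } else {
          c(u, pidx(paste0("V_", tag)), pidx(paste0("K_", tag)))
        }
      } else if (model$inhibition_mechanism == "blocking") {
        blk[[length(blk) + 1L]] <- c(u, pidx(paste0("Ki_", tag)))
      } else {
        rem[[length(rem) + 1L]] <- c(u, pidx(paste0("kr_", tag)))
      }
    }
    list(act = act, blk = blk, rem = rem, decay = pidx(paste0("d", target)))
  })
  mm <- model$kinetics == "michaelis_menten"
  fn <- function(t, y, parms) {
    p <- parms$p
    nd <- parms$nd
    dy <- numeric(3L * nd)
    for (di in seq_len(nd)) {
      off <- (di - 1L) * 3L
      tot1 <- parms$Rtot[di]
      for (s in 1:3) {
        st <- struct[[s]]
        ys <- y[off + s]
        free <- (if (s == 1L) tot1 else 1) - ys
        if (free < 0) free <- 0
        flux <- 0
        for (a in st$act) {
          flux <- flux + if (mm) {
            p[a[2L]] * y[off + a[1L]] * free / (p[a[3L]] + free)
          } else {
            p[a[2L]] * y[off + a[1L]] * free
          }
        }
        for (b in st$blk) {
          flux <- flux / (1 + y[off + b[1L]] / p[b[2L]])
        }
        loss <- 0
        for (r in st$rem) {
          loss <- loss + p[r[2L]] * y[off + r[1L]] * ys
        }
        dy[off + s] <- flux - loss - p[st$decay] * ys
      }
    }
    list(dy)
  }
  .rhs_cache[[key]] <- fn
  fn
}

.rhs_cache <- new.env(parent = emptyenv())

#' Serialize a model specification to JSON
#'
#' @param model a `model_spec`.
#' @return a JSON string; [model_from_json()] inverts it exactly.
#' @export
model_to_json <- function(model) {
  jsonlite::toJSON(list(interactions = as.list(model$interactions),
                        kinetics = model$kinetics,
                        inhibition_mechanism = model$inhibition_mechanism),
                   auto_unbox = TRUE)
}

#' @rdname model_to_json
#' @param json a JSON string produced by [model_to_json()].
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  model_spec(unlist(obj$interactions), kinetics = obj$kinetics,
             inhibition_mechanism = obj$inhibition_mechanism)
}

#' Write / read a model pool as JSON lines
#'
#' @param pool list of `model_spec`.
#' @param path file path.
#' @export
write_model_pool <- function(pool, path) {
  writeLines(vapply(pool, function(mdl) as.character(model_to_json(mdl)),
                    character(1L)), path)
  invisible(path)
}

#' @rdname write_model_pool
#' @export
read_model_pool <- function(path) {
  lapply(readLines(path), model_from_json)
}
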