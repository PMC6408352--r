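# End-to-end orchestration: load -> similarity -> cluster -> (fit) ->
# report, with a reproducibility manifest. Each stage error is re-raised
# with the stage name so failures are attributable.

#' @noRd
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop2("stage ", stage, ": ", conditionMessage(e))
  })
}

#' Run the full clustering (and optional model-identification) pipeline
#'
#' Stages: obtain a data tensor (from a long-format CSV or the synthetic
#' generator), flatten and normalize it, build the cosine similarity
#' matrix/tensor, find the optimal rectangular partition (either directly
#' by the similarity-driven integer program, or by refining a seed
#' clustering), and optionally fit and rank a crosstalk model pool on each
#' cluster's mean response. All outputs land in `config$out_dir` together
#' with a manifest (versions, seeds, solver certification, content hashes).
#' Re-running with the same config reproduces the deterministic outputs
#' bit-exactly.
#'
#' @param config a list (or path to a JSON file) with fields:
#'   `input` (path to a long CSV) or `synthetic`
#'   (`list(n1, n2, m, sigma, seed)`); `axes` (axis names, default the
#'   synthetic schema) and `value` column; `d` (experiment axes, default
#'   2); `normalization`; `pathway` (`"direct"` or `"refine"`); `lambda`
#'   (number, or `"auto"` for the planted-separation value when the truth
#'   is known); `seed_method` and `m` (refine pathway); `seed_partition`
#'   (CSV path overriding the built-in seed methods); `solver`
#'   (options passed to [solve_ip()]); `fit` (logical), `fit_pairs`,
#'   `fit_whitelist`, `fit_options`, `top`; `make_plot`; `out_dir`.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  out_dir <- config$out_dir %||% stop2("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("recticluster")),
                   r_version = R.version.string,
                   config = config, files = list(), warnings = character(0))
  truth <- NULL
  Z <- run_stage("load_long_table", {
    if (!is.null(config$synthetic)) {
      sy <- config$synthetic
      P0 <- sample_rectangular_partition(sy$n1, sy$n2, sy$m,
                                         seed = sy$seed %||% 0L)
      # the stage expression is evaluated lazily in this function's frame,
      # so plain assignment updates the local `truth`
      truth <- synthetic_truth(P0, noise_sigma = sy$sigma %||% 0,
                               seed = sy$seed %||% 0L)
      generate_dataset(truth)
    } else {
      if (is.null(config$input) || !file.exists(config$input)) {
        stop2("input file '", config$input %||% "<missing>", "' not found")
      }
      load_long_table(config$input,
                      axes = config$axes %||% c("cell_line", "ligand",
                                                "dose", "time", "protein"),
                      value = config$value %||% "value")
    }
  })
  d <- config$d %||% 2L
  S_mat <- run_stage("similarity", {
    M <- flatten_tensor(Z, d)
    M <- normalize_rows(M, config$normalization %||% "unit-l2")
    cosine_similarity(M)
  })
  sim_path <- file.path(out_dir, "similarity.csv")
  write_similarity_csv(S_mat, sim_path)
  pathway <- config$pathway %||% "direct"
  solver_opts <- config$solver %||% list()
  clus <- run_stage(pathway, {
    if (pathway == "direct") {
      S <- unflatten_similarity(S_mat)
      lambda <- config$lambda %||% 0.5
      if (identical(lambda, "auto")) {
        if (is.null(truth)) stop2("lambda = 'auto' needs synthetic truth")
        lambda <- separation_lambda(S_mat, truth$partition)$lambda
      }
      prog <- build_direct_program(S, lambda)
      res <- solve_ip(prog, solver_opts)
      list(partition = decode_direct(res, prog$grid_shape), result = res,
           lambda = lambda)
    } else if (pathway == "refine") {
      m <- config$m %||% stop2("config$m is required for the refine pathway")
      W <- if (!is.null(config$seed_partition)) {
        read_assignment_csv(config$seed_partition)$y
      } else {
        cluster_flat(S_mat, m,
                     method = config$seed_method %||% "agglomerative-average",
                     seed = config$seed %||% 0L)
      }
      prog <- build_refine_program(W)
      res <- solve_ip(prog, solver_opts)
      list(partition = decode_refine(res, prog$grid_shape, prog$m),
           result = res)
    } else {
      stop2("unknown pathway '", pathway, "'")
    }
  })
  P <- clus$partition
  P$row_labels <- Z$axes[[1L]]
  P$col_labels <- Z$axes[[2L]]
  part_json <- file.path(out_dir, "partition.json")
  part_csv <- file.path(out_dir, "partition.csv")
  write_partition_json(P, part_json)
  write_partition_csv(P, part_csv)
  manifest$solver <- list(status = clus$result$status,
                          objective = clus$result$objective_value,
                          gap = clus$result$gap,
                          certified = clus$result$status == "optimal",
                          log = clus$result$solver_log)
  if (!manifest$solver$certified) {
    manifest$warnings <- c(manifest$warnings,
                           "solver hit its limit; partition not certified optimal")
  }
  if (!is.null(truth)) {
    manifest$rand_index_vs_truth <- rand_index(P, truth$partition)
  }
  if (isTRUE(config$make_plot)) {
    plot_path <- file.path(out_dir, "partition.png")
    grDevices::png(plot_path, width = 640, height = 480)
    plot_partition(P)
    grDevices::dev.off()
    manifest$files$partition_plot <- "partition.png"
  }
  if (isTRUE(config$fit)) {
    rankings <- run_stage("fit", {
      pool <- if (!is.null(config$fit_whitelist)) {
        identifiability_filter(enumerate_models(), data_shape = c(0, 0, 0),
                               whitelist = config$fit_whitelist)
      } else {
        pool0 <- enumerate_models(pairs = config$fit_pairs %||% .species_pairs,
                                  receptor_edge_filter = TRUE)
        identifiability_filter(pool0, data_shape = dim(Z)[c(4L, 3L, 5L)])
      }
      lapply(seq_along(P$clusters), function(k) {
        resp <- mean_response(Z, P, k)
        fits <- lapply(pool, function(mdl) {
          fit_model(mdl, resp, options = config$fit_options %||% list())
        })
        rank_models(fits, top = config$top %||% 4L)
      })
    })
    rank_path <- file.path(out_dir, "model_ranking.json")
    jsonlite::write_json(lapply(rankings, function(r) r$table), rank_path,
                         dataframe = "rows", digits = NA, pretty = TRUE)
    manifest$files$model_ranking <- "model_ranking.json"
  }
  manifest$files$similarity <- "similarity.csv"
  manifest$files$partition_json <- "partition.json"
  manifest$files$partition_csv <- "partition.csv"
  hashed <- vapply(manifest$files, function(f) {
    unname(tools::md5sum(file.path(out_dir, f)))
  }, character(1L))
  manifest$hashes <- as.list(hashed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Plot a rectangular partition as a cluster-coloured grid
#'
#' @param P a `rect_partition`.
#' @param ... passed to [graphics::image()].
#' @export
plot_partition <- function(P, ...) {
  M <- partition_membership(P)
  n1 <- nrow(M); n2 <- ncol(M)
  cols <- grDevices::hcl.colors(max(M), "Set 3")
  graphics::image(seq_len(n2), seq_len(n1), t(M)[, n1:1, drop = FALSE],
                  col = cols, axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1L, at = seq_len(n2), labels = P$col_labels, las = 2,
                 cex.axis = 0.7)
  graphics::axis(2L, at = seq_len(n1), labels = rev(P$row_labels), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(P)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `recticluster` Rscript wrapper
#' (`inst/cli/recticluster.R`). Subcommands: `synth`, `seed`, `direct`,
#' `refine`, `fit`, `run`. Run with `--help` after a subcommand for its
#' options. Returns the exit code (0 only when every solver involved
#' certified optimality, unless `--allow-gap`).
#'
#' @param args character vector of command-line arguments (after the
#'   script name).
#' @return integer exit code, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    cat("usage: recticluster <synth|seed|direct|refine|fit|run> [options]\n")
    return(invisible(0L))
  }
  if (!requireNamespace("optparse", quietly = TRUE)) {
    stop2("the command-line interface needs the 'optparse' package")
  }
  sub <- args[1L]; rest <- args[-1L]
  o <- function(...) optparse::make_option(...)
  parse <- function(opts) {
    optparse::parse_args(optparse::OptionParser(option_list = opts),
                         args = rest)
  }
  code <- 0L
  if (sub == "synth") {
    op <- parse(list(
      o("--n1", type = "integer", default = 6L),
      o("--n2", type = "integer", default = 5L),
      o("--m", type = "integer", default = 3L),
      o("--sigma", type = "double", default = 0.05),
      o("--seed", type = "integer", default = 0L),
      o("--out", type = "character", default = "data.csv"),
      o("--truth", type = "character", default = "truth.json")))
    P <- sample_rectangular_partition(op$n1, op$n2, op$m, seed = op$seed)
    truth <- synthetic_truth(P, noise_sigma = op$sigma, seed = op$seed)
    Z <- generate_dataset(truth)
    df <- as.data.frame.table(Z$values, responseName = "value",
                              stringsAsFactors = FALSE)
    names(df) <- c(names(Z$axes), "value")
    utils::write.csv(df, op$out, row.names = FALSE)
    write_partition_json(P, op$truth)
    message("wrote ", op$out, " and ", op$truth)
  } else if (sub == "seed") {
    op <- parse(list(
      o("--similarity", type = "character"),
      o("--dims", type = "character"),
      o("--m", type = "integer"),
      o("--method", type = "character", default = "agglomerative-average"),
      o("--seed", type = "integer", default = 0L),
      o("--out", type = "character", default = "seed.csv")))
    dims <- as.integer(strsplit(op$dims, ",")[[1L]])
    S_mat <- read_similarity_csv(op$similarity, dims)
    W <- cluster_flat(S_mat, op$m, method = op$method, seed = op$seed)
    g <- rowmajor_grid(dims)
    memb <- apply(W, c(1L, 2L), which.max)
    df <- data.frame(row_label = paste0("r", g[, 1L]),
                     col_label = paste0("c", g[, 2L]),
                     cluster_id = memb[g])
    utils::write.csv(df, op$out, row.names = FALSE)
    message("wrote ", op$out)
  } else if (sub %in% c("direct", "refine", "fit", "run")) {
    op <- parse(list(
      o("--config", type = "character", default = NULL),
      o("--data", type = "character", default = NULL),
      o("--dims", type = "character", default = NULL),
      o("--lam", type = "double", default = 0.5),
      o("--m", type = "integer", default = 3L),
      o("--init", type = "character", default = NULL),
      o("--seed", type = "integer", default = 0L),
      o("--time-limit", type = "double", default = Inf),
      o("--allow-gap", action = "store_true", default = FALSE),
      o("--out", type = "character", default = "run_out")))
    config <- if (!is.null(op$config)) {
      jsonlite::fromJSON(op$config, simplifyVector = TRUE)
    } else {
      list()
    }
    if (!is.null(op$data)) config$input <- op$data
    config$pathway <- if (sub == "run") config$pathway %||% "direct" else
      if (sub == "fit") config$pathway %||% "direct" else sub
    if (sub == "fit") config$fit <- TRUE
    config$lambda <- config$lambda %||% op$lam
    config$m <- config$m %||% op$m
    if (!is.null(op$init)) config$seed_partition <- op$init
    config$seed <- config$seed %||% op$seed
    config$solver <- config$solver %||%
      list(time_limit = op[["time-limit"]], seed = op$seed)
    config$out_dir <- config$out_dir %||% op$out
    manifest <- run_pipeline(config)
    if (!manifest$solver$certified && !op[["allow-gap"]]) code <- 1L
  } else {
    message("unknown subcommand '", sub, "'")
    code <- 2L
  }
  invisible(code)
}
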