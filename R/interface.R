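#' Apply an ablation variant to a configuration
#'
#' The named variants switch off exactly one modelling component:
#' `"no-grn"` disables the prior gene mask, `"no-iterate"` caps the outer
#' loop at one iteration, `"shared-gnn"` shares GNN parameters across
#' views, `"per-view-decoder"` gives each view its own decoder. `"full"` (or
#' `NULL`) returns the configuration unchanged.
#'
#' @param config a [run_config()].
#' @param variant variant name.
#' @return Modified `run_config`.
#' @export
ablation_config <- function(config,
                            variant = c("full", "no-grn", "no-iterate",
                                        "shared-gnn", "per-view-decoder")) {
  if (is.null(variant)) return(config)
  variant <- match.arg(variant)
  switch(variant,
         "full" = config,
         "no-grn" = { config$use_prior_mask <- FALSE; config },
         "no-iterate" = { config$max_iterations <- 1L; config },
         "shared-gnn" = { config$share_gnn_across_views <- TRUE; config },
         "per-view-decoder" = { config$per_view_decoder <- TRUE; config })
}

#' Build a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; unknown keys are rejected.
#'
#' @param path YAML file.
#' @param base configuration the file overrides.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, base = run_config()) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(base))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  base[names(vals)] <- vals
  args <- base[c("theta", "k", "alpha", "max_iterations", "hops",
                 "expression_eps")]
  mc <- base[c("d", "L", "gnn_arch", "learning_rate", "max_epochs",
               "patience", "min_delta", "min_delta_regulatory",
               "share_gnn_across_views", "per_view_decoder",
               "use_prior_mask", "seed")]
  do.call(run_config, c(args, mc))
}

#' Read a simulated-dataset file set
#'
#' Inverse of [write_simulated_dataset()]; the `dense/` matrix, `truth.csv`
#' and `zones.csv` are attached when present.
#'
#' @param dir dataset directory.
#' @return A `simulated_dataset`-like list (`data`, `lr`, `prior`, and when
#'   available `dense`, `truth`, `zones`).
#' @export
read_simulated_dataset <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing file: ", p)
    p
  }
  data <- read_spatial_dataset(need("matrix.mtx"), need("coords.csv"),
                               need("cell_types.csv"),
                               genes_path = need("genes.txt"),
                               cells_path = need("cells.txt"))
  out <- list(data = data, lr = read_lr_table(need("lr_table.csv")))
  out$prior <- if (file.exists(file.path(dir, "prior.csv")))
    read_prior_network(file.path(dir, "prior.csv")) else NULL
  if (file.exists(file.path(dir, "dense", "matrix.mtx")))
    out$dense <- read_spatial_dataset(
      file.path(dir, "dense", "matrix.mtx"),
      file.path(dir, "dense", "coords.csv"),
      file.path(dir, "dense", "cell_types.csv"),
      genes_path = file.path(dir, "dense", "genes.txt"),
      cells_path = file.path(dir, "dense", "cells.txt"))
  if (file.exists(file.path(dir, "truth.csv")))
    out$truth <- utils::read.csv(file.path(dir, "truth.csv"),
                                 stringsAsFactors = FALSE)
  if (file.exists(file.path(dir, "zones.csv")))
    out$zones <- utils::read.csv(file.path(dir, "zones.csv"),
                                 stringsAsFactors = FALSE)
  class(out) <- "simulated_dataset"
  out
}

manifest <- function(dir, what) {
  files <- sort(list.files(dir, recursive = TRUE))
  writeLines(c(paste0("# ", what), files), file.path(dir, "MANIFEST"))
  message(what, ": ", length(files), " file(s) under ", dir)
  invisible(files)
}

#' Generate and write a simulated dataset (command entry point)
#'
#' @param out_dir output directory.
#' @param setting preset id 1..9 (see [simulation_setting()]); `NULL` uses
#'   explicit parameters in `...`.
#' @param seed generator seed.
#' @param ... overrides passed to the simulation configuration.
#' @return File manifest, invisibly.
#' @export
cmd_simulate <- function(out_dir, setting = 1, seed = 1, ...) {
  config <- if (is.null(setting)) simulation_config(seed = seed, ...)
            else simulation_setting(setting, seed = seed, ...)
  dataset <- simulate_dataset(config)
  write_simulated_dataset(dataset, out_dir)
  yaml::write_yaml(unclass(config), file.path(out_dir, "sim_config.yaml"))
  manifest(out_dir, "simulated dataset")
}

#' Run the full pipeline on an input file set (command entry point)
#'
#' Reads the dataset under `input_dir`, executes the iterative pipeline and
#' writes: the imputed matrix and baseline (`imputed.csv`,
#' `baseline.csv`), the per-view micro-environment components as a long
#' table (`components.csv`, entries above `component_min` only), the
#' iteration history, and the top-`K` regulatory rankings per (cell, gene)
#' (`rankings.csv`).
#'
#' @param input_dir dataset directory ([cmd_simulate()] layout).
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @param ablation optional variant name (see [ablation_config()]).
#' @param config_yaml optional YAML overriding `config`.
#' @param K rankings cut-off.
#' @param component_min smallest component entry worth writing.
#' @return File manifest, invisibly.
#' @export
cmd_run <- function(input_dir, out_dir, config = run_config(),
                    ablation = NULL, config_yaml = NULL, K = 5,
                    component_min = 1e-3) {
  if (!is.null(config_yaml)) config <- read_run_config(config_yaml, config)
  if (!is.null(ablation)) config <- ablation_config(config, ablation)
  ds <- read_simulated_dataset(input_dir)
  run <- run_pipeline(ds$data, ds$lr, ds$prior, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run$result

  wmat <- function(M, f) {
    utils::write.csv(data.frame(cell_id = rownames(M),
                                as.data.frame(M), check.names = FALSE),
                     file.path(out_dir, f), row.names = FALSE, quote = FALSE)
  }
  wmat(res$X_hat, "imputed.csv")
  wmat(res$X_hat_b, "baseline.csv")
  comp <- do.call(rbind, lapply(names(res$components), function(id) {
    M <- res$components[[id]]
    hit <- which(M > component_min, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    data.frame(lr_id = id, cell_id = rownames(M)[hit[, 1]],
               gene = colnames(M)[hit[, 2]], value = M[hit],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(comp, file.path(out_dir, "components.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(run$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(res$training_log, file.path(out_dir, "training_log.csv"),
                   row.names = FALSE, quote = FALSE)

  combos <- expand.grid(cell = rownames(res$X_hat),
                        gene = colnames(res$X_hat),
                        stringsAsFactors = FALSE)
  rt <- ranking_table(res, combos)
  rt <- rt[rt$rank <= K, ]
  utils::write.csv(rt, file.path(out_dir, "rankings.csv"),
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "run_config.yaml"))
  message("converged: ", run$converged, "; iterations: ",
          nrow(run$history), "; final views: ",
          utils::tail(run$history$n_views, 1))
  manifest(out_dir, "pipeline run")
}

#' Benchmark against simulation ground truth (command entry point)
#'
#' @param input_dir dataset directory; must contain `truth.csv` (only
#'   simulated data carries planted ground truth).
#' @param out_dir output directory for `report.csv` and `summary.csv`.
#' @param config a [run_config()].
#' @param replicates hold-out replicates.
#' @param K precision cut-off.
#' @param seed split seed.
#' @return The summary data frame, invisibly.
#' @export
cmd_evaluate <- function(input_dir, out_dir, config = run_config(),
                         replicates = 2, K = 5, seed = 1) {
  ds <- read_simulated_dataset(input_dir)
  if (is.null(ds$truth))
    stop("missing ", file.path(input_dir, "truth.csv"),
         ": ranking ground truth exists only for simulated datasets ",
         "(see cmd_simulate)")
  bench <- benchmark_run(ds, config, n_replicates = replicates, K = K,
                         seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bench$report, file.path(out_dir, "report.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bench$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest(out_dir, "evaluation")
  invisible(bench$summary)
}

#' Ablation sweep (command entry point)
#'
#' Runs the pipeline once per variant and seed on one dataset and collects
#' the regulatory-recovery metrics (plus held-out imputation RMSE when a
#' split is used) into a single table.
#'
#' @param dataset a `simulated_dataset` (or directory path).
#' @param config base [run_config()].
#' @param variants variant names.
#' @param seeds integer vector of model seeds.
#' @param K precision cut-off.
#' @param with_holdout also compute held-out imputation RMSE per run.
#' @return Data frame: variant, seed, metric, value.
#' @export
ablation_sweep <- function(dataset, config = run_config(),
                           variants = c("full", "no-grn", "no-iterate",
                                        "shared-gnn", "per-view-decoder"),
                           seeds = 1:5, K = 5, with_holdout = FALSE) {
  if (is.character(dataset)) dataset <- read_simulated_dataset(dataset)
  rows <- list()
  for (variant in variants) {
    for (seed in seeds) {
      cfg <- ablation_config(config, variant)
      cfg$seed <- as.integer(seed)
      if (with_holdout) {
        split <- make_splits(dataset$data$X, 1, seed = seed)[[1]]
        X_in <- as.matrix(dataset$data$X)
        X_in[split$test] <- 0
        data_in <- spatial_expression(X_in, dataset$data$coords,
                                      dataset$data$cell_types)
        run <- run_pipeline(data_in, dataset$lr, dataset$prior, cfg,
                            split = split[c("train", "val")])
        imp <- imputation_metrics(run$result$X_hat, dataset$data$X,
                                  split$test)
      } else {
        run <- run_pipeline(dataset$data, dataset$lr, dataset$prior, cfg)
        imp <- NULL
      }
      sc <- score_regulatory_recovery(run$result, dataset, K = K)
      metrics <- c(sc[1:4], list(n_views = length(run$result$views_used)),
                   if (!is.null(imp)) imp)
      rows[[length(rows) + 1]] <- data.frame(
        variant = variant, seed = seed, metric = names(metrics),
        value = unname(unlist(metrics)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
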