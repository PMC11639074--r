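#' Hold-out splits over observed entries
#'
#' Partitions the non-zero entries of the observed matrix into train /
#' validation / test sets, with 10% of non-zero entries (to the nearest
#' entry) each for validation and testing. Splits are independent across
#' replicates and reproducible from the seed.
#'
#' @param X observed matrix (dense or sparse).
#' @param n_replicates number of independent splits.
#' @param seed integer seed.
#' @param frac_val,frac_test held-out fractions (default 0.1 each).
#' @return List of length `n_replicates`; each element has integer vectors
#'   `train`, `val`, `test` of linear indices plus `replicate` and `seed`.
#' @export
make_splits <- function(X, n_replicates = 10, seed = 1,
                        frac_val = 0.1, frac_test = 0.1) {
  X <- as.matrix(X)
  nz <- which(X != 0)
  n_test <- round(frac_test * length(nz))
  n_val <- round(frac_val * length(nz))
  if (n_test < 1 || n_val < 1 || n_test + n_val >= length(nz))
    stop("too few non-zero entries (", length(nz),
         ") for a ", frac_val, "/", frac_test, " validation/test split")
  set.seed(seed)
  lapply(seq_len(n_replicates), function(rep) {
    test <- sample(nz, n_test)
    rest <- setdiff(nz, test)
    val <- sample(rest, n_val)
    list(train = setdiff(rest, val), val = val, test = test,
         replicate = rep, seed = seed)
  })
}

#' Imputation accuracy on an index set
#'
#' Mean absolute error, root-mean-square error and cosine similarity
#' between predicted and true values at the given entries (a single global
#' cosine over the held-out vector, not per-cell).
#'
#' @param X_hat,X_truth equally shaped matrices.
#' @param idx non-empty vector of linear indices.
#' @return Named list `l1`, `rmse`, `cosine`.
#' @export
imputation_metrics <- function(X_hat, X_truth, idx) {
  stopifnot(length(idx) > 0)
  a <- as.matrix(X_hat)[idx]
  b <- as.matrix(X_truth)[idx]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity undefined: zero-norm value vector")
  list(l1 = mean(abs(a - b)),
       rmse = sqrt(mean((a - b)^2)),
       cosine = sum(a * b) / (na * nb))
}

#' Ranking quality against binary relevance
#'
#' Precision at K, NDCG (binary gains, `1/log2(rank + 1)` discount over the
#' full list, normalised by the ideal ordering), and Spearman / Kendall
#' correlation between the scores and the 0/1 relevance vector (standard
#' tie-corrected formulas; `NA` when either vector is constant).
#'
#' @param ranking a `regulatory_ranking` or data frame with columns
#'   `lr_id` (rank order) and `psi`.
#' @param relevant character vector of relevant pair ids; must be covered
#'   by the ranking.
#' @param K cut-off for precision (default 5).
#' @return Named list `precision`, `ndcg`, `spearman`, `kendall`.
#' @export
ranking_metrics <- function(ranking, relevant, K = 5) {
  stopifnot(K >= 1)
  relevant <- intersect(relevant, ranking$lr_id)
  if (length(relevant) == 0)
    stop("ranking metrics undefined: no relevant item in the ranking")
  rel <- as.numeric(ranking$lr_id %in% relevant)
  n <- length(rel)
  disc <- 1 / log2(seq_len(n) + 1)
  ndcg <- sum(rel * disc) / sum(disc[seq_len(sum(rel))])
  kk <- min(K, n)
  list(precision = sum(rel[seq_len(kk)]) / K,
       ndcg = ndcg,
       spearman = suppressWarnings(
         stats::cor(ranking$psi, rel, method = "spearman")),
       kendall = suppressWarnings(
         stats::cor(ranking$psi, rel, method = "kendall")))
}

# unique evaluated (cell, gene) combinations with their relevant pair sets
truth_relevance <- function(truth) {
  key <- paste(truth$cell_id, truth$gene, sep = "\r")
  split_ids <- split(truth$lr_id, key)
  keys <- strsplit(names(split_ids), "\r", fixed = TRUE)
  data.frame(cell_id = vapply(keys, `[`, "", 1),
             gene = vapply(keys, `[`, "", 2),
             relevant = I(unname(split_ids)),
             stringsAsFactors = FALSE)
}

# psi over a fixed pair universe; pairs outside the trained view set
# contribute zero (they received no micro-environment component)
extended_ranking <- function(result, universe, cell, gene) {
  psi <- stats::setNames(rep(0, length(universe)), universe)
  used <- intersect(universe, result$views_used)
  psi[used] <- vapply(used, function(id)
    result$components[[id]][cell, gene], numeric(1))
  ord <- order(-psi, universe)
  data.frame(lr_id = universe[ord], psi = unname(psi[ord]),
             stringsAsFactors = FALSE)
}

#' Score a trained run against simulation ground truth
#'
#' Evaluates every (cell, gene) combination with planted regulators: ranks
#' the full pair universe by regulatory score (pairs never activated score
#' zero) and averages the four ranking metrics over combinations
#' (correlations with `na.rm`).
#'
#' @param result an `imputation_result`.
#' @param dataset a `simulated_dataset`.
#' @param K precision cut-off.
#' @return Named list of mean `precision`, `ndcg`, `spearman`, `kendall`
#'   and `n_pairs_evaluated`.
#' @export
score_regulatory_recovery <- function(result, dataset, K = 5) {
  universe <- sort(names(dataset$lr))
  combos <- truth_relevance(dataset$truth)
  vals <- lapply(seq_len(nrow(combos)), function(i) {
    rk <- extended_ranking(result, universe, combos$cell_id[i],
                           combos$gene[i])
    ranking_metrics(rk, combos$relevant[[i]], K = K)
  })
  agg <- function(f) mean(vapply(vals, function(v) v[[f]], numeric(1)),
                          na.rm = TRUE)
  list(precision = agg("precision"), ndcg = agg("ndcg"),
       spearman = agg("spearman"), kendall = agg("kendall"),
       n_pairs_evaluated = nrow(combos))
}

#' Random-guess ranking baseline
#'
#' Same evaluation as [score_regulatory_recovery()] with each ranking
#' replaced by a uniformly random permutation of the pair universe.
#'
#' @param dataset a `simulated_dataset`.
#' @param K precision cut-off.
#' @param seed seed for the permutations.
#' @return Same shape as [score_regulatory_recovery()].
#' @export
score_random_baseline <- function(dataset, K = 5, seed = 1) {
  set.seed(seed)
  universe <- sort(names(dataset$lr))
  combos <- truth_relevance(dataset$truth)
  vals <- lapply(seq_len(nrow(combos)), function(i) {
    ids <- sample(universe)
    rk <- data.frame(lr_id = ids,
                     psi = seq(length(ids), 1), stringsAsFactors = FALSE)
    ranking_metrics(rk, combos$relevant[[i]], K = K)
  })
  agg <- function(f) mean(vapply(vals, function(v) v[[f]], numeric(1)),
                          na.rm = TRUE)
  list(precision = agg("precision"), ndcg = agg("ndcg"),
       spearman = agg("spearman"), kendall = agg("kendall"),
       n_pairs_evaluated = nrow(combos))
}

#' Benchmark the pipeline on a simulated dataset
#'
#' For each hold-out replicate: trains the full iterative pipeline with the
#' replicate's train/validation entries, measures imputation accuracy on
#' the held-out test entries (held-out observed values as ground truth, as
#' in down-sampling benchmarks), and measures regulatory-ranking quality
#' against the planted truth, alongside a random-permutation baseline.
#'
#' @param dataset a `simulated_dataset`.
#' @param config a [run_config()].
#' @param n_replicates number of hold-out replicates.
#' @param K precision cut-off.
#' @param seed split seed.
#' @return List with `report` (long data frame: replicate, arm, metric,
#'   value) and `summary` (arm, metric, mean, sd).
#' @export
benchmark_run <- function(dataset, config = run_config(),
                          n_replicates = 2, K = 5, seed = 1) {
  splits <- make_splits(dataset$data$X, n_replicates, seed = seed)
  rows <- list()
  add <- function(rep, arm, metrics) {
    rows[[length(rows) + 1]] <<- data.frame(
      replicate = rep, arm = arm, metric = names(metrics),
      value = unname(unlist(metrics)), stringsAsFactors = FALSE)
  }
  for (s in splits) {
    cfg <- config
    cfg$seed <- as.integer(config$seed + s$replicate - 1L)
    # test entries are hidden from the pipeline entirely (graph construction
    # included); validation entries stay visible but are excluded from the
    # training loss and drive early stopping
    X_in <- as.matrix(dataset$data$X)
    X_in[s$test] <- 0
    data_in <- spatial_expression(X_in, dataset$data$coords,
                                  dataset$data$cell_types)
    run <- run_pipeline(data_in, dataset$lr, dataset$prior, cfg,
                        split = s[c("train", "val")])
    imp <- imputation_metrics(run$result$X_hat, dataset$data$X, s$test)
    rnk <- score_regulatory_recovery(run$result, dataset, K = K)
    add(s$replicate, "model", c(imp, rnk[1:4]))
    rnd <- score_random_baseline(dataset, K = K, seed = seed + s$replicate)
    add(s$replicate, "random", rnd[1:4])
  }
  report <- do.call(rbind, rows)
  summary <- stats::aggregate(value ~ arm + metric, data = report,
                              FUN = function(v) c(mean = mean(v),
                                                  sd = stats::sd(v)))
  summary <- data.frame(arm = summary$arm, metric = summary$metric,
                        mean = summary$value[, "mean"],
                        sd = summary$value[, "sd"])
  list(report = report, summary = summary)
}
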