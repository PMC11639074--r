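#' Re-screen LR pairs against an imputed matrix
#'
#' Recomputes the expressed fractions from the imputed matrix `X_hat`
#' (not the observations) and applies the same strict threshold used for
#' the initial screen. Because a continuous decoder rarely emits exact
#' zeros, a cell counts as expressing when its level exceeds
#' `expression_eps`.
#'
#' @param X_hat imputed n x m matrix (dimnames give cell ids/gene names).
#' @param lr an `lr_table` (pairs with absent genes are dropped with a
#'   warning).
#' @param theta expression-fraction threshold.
#' @param expression_eps positivity tolerance for imputed values
#'   (default 1e-6).
#' @return Character vector of active pair ids.
#' @export
update_lr_set <- function(X_hat, lr, theta = 0.15, expression_eps = 1e-6) {
  gene_names <- colnames(X_hat)
  pseudo <- list(X = X_hat, gene_names = gene_names)
  lr <- match_lr_table(lr, gene_names)
  summaries <- lapply(lr, function(p)
    summarize_lr_expression(pseudo, p, positive_tol = expression_eps))
  filter_expressed_pairs(summaries, theta)
}

#' Blend two generations of a communication view
#'
#' Edgewise convex combination `alpha * old + (1 - alpha) * new`; an edge
#' present in only one operand is blended against weight zero. The blend is
#' then re-sparsified to `k` outgoing edges per sender (nearest neighbours
#' by `D`) so graph density stays bounded across iterations; with the
#' distance-based neighbour rule both operands live on the same support, so
#' this is a safeguard rather than a pruning step. Blending a view with
#' itself returns the view unchanged (fixed point).
#'
#' @param old_view,new_view `ccc_view` objects for the same pair over the
#'   same cells.
#' @param alpha blending coefficient in \[0, 1\]; `alpha = 1` keeps the old
#'   view, `alpha = 0` adopts the new one.
#' @param D distance matrix (for re-sparsification); `NULL` to skip.
#' @param k neighbours per sender.
#' @return A `ccc_view`.
#' @export
blend_view <- function(old_view, new_view, alpha = 0.2, D = NULL, k = NULL) {
  stopifnot(identical(old_view$lr_id, new_view$lr_id),
            all(dim(old_view$edges) == dim(new_view$edges)),
            alpha >= 0, alpha <= 1)
  edges <- alpha * old_view$edges + (1 - alpha) * new_view$edges
  edges <- Matrix::drop0(edges)
  if (!is.null(D) && !is.null(k)) {
    n <- nrow(D)
    nn <- knn_index(D, k)
    keep <- Matrix::sparseMatrix(i = rep(seq_len(n), each = ncol(nn)),
                                 j = as.vector(t(nn)), x = 1,
                                 dims = c(n, n))
    edges <- Matrix::drop0(edges * keep)
  }
  structure(list(lr_id = old_view$lr_id, edges = edges), class = "ccc_view")
}

#' One refinement step of the communication network
#'
#' Re-screens LR pairs from the current imputation, builds fresh views
#' (from `X_hat`) for newly activated pairs, blends the views of pairs
#' active in both generations, retains unchanged any view whose pair fell
#' back below threshold (the active set never shrinks), and retrains with
#' warm-started model parameters. When no new pair activates the state is
#' returned with `converged = TRUE` and no retraining.
#'
#' @param state list with `iteration`, `multiview`, `result`, `history`.
#' @param data a [spatial_expression()].
#' @param lr an `lr_table`.
#' @param prior a [prior_network()] or `NULL`.
#' @param config a [run_config()].
#' @param split optional train/val split passed to [train_imputation()].
#' @return Updated state; `converged` flag set when no view was added.
#' @export
refine <- function(state, data, lr, prior, config, split = NULL) {
  mv <- state$multiview
  X_hat <- state$result$X_hat
  new_ids <- update_lr_set(X_hat, lr, theta = config$theta,
                           expression_eps = config$expression_eps)
  old_ids <- names(mv$views)
  added <- setdiff(new_ids, old_ids)
  if (length(added) == 0) {
    state$converged <- TRUE
    return(state)
  }

  imputed <- list(X = X_hat, gene_names = colnames(X_hat))
  lr_panel <- match_lr_table(lr, colnames(X_hat))
  summaries <- lapply(lr_panel[intersect(union(new_ids, old_ids),
                                         names(lr_panel))],
                      function(p) summarize_lr_expression(
                        imputed, p, positive_tol = config$expression_eps))

  views <- mv$views
  for (id in intersect(old_ids, new_ids)) {
    fresh <- build_ccc_view(summaries[[id]], mv$D, mv$k)
    views[[id]] <- blend_view(views[[id]], fresh, alpha = config$alpha,
                              D = mv$D, k = mv$k)
  }
  for (id in added)
    views[[id]] <- build_ccc_view(summaries[[id]], mv$D, mv$k)
  views <- views[sort(names(views))]
  mv$views <- views

  iter <- state$iteration + 1L
  model_cfg <- as_model_config(config)
  masks <- derive_gene_masks(if (model_cfg$use_prior_mask) prior else NULL,
                             lr, names(views), data$gene_names,
                             hops = config$hops)
  result <- train_imputation(data, mv, masks, model_cfg,
                             params = state$result$params, split = split,
                             init_seed = config$seed + iter)
  history <- rbind(state$history,
                   data.frame(iteration = iter, n_views = length(views),
                              n_new_views = length(added),
                              train_loss = utils::tail(
                                result$training_log$train_loss, 1)))
  list(iteration = iter, multiview = mv, result = result,
       history = history, converged = FALSE)
}

#' Full pipeline configuration
#'
#' [model_config()] hyperparameters plus the outer-loop controls: the
#' activity threshold `theta` (0.15), neighbour count `k` (5), blending
#' coefficient `alpha` (0.2), prior-mask reach `hops` (2), maximum outer
#' iterations (10) and the positivity tolerance for imputed values.
#'
#' @param theta expression-fraction threshold in (0, 1).
#' @param k neighbours per sender for graph construction.
#' @param alpha blending coefficient in \[0, 1\].
#' @param max_iterations outer-loop safety cap.
#' @param hops prior-network reach for gene masks.
#' @param expression_eps positivity tolerance for imputed expression.
#' @param ... passed to [model_config()].
#' @return A list of class `run_config` (also a valid `model_config`
#'   carrier via [as_model_config()]).
#' @export
run_config <- function(theta = 0.15, k = 5, alpha = 0.2,
                       max_iterations = 10, hops = 2,
                       expression_eps = 1e-6, ...) {
  stopifnot(theta > 0, theta < 1, k >= 1, alpha >= 0, alpha <= 1,
            max_iterations >= 1, hops >= 1)
  mc <- model_config(...)
  structure(c(list(theta = theta, k = as.integer(k), alpha = alpha,
                   max_iterations = as.integer(max_iterations),
                   hops = as.integer(hops),
                   expression_eps = expression_eps),
              unclass(mc)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
as_model_config <- function(config) {
  do.call(model_config,
          config[c("d", "L", "gnn_arch", "learning_rate", "max_epochs",
                   "patience", "min_delta", "min_delta_regulatory",
                   "share_gnn_across_views", "per_view_decoder",
                   "use_prior_mask", "seed")])
}

#' Run the full iterative pipeline
#'
#' Builds the initial communication network from the observed matrix,
#' trains the imputation model, then alternates re-screening LR pairs from
#' the imputation with retraining until no new view can be added (or
#' `max_iterations` is reached).
#'
#' @param data a [spatial_expression()].
#' @param lr an `lr_table`.
#' @param prior a [prior_network()] or `NULL` (equivalent to
#'   `use_prior_mask = FALSE`).
#' @param config a [run_config()].
#' @param split optional train/val entry split (linear indices), used for
#'   both training and early stopping.
#' @return List with `result` (final `imputation_result`), `multiview`
#'   (final `multiview_ccc`), `history` (one row per iteration: iteration,
#'   n_views, n_new_views, train_loss) and `converged`.
#' @export
run_pipeline <- function(data, lr, prior = NULL, config = run_config(),
                         split = NULL) {
  model_cfg <- as_model_config(config)
  mv <- assemble_multiview(data, lr, theta = config$theta, k = config$k)
  masks <- derive_gene_masks(if (model_cfg$use_prior_mask) prior else NULL,
                             lr, names(mv$views), data$gene_names,
                             hops = config$hops)
  result <- train_imputation(data, mv, masks, model_cfg, split = split)
  state <- list(
    iteration = 0L, multiview = mv, result = result,
    history = data.frame(iteration = 0L, n_views = length(mv$views),
                         n_new_views = length(mv$views),
                         train_loss = utils::tail(
                           result$training_log$train_loss, 1)),
    converged = FALSE)
  while (!state$converged && state$iteration < config$max_iterations - 1L) {
    state <- refine(state, data, lr, prior, config, split = split)
  }
  if (!state$converged) {
    # distinguish "cap reached" from "no new views": one more screen
    probe <- update_lr_set(state$result$X_hat, lr, theta = config$theta,
                           expression_eps = config$expression_eps)
    state$converged <- length(setdiff(probe, names(state$multiview$views))) == 0
  }
  list(result = state$result, multiview = state$multiview,
       history = state$history, converged = state$converged)
}
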