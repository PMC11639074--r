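#' Model configuration
#'
#' Hyperparameters of the imputation model. Defaults: hidden dimension 32,
#' two message-passing layers, graph-transformer aggregation, Adam with
#' learning rate 0.01, at most 1000 epochs, early stopping after 10 epochs
#' without improvement. For imputation any strict decrease of the monitored
#' loss resets the patience counter (`min_delta = 0`); for regulatory-score
#' training a decrease must exceed `min_delta_regulatory` (0.001).
#'
#' @param d embedding dimension (>= 1).
#' @param L number of message-passing layers (>= 1).
#' @param gnn_arch aggregation architecture: `"graph_transformer"` (default),
#'   `"gcn"`, `"gat"` or `"graphsage"`. Edge weights act as the
#'   attention/aggregation weights of the named architecture.
#' @param learning_rate Adam step size (> 0).
#' @param max_epochs maximum training epochs per outer iteration.
#' @param patience epochs without improvement before stopping.
#' @param min_delta minimum decrease counting as improvement.
#' @param min_delta_regulatory the `min_delta` used for regulatory-score
#'   training.
#' @param share_gnn_across_views use one set of GNN parameters for all
#'   views (ablation variant) instead of per-view parameters.
#' @param per_view_decoder use a separate decoder per view (ablation
#'   variant) instead of a shared one.
#' @param use_prior_mask apply the GRN/PPI-derived gene masks.
#' @param seed integer seed controlling parameter initialisation.
#' @return A list of class `model_config`.
#' @export
model_config <- function(d = 32, L = 2,
                         gnn_arch = c("graph_transformer", "gcn", "gat",
                                      "graphsage"),
                         learning_rate = 0.01, max_epochs = 1000,
                         patience = 10, min_delta = 0,
                         min_delta_regulatory = 0.001,
                         share_gnn_across_views = FALSE,
                         per_view_decoder = FALSE,
                         use_prior_mask = TRUE, seed = 1) {
  gnn_arch <- match.arg(gnn_arch)
  stopifnot(d >= 1, L >= 1, learning_rate > 0, max_epochs >= 1,
            patience >= 1)
  structure(list(d = as.integer(d), L = as.integer(L), gnn_arch = gnn_arch,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_delta = min_delta,
                 min_delta_regulatory = min_delta_regulatory,
                 share_gnn_across_views = isTRUE(share_gnn_across_views),
                 per_view_decoder = isTRUE(per_view_decoder),
                 use_prior_mask = isTRUE(use_prior_mask),
                 seed = as.integer(seed)),
            class = "model_config")
}

# ---- numerics ----------------------------------------------------------

softplus <- function(z) {
  out <- z
  small <- z < 30
  out[small] <- log1p(exp(z[small]))
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))

relu <- function(z) {
  z[z < 0] <- 0
  z
}

# add a bias row-vector to every row (column-major; faster than sweep)
add_bias <- function(M, b) M + rep(b, each = nrow(M))

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

# ---- aggregation operators --------------------------------------------

# S is the linear neighbour-aggregation operator of one view: row i of
# S %*% H is the weighted combination of sender embeddings feeding cell i.
# use_root: whether the layer adds a separate learned self/root term.
build_aggregator <- function(view, arch) {
  In <- Matrix::t(view$edges)          # row = receiver, col = sender
  n <- nrow(In)
  row_normalize <- function(A) {
    rs <- Matrix::rowSums(A)
    rs[rs == 0] <- 1
    Matrix::Diagonal(x = 1 / rs) %*% A
  }
  finish <- function(S, use_root) {
    S <- methods::as(S, "CsparseMatrix")
    list(S = S, St = Matrix::t(S), use_root = use_root)
  }
  if (arch %in% c("graph_transformer", "graphsage")) {
    # edge weights as (pre-normalised) attention over incoming edges;
    # a learned root-weight term carries the cell's own features.
    finish(row_normalize(In), TRUE)
  } else if (arch == "gat") {
    # self-loop enters the attention with weight max(incoming), so isolated
    # cells fall back to their own features.
    e <- Matrix::summary(In)
    selfw <- rep(1, n)
    if (nrow(e) > 0) {
      mx <- tapply(e$x, e$i, max)
      selfw[as.integer(names(mx))] <- pmax(mx, 1e-12)
    }
    A <- In + Matrix::Diagonal(x = selfw)
    finish(row_normalize(A), FALSE)
  } else { # gcn
    A <- In + Matrix::Diagonal(n)
    dr <- 1 / sqrt(Matrix::rowSums(A))
    dc <- 1 / sqrt(Matrix::colSums(A))
    finish(Matrix::Diagonal(x = dr) %*% A %*% Matrix::Diagonal(x = dc),
           FALSE)
  }
}

# ---- parameter containers ---------------------------------------------

init_gnn_params <- function(t_in, config) {
  lapply(seq_len(config$L), function(l) {
    nin <- if (l == 1) t_in else config$d
    p <- list(W = glorot(nin, config$d), b = rep(0, config$d))
    p$U <- glorot(nin, config$d)   # root weight; unused when !use_root
    p
  })
}

init_mlp_params <- function(n_in, n_hidden, n_out) {
  list(W1 = glorot(n_in, n_hidden), b1 = rep(0, n_hidden),
       W2 = glorot(n_hidden, n_out), b2 = rep(0, n_out))
}

#' Initialise model parameters
#'
#' Creates baseline-MLP, decoder and per-view GNN parameters for the given
#' view set, deterministically from `config$seed`.
#'
#' @param data a [spatial_expression()].
#' @param view_ids character vector of view (LR pair) ids.
#' @param config a [model_config()].
#' @return Nested parameter list with elements `baseline`, `decoder`
#'   (or `decoders` when `per_view_decoder`), `views` (or `gnn` when
#'   `share_gnn_across_views`).
#' @export
init_model_params <- function(data, view_ids, config) {
  t_in <- ncol(data$cell_types)
  m <- length(data$gene_names)
  set.seed(config$seed)
  params <- list(baseline = init_mlp_params(t_in, config$d, m))
  if (config$share_gnn_across_views) {
    params$gnn <- init_gnn_params(t_in, config)
  } else {
    params$views <- lapply(view_ids, function(id) init_gnn_params(t_in, config))
    names(params$views) <- view_ids
  }
  if (config$per_view_decoder) {
    params$decoders <- lapply(view_ids, function(id)
      init_mlp_params(config$d, config$d, m))
    names(params$decoders) <- view_ids
  } else {
    params$decoder <- init_mlp_params(config$d, config$d, m)
  }
  params
}

# add parameters for views that joined the graph after a warm start
grow_model_params <- function(params, data, view_ids, config, seed) {
  set.seed(seed)
  if (!config$share_gnn_across_views) {
    new_ids <- setdiff(view_ids, names(params$views))
    for (id in new_ids)
      params$views[[id]] <- init_gnn_params(ncol(data$cell_types), config)
  }
  if (config$per_view_decoder) {
    new_ids <- setdiff(view_ids, names(params$decoders))
    for (id in new_ids)
      params$decoders[[id]] <- init_mlp_params(config$d, config$d,
                                               length(data$gene_names))
  }
  params
}

# ---- forward passes ----------------------------------------------------

gnn_forward <- function(Tmat, agg, layers) {
  H <- Tmat
  cache <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    p <- layers[[l]]
    SH <- as.matrix(agg$S %*% H)
    pre <- SH %*% p$W
    if (agg$use_root) pre <- pre + H %*% p$U
    pre <- add_bias(pre, p$b)
    cache[[l]] <- list(H_in = H, SH = SH, pre = pre)
    H <- relu(pre)
  }
  list(H = H, cache = cache)
}

gnn_backward <- function(dH, agg, layers, cache) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    p <- layers[[l]]
    cc <- cache[[l]]
    dpre <- dH * (cc$pre > 0)
    g <- list(W = crossprod(cc$SH, dpre), b = colSums(dpre))
    dH <- as.matrix(agg$St %*% (dpre %*% t(p$W)))
    if (agg$use_root) {
      g$U <- crossprod(cc$H_in, dpre)
      dH <- dH + dpre %*% t(p$U)
    } else {
      g$U <- p$U * 0
    }
    grads[[l]] <- g
  }
  grads
}

# cols restricts the output layer to a subset of gene columns (a view's
# unmasked genes); the hidden layer is always full width.
mlp_forward <- function(X, p, cols = NULL) {
  A1 <- add_bias(X %*% p$W1, p$b1)
  R1 <- relu(A1)
  if (is.null(cols)) {
    Z <- add_bias(R1 %*% p$W2, p$b2)
  } else {
    Z <- add_bias(R1 %*% p$W2[, cols, drop = FALSE], p$b2[cols])
  }
  list(out = softplus(Z), A1 = A1, R1 = R1, Z = Z, X = X, cols = cols)
}

# returns output-layer grads on the restricted columns; the caller
# scatters them into full-size accumulators
mlp_backward <- function(dout, fw, p) {
  dZ <- dout * sigmoid(fw$Z)
  W2 <- if (is.null(fw$cols)) p$W2 else p$W2[, fw$cols, drop = FALSE]
  dR1 <- dZ %*% t(W2)
  dA1 <- dR1 * (fw$A1 > 0)
  list(grads = list(W1 = crossprod(fw$X, dA1), b1 = colSums(dA1),
                    W2 = crossprod(fw$R1, dZ), b2 = colSums(dZ)),
       dX = dA1 %*% t(p$W1))
}

# ---- spec-level operations (exposed for inspection and testing) --------

#' Encode one view into node embeddings
#'
#' Runs `config$L` rounds of weighted neighbour aggregation over the view's
#' directed edges, starting from the cell-type matrix as node features.
#'
#' @param Tmat cell-by-cell-type matrix, row-aligned with the view.
#' @param view a `ccc_view`.
#' @param layers per-layer GNN parameters (from [init_model_params()]).
#' @param config a [model_config()].
#' @return n x d embedding matrix.
#' @export
encode_view <- function(Tmat, view, layers, config) {
  agg <- build_aggregator(view, config$gnn_arch)
  H <- gnn_forward(as.matrix(Tmat), agg, layers)$H
  if (!all(is.finite(H)))
    stop("numeric error: non-finite embedding in view ", view$lr_id)
  H
}

#' Decode embeddings into a per-view expression matrix
#'
#' One hidden layer of width d with ReLU, then a linear map to the gene
#' panel with a softplus output so predicted expression is non-negative.
#'
#' @param H n x d embedding matrix.
#' @param decoder decoder MLP parameters.
#' @return n x m non-negative matrix.
#' @export
decode <- function(H, decoder) {
  mlp_forward(H, decoder)$out
}

#' Apply a gene mask to a view's decoded expression
#'
#' Zeroes the columns of genes the prior network does not allow this view
#' to regulate.
#'
#' @param Xs n x m matrix.
#' @param mask a `gene_mask` (or bare 0/1 vector of length m).
#' @return Matrix with masked columns identically zero.
#' @export
apply_mask <- function(Xs, mask) {
  mvec <- if (inherits(mask, "gene_mask")) mask$mask else mask
  stopifnot(length(mvec) == ncol(Xs))
  Xs[, mvec == 0] <- 0
  Xs
}

#' Cell-type baseline expression
#'
#' The component of expression explained by cell type alone: an MLP of the
#' cell-type matrix, so two cells with identical type rows receive
#' identical baselines.
#'
#' @param Tmat cell-by-cell-type matrix.
#' @param baseline baseline MLP parameters.
#' @return n x m non-negative matrix.
#' @export
baseline_expression <- function(Tmat, baseline) {
  mlp_forward(as.matrix(Tmat), baseline)$out
}

#' Combine baseline and per-view components
#'
#' @param X_hat_b baseline matrix.
#' @param components list of equally shaped per-view matrices.
#' @return Elementwise sum.
#' @export
combine <- function(X_hat_b, components) {
  for (comp in components) {
    if (!all(dim(comp) == dim(X_hat_b)))
      stop("shape mismatch between baseline and a view component")
    X_hat_b <- X_hat_b + comp
  }
  X_hat_b
}

#' Masked mean squared error
#'
#' MSE restricted to the observed (non-zero) entries of `X_obs`, or to an
#' explicit index set.
#'
#' @param X_hat,X_obs equally shaped matrices.
#' @param idx optional vector of linear indices to average over; defaults
#'   to the non-zero entries of `X_obs`.
#' @return Non-negative scalar.
#' @export
masked_mse <- function(X_hat, X_obs, idx = NULL) {
  X_obs <- as.matrix(X_obs)
  stopifnot(all(dim(X_hat) == dim(X_obs)))
  if (is.null(idx)) idx <- which(X_obs != 0)
  if (length(idx) == 0)
    stop("undefined loss: X_obs has no non-zero entries")
  mean((X_hat[idx] - X_obs[idx])^2)
}

# ---- Adam --------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

# one Adam step over a nested parameter list; returns updated params/state
adam_step <- function(params, grads, m, v, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, mm, vv) {
    if (is.list(p)) {
      out_p <- p; out_m <- mm; out_v <- vv
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], mm[[k]], vv[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      mm <- beta1 * mm + (1 - beta1) * g
      vv <- beta2 * vv + (1 - beta2) * g * g
      mhat <- mm / (1 - beta1^step)
      vhat <- vv / (1 - beta2^step)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
    }
  }
  walk(params, grads, m, v)
}

# ---- training ----------------------------------------------------------

view_gnn_params <- function(params, id, config) {
  if (config$share_gnn_across_views) params$gnn else params$views[[id]]
}
view_decoder_params <- function(params, id, config) {
  if (config$per_view_decoder) params$decoders[[id]] else params$decoder
}

mask_cols <- function(mask) {
  mvec <- if (inherits(mask, "gene_mask")) mask$mask else mask
  which(mvec == 1)
}

# ---- batched training path --------------------------------------------
# All views are stacked row-wise (V blocks of n cells) so every sparse
# aggregation is a single block-diagonal product and every elementwise op
# runs once over the stack. Produces results identical to the per-view
# reference path (model_forward); verified in the test suite.

build_training_setup <- function(Tmat, aggs, masks, config) {
  ids <- names(aggs)[vapply(masks[names(aggs)],
                            function(m) length(mask_cols(m)) > 0,
                            logical(1))]
  n <- nrow(Tmat)
  V <- length(ids)
  rows <- lapply(seq_len(V), function(v) ((v - 1) * n + 1):(v * n))
  names(rows) <- ids
  S_bd <- methods::as(Matrix::bdiag(lapply(aggs[ids], `[[`, "S")),
                      "CsparseMatrix")
  St_bd <- methods::as(Matrix::bdiag(lapply(aggs[ids], `[[`, "St")),
                       "CsparseMatrix")
  T_tall <- Tmat[rep(seq_len(n), times = V), , drop = FALSE]
  use_root <- if (V > 0) aggs[[ids[1]]]$use_root else FALSE
  cols <- lapply(masks[ids], mask_cols)
  list(ids = ids, n = n, V = V, rows = rows, S_bd = S_bd, St_bd = St_bd,
       T_tall = T_tall, use_root = use_root, cols = cols)
}

gnn_forward_batch <- function(setup, params, config) {
  H <- setup$T_tall
  L <- config$L
  cache <- vector("list", L)
  shared <- config$share_gnn_across_views
  for (l in seq_len(L)) {
    SH <- as.matrix(setup$S_bd %*% H)
    if (shared) {
      p <- params$gnn[[l]]
      pre <- SH %*% p$W
      if (setup$use_root) pre <- pre + H %*% p$U
      pre <- add_bias(pre, p$b)
    } else {
      pre <- matrix(0, nrow(H), config$d)
      for (id in setup$ids) {
        p <- params$views[[id]][[l]]
        r <- setup$rows[[id]]
        blk <- SH[r, , drop = FALSE] %*% p$W
        if (setup$use_root)
          blk <- blk + H[r, , drop = FALSE] %*% p$U
        pre[r, ] <- add_bias(blk, p$b)
      }
    }
    pos <- pre > 0
    cache[[l]] <- list(H_in = H, SH = SH, pos = pos)
    H <- pre * pos
  }
  list(H = H, cache = cache)
}

gnn_backward_batch <- function(dH, setup, params, config, cache) {
  shared <- config$share_gnn_across_views
  grads <- if (shared) vector("list", config$L) else
    stats::setNames(lapply(setup$ids, function(id)
      vector("list", config$L)), setup$ids)
  for (l in rev(seq_len(config$L))) {
    cc <- cache[[l]]
    dpre <- dH * cc$pos
    if (shared) {
      p <- params$gnn[[l]]
      g <- list(W = crossprod(cc$SH, dpre), b = colSums(dpre))
      dmid <- dpre %*% t(p$W)
      dH <- as.matrix(setup$St_bd %*% dmid)
      if (setup$use_root) {
        g$U <- crossprod(cc$H_in, dpre)
        dH <- dH + dpre %*% t(p$U)
      } else g$U <- p$U * 0
      grads[[l]] <- g
    } else {
      dmid <- matrix(0, nrow(dpre), ncol(cc$H_in))
      droot <- if (setup$use_root) matrix(0, nrow(dpre), ncol(cc$H_in))
      for (id in setup$ids) {
        p <- params$views[[id]][[l]]
        r <- setup$rows[[id]]
        dpre_v <- dpre[r, , drop = FALSE]
        g <- list(W = crossprod(cc$SH[r, , drop = FALSE], dpre_v),
                  b = colSums(dpre_v))
        dmid[r, ] <- dpre_v %*% t(p$W)
        if (setup$use_root) {
          g$U <- crossprod(cc$H_in[r, , drop = FALSE], dpre_v)
          droot[r, ] <- dpre_v %*% t(p$U)
        } else g$U <- p$U * 0
        grads[[id]][[l]] <- g[c("W", "b", "U")]
      }
      dH <- as.matrix(setup$St_bd %*% dmid)
      if (setup$use_root) dH <- dH + droot
    }
  }
  # reorder leaf grads to the parameter layout (W, b, U)
  if (shared) grads <- lapply(grads, function(g) g[c("W", "b", "U")])
  grads
}

forward_pass <- function(Tmat, setup, params, config,
                         want_components = FALSE) {
  fw_b <- mlp_forward(Tmat, params$baseline)
  X_hat <- fw_b$out
  n <- setup$n
  m <- ncol(X_hat)
  if (setup$V == 0)
    return(list(X_hat = X_hat, X_hat_b = fw_b$out, fw_b = fw_b,
                components = if (want_components) list() else NULL))
  gf <- gnn_forward_batch(setup, params, config)
  dec_fw <- list()
  components <- if (want_components) list() else NULL
  shared_dec <- !config$per_view_decoder
  A1_tall <- NULL
  if (shared_dec) {
    # one batched hidden layer for the shared decoder
    A1_tall <- add_bias(gf$H %*% params$decoder$W1, params$decoder$b1)
    pos1_tall <- A1_tall > 0
    R1_tall <- A1_tall * pos1_tall
  }
  for (id in setup$ids) {
    r <- setup$rows[[id]]
    cols <- setup$cols[[id]]
    p <- view_decoder_params(params, id, config)
    if (shared_dec) {
      R1 <- R1_tall[r, , drop = FALSE]
      pos1 <- pos1_tall[r, , drop = FALSE]
    } else {
      A1 <- add_bias(gf$H[r, , drop = FALSE] %*% p$W1, p$b1)
      pos1 <- A1 > 0
      R1 <- A1 * pos1
    }
    Z <- add_bias(R1 %*% p$W2[, cols, drop = FALSE], p$b2[cols])
    out <- softplus(Z)
    dec_fw[[id]] <- list(R1 = R1, pos1 = pos1, Z = Z)
    X_hat[, cols] <- X_hat[, cols] + out
    if (want_components) {
      comp <- matrix(0, n, m)
      comp[, cols] <- out
      components[[id]] <- comp
    }
  }
  list(X_hat = X_hat, X_hat_b = fw_b$out, fw_b = fw_b, gnn = gf,
       dec = dec_fw, components = components)
}

backward_pass <- function(dX_hat, Tmat, setup, params, config, fw) {
  grads <- list()
  bb <- mlp_backward(dX_hat, fw$fw_b, params$baseline)
  grads$baseline <- bb$grads
  m <- ncol(dX_hat)
  d <- config$d
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  if (setup$V == 0) {
    for (nm in setdiff(names(params), "baseline"))
      grads[[nm]] <- zero_like(params[[nm]])
    return(grads[names(params)])
  }
  shared_dec <- !config$per_view_decoder
  if (shared_dec)
    dec_acc <- list(W1 = matrix(0, d, d), b1 = rep(0, d),
                    W2 = matrix(0, d, m), b2 = rep(0, m))
  dH_tall <- matrix(0, setup$V * setup$n, d)
  for (id in setup$ids) {
    r <- setup$rows[[id]]
    cols <- setup$cols[[id]]
    p <- view_decoder_params(params, id, config)
    dfw <- fw$dec[[id]]
    dout <- dX_hat[, cols, drop = FALSE]
    dZ <- dout * sigmoid(dfw$Z)
    dR1 <- dZ %*% t(p$W2[, cols, drop = FALSE])
    dA1 <- dR1 * dfw$pos1
    H_v <- fw$gnn$H[r, , drop = FALSE]
    gW1 <- crossprod(H_v, dA1)
    gW2 <- crossprod(dfw$R1, dZ)
    if (shared_dec) {
      dec_acc$W1 <- dec_acc$W1 + gW1
      dec_acc$b1 <- dec_acc$b1 + colSums(dA1)
      dec_acc$W2[, cols] <- dec_acc$W2[, cols] + gW2
      dec_acc$b2[cols] <- dec_acc$b2[cols] + colSums(dZ)
    } else {
      g <- list(W1 = gW1, b1 = colSums(dA1),
                W2 = matrix(0, d, m), b2 = rep(0, m))
      g$W2[, cols] <- gW2
      g$b2[cols] <- colSums(dZ)
      grads$decoders[[id]] <- g
    }
    dH_tall[r, ] <- dA1 %*% t(p$W1)
  }
  if (shared_dec) grads$decoder <- dec_acc
  gg <- gnn_backward_batch(dH_tall, setup, params, config, fw$gnn$cache)
  if (config$share_gnn_across_views) grads$gnn <- gg
  else grads$views <- gg
  # fully masked views carry zero grads so the trees stay congruent
  if (!config$share_gnn_across_views) {
    for (id in setdiff(names(params$views), names(grads$views)))
      grads$views[[id]] <- zero_like(params$views[[id]])
    grads$views <- grads$views[names(params$views)]
  }
  if (config$per_view_decoder) {
    for (id in setdiff(names(params$decoders), names(grads$decoders)))
      grads$decoders[[id]] <- zero_like(params$decoders[[id]])
    grads$decoders <- grads$decoders[names(params$decoders)]
  }
  grads[names(params)]
}

# full forward pass; per-view decoding is restricted to unmasked columns.
# want_components materialises the full per-view matrices (only needed for
# the returned decomposition, not during training).
model_forward <- function(Tmat, aggs, masks, params, config,
                          want_components = FALSE) {
  fw_b <- mlp_forward(Tmat, params$baseline)
  view_fw <- list()
  components <- if (want_components) list() else NULL
  X_hat <- fw_b$out
  m <- ncol(X_hat)
  for (id in names(aggs)) {
    cols <- mask_cols(masks[[id]])
    if (length(cols) == 0) {
      view_fw[id] <- list(NULL)
      if (want_components)
        components[[id]] <- matrix(0, nrow(X_hat), m)
      next
    }
    gf <- gnn_forward(Tmat, aggs[[id]], view_gnn_params(params, id, config))
    df <- mlp_forward(gf$H, view_decoder_params(params, id, config), cols)
    view_fw[[id]] <- list(gnn = gf, dec = df)
    X_hat[, cols] <- X_hat[, cols] + df$out
    if (want_components) {
      comp <- matrix(0, nrow(X_hat), m)
      comp[, cols] <- df$out
      components[[id]] <- comp
    }
  }
  list(X_hat = X_hat, X_hat_b = fw_b$out, components = components,
       fw_b = fw_b, view_fw = view_fw)
}

model_backward <- function(dX_hat, Tmat, aggs, masks, params, config, fw) {
  grads <- list()
  bb <- mlp_backward(dX_hat, fw$fw_b, params$baseline)
  grads$baseline <- bb$grads
  m <- ncol(dX_hat)
  dec_shared <- NULL
  for (id in names(aggs)) {
    if (is.null(fw$view_fw[[id]])) next   # fully masked view
    cols <- fw$view_fw[[id]]$dec$cols
    dcomp <- dX_hat[, cols, drop = FALSE]
    dec_p <- view_decoder_params(params, id, config)
    db <- mlp_backward(dcomp, fw$view_fw[[id]]$dec, dec_p)
    # scatter restricted output-layer grads to full width
    full <- list(W1 = db$grads$W1, b1 = db$grads$b1,
                 W2 = matrix(0, config$d, m), b2 = rep(0, m))
    full$W2[, cols] <- db$grads$W2
    full$b2[cols] <- db$grads$b2
    if (config$per_view_decoder) {
      grads$decoders[[id]] <- full
    } else if (is.null(dec_shared)) {
      dec_shared <- full
    } else {
      dec_shared$W1 <- dec_shared$W1 + full$W1
      dec_shared$b1 <- dec_shared$b1 + full$b1
      dec_shared$W2[, cols] <- dec_shared$W2[, cols] + db$grads$W2
      dec_shared$b2[cols] <- dec_shared$b2[cols] + db$grads$b2
    }
    gnn_p <- view_gnn_params(params, id, config)
    gb <- gnn_backward(db$dX, aggs[[id]], gnn_p, fw$view_fw[[id]]$gnn$cache)
    if (config$share_gnn_across_views) {
      grads$gnn <- if (is.null(grads$gnn)) gb
                   else Map(function(a, b) Map(`+`, a, b), grads$gnn, gb)
    } else {
      grads$views[[id]] <- gb
    }
  }
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  if (!config$per_view_decoder)
    grads$decoder <- if (is.null(dec_shared)) zero_like(params$decoder)
                     else dec_shared
  if (config$share_gnn_across_views && is.null(grads$gnn))
    grads$gnn <- zero_like(params$gnn)
  # fully masked (or absent) views still need zero grads so the grad tree
  # stays congruent with the parameter tree: adam_step walks positionally
  if (!config$share_gnn_across_views) {
    for (id in setdiff(names(params$views), names(grads$views)))
      grads$views[[id]] <- zero_like(params$views[[id]])
    grads$views <- grads$views[names(params$views)]
  }
  if (config$per_view_decoder) {
    for (id in setdiff(names(params$decoders), names(grads$decoders)))
      grads$decoders[[id]] <- zero_like(params$decoders[[id]])
    grads$decoders <- grads$decoders[names(params$decoders)]
  }
  grads[names(params)]
}

#' Train the imputation model on a fixed view set
#'
#' Full-batch Adam on the masked MSE over observed (training) entries, with
#' early stopping on the validation loss when a validation index set is
#' supplied and on the training loss otherwise. The parameters achieving
#' the best monitored loss are restored before the decomposition is
#' returned.
#'
#' @param data a [spatial_expression()].
#' @param multiview a `multiview_ccc`.
#' @param masks named list of `gene_mask` objects, one per view.
#' @param config a [model_config()].
#' @param params optional warm-start parameters; parameters for views
#'   absent from `params` are freshly initialised. Adam state always starts
#'   from zero.
#' @param split optional list with integer vectors `train` (and optionally
#'   `val`) of linear indices into the expression matrix; defaults to
#'   training on all non-zero entries.
#' @param init_seed seed used when initialising (or growing) parameters;
#'   defaults to `config$seed`.
#' @return An `imputation_result`: `X_hat`, `X_hat_b`, `components` (named
#'   list of per-view matrices, masked columns exactly zero),
#'   `training_log` (data frame epoch/train_loss/val_loss), `views_used`,
#'   `params`, `config`.
#' @export
train_imputation <- function(data, multiview, masks, config,
                             params = NULL, split = NULL,
                             init_seed = config$seed) {
  if (length(multiview$views) == 0)
    stop("at least one communication view is required")
  X <- as.matrix(data$X)
  Tmat <- as.matrix(data$cell_types)
  view_ids <- names(multiview$views)
  if (is.null(split)) {
    train_idx <- which(X != 0)
    val_idx <- NULL
  } else {
    train_idx <- split$train
    val_idx <- split$val
  }
  if (length(train_idx) == 0)
    stop("undefined loss: no non-zero training entries")

  aggs <- lapply(multiview$views, build_aggregator, arch = config$gnn_arch)
  setup <- build_training_setup(Tmat, aggs, masks, config)
  if (is.null(params)) {
    params <- init_model_params(data, view_ids, config)
  } else {
    params <- grow_model_params(params, data, view_ids, config, init_seed)
  }

  m_state <- adam_init(params)
  v_state <- adam_init(params)
  n_train <- length(train_idx)

  log_epoch <- integer(0); log_train <- numeric(0); log_val <- numeric(0)
  best <- Inf; best_params <- params; wait <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    fw <- forward_pass(Tmat, setup, params, config)
    diff <- fw$X_hat[train_idx] - X[train_idx]
    train_loss <- mean(diff^2)
    if (!is.finite(train_loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    val_loss <- if (!is.null(val_idx))
      mean((fw$X_hat[val_idx] - X[val_idx])^2) else NA_real_
    log_epoch <- c(log_epoch, epoch)
    log_train <- c(log_train, train_loss)
    log_val <- c(log_val, val_loss)

    monitored <- if (!is.null(val_idx)) val_loss else train_loss
    if (monitored < best - config$min_delta) {
      best <- monitored
      best_params <- params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }

    dX_hat <- matrix(0, nrow(X), ncol(X))
    dX_hat[train_idx] <- 2 * diff / n_train
    grads <- backward_pass(dX_hat, Tmat, setup, params, config, fw)
    st <- adam_step(params, grads, m_state, v_state,
                    lr = config$learning_rate, step = epoch)
    params <- st$p; m_state <- st$m; v_state <- st$v
  }

  params <- best_params
  fw <- forward_pass(Tmat, setup, params, config, want_components = TRUE)
  dn <- list(data$cell_ids, data$gene_names)
  components <- lapply(fw$components, function(M) { dimnames(M) <- dn; M })
  for (id in setdiff(view_ids, names(components)))   # fully masked views
    components[[id]] <- matrix(0, nrow(X), ncol(X), dimnames = dn)
  components <- components[view_ids]
  X_hat <- fw$X_hat; dimnames(X_hat) <- dn
  X_hat_b <- fw$X_hat_b; dimnames(X_hat_b) <- dn
  structure(
    list(X_hat = X_hat, X_hat_b = X_hat_b, components = components,
         training_log = data.frame(epoch = log_epoch,
                                   train_loss = log_train,
                                   val_loss = log_val),
         views_used = view_ids, params = params, config = config),
    class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("<imputation_result> ", nrow(x$X_hat), " cells x ", ncol(x$X_hat),
      " genes, ", length(x$views_used), " views, ",
      nrow(x$training_log), " epochs (final train loss ",
      sprintf("%.4g", utils::tail(x$training_log$train_loss, 1)), ")\n",
      sep = "")
  invisible(x)
}
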