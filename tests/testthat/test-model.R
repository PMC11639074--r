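# model-core tests run on a deliberately tiny instance so the whole file
# stays fast
model_fixture <- function(seed = 5, arch = "graph_transformer",
                          d = 6, ...) {
  ds <- small_sim(seed = seed, n_cells = 25, n_lr_pairs = 4, n_genes = 12)
  mv <- assemble_multiview(ds$data, ds$lr, theta = 0.1, k = 3)
  mc <- model_config(d = d, seed = 2, gnn_arch = arch, ...)
  masks <- derive_gene_masks(ds$prior, ds$lr, names(mv$views),
                             ds$data$gene_names, hops = 2)
  params <- init_model_params(ds$data, names(mv$views), mc)
  list(ds = ds, mv = mv, mc = mc, masks = masks, params = params,
       Tmat = as.matrix(ds$data$cell_types),
       X = as.matrix(ds$data$X))
}

test_that("masked MSE averages over observed entries only", {
  X_hat <- rbind(c(1, 0), c(2, 3))
  X_obs <- rbind(c(2, 0), c(2, 4))
  expect_equal(masked_mse(X_hat, X_obs), (1 + 0 + 1) / 3)
  expect_equal(masked_mse(X_obs, X_obs), 0)
  # perturbing a zero entry of X_obs leaves the loss unchanged
  X_hat2 <- X_hat; X_hat2[1, 2] <- 99
  expect_equal(masked_mse(X_hat2, X_obs), masked_mse(X_hat, X_obs))
  expect_error(masked_mse(X_hat, X_obs * 0), "non-zero")
})

test_that("mask application and combination behave elementwise", {
  M <- rbind(c(5, 7))
  expect_equal(apply_mask(M, c(1, 0)), rbind(c(5, 0)))
  expect_equal(apply_mask(M, c(1, 1)), M)
  expect_equal(apply_mask(M, c(0, 0)), rbind(c(0, 0)))
  expect_equal(combine(matrix(1), list(matrix(2), matrix(3))), matrix(6))
  expect_equal(combine(matrix(1), list()), matrix(1))
  expect_error(combine(matrix(1), list(matrix(0, 2, 2))), "shape")
})

test_that("baseline is a function of the cell-type row alone", {
  fx <- model_fixture()
  Xb <- baseline_expression(fx$Tmat, fx$params$baseline)
  expect_equal(dim(Xb), c(nrow(fx$Tmat), length(fx$ds$data$gene_names)))
  same_type <- which(fx$Tmat[, 1] == 1)
  expect_gt(length(same_type), 1)
  expect_equal(Xb[same_type[1], ], Xb[same_type[2], ])
})

test_that("encoding is deterministic and isolated cells see only themselves", {
  fx <- model_fixture()
  v <- fx$mv$views[[1]]
  layers <- fx$params$views[[1]]
  H1 <- encode_view(fx$Tmat, v, layers, fx$mc)
  H2 <- encode_view(fx$Tmat, v, layers, fx$mc)
  expect_identical(H1, H2)
  expect_equal(dim(H1), c(nrow(fx$Tmat), fx$mc$d))

  # a cell with no incoming edges (and a root term) ignores other cells
  iso <- which(Matrix::colSums(v$edges) == 0)
  if (length(iso) > 0) {
    T2 <- fx$Tmat
    other <- setdiff(seq_len(nrow(T2)), iso[1])[1]
    T2[other, ] <- rev(T2[other, ])
    H3 <- encode_view(T2, v, layers, fx$mc)
    expect_equal(H3[iso[1], ], H1[iso[1], ])
  }
})

test_that("shared decoder maps identical embeddings identically", {
  fx <- model_fixture()
  H <- encode_view(fx$Tmat, fx$mv$views[[1]], fx$params$views[[1]], fx$mc)
  H[2, ] <- H[1, ]
  out <- decode(H, fx$params$decoder)
  expect_equal(out[1, ], out[2, ])
  expect_equal(dim(out), c(nrow(H), length(fx$ds$data$gene_names)))
  expect_true(all(out >= 0))   # softplus output
})

test_that("analytic gradients match numeric gradients in every architecture", {
  for (arch in c("graph_transformer", "gcn", "gat", "graphsage")) {
    fx <- model_fixture(arch = arch)
    aggs <- lapply(fx$mv$views, intercell:::build_aggregator, arch = arch)
    setup <- intercell:::build_training_setup(fx$Tmat, aggs, fx$masks, fx$mc)
    idx <- which(fx$X != 0)
    lossfn <- function(p) {
      fw <- intercell:::forward_pass(fx$Tmat, setup, p, fx$mc)
      mean((fw$X_hat[idx] - fx$X[idx])^2)
    }
    fw <- intercell:::forward_pass(fx$Tmat, setup, fx$params, fx$mc)
    dX <- matrix(0, nrow(fx$X), ncol(fx$X))
    dX[idx] <- 2 * (fw$X_hat[idx] - fx$X[idx]) / length(idx)
    gr <- intercell:::backward_pass(dX, fx$Tmat, setup, fx$params, fx$mc, fw)

    v1 <- names(fx$mv$views)[1]
    paths <- list(list("baseline", "W1"), list("baseline", "b2"),
                  list("decoder", "W2"), list("decoder", "b1"),
                  list("views", v1, 1L, "W"), list("views", v1, 1L, "U"),
                  list("views", v1, 2L, "W"), list("views", v1, 2L, "b"))
    set.seed(9)
    for (path in paths) {
      target <- fx$params
      for (k in path) target <- target[[k]]
      i <- sample(length(target), 1)
      num <- numeric_grad(lossfn, fx$params, path, i)
      ana <- leaf_value(gr, path, i)
      expect_equal(ana, num, tolerance = 1e-5,
                   label = paste(arch, paste(unlist(path), collapse = "/")))
    }
  }
})

test_that("batched training path equals the per-view reference path", {
  for (opts in list(list(), list(share_gnn_across_views = TRUE),
                    list(per_view_decoder = TRUE))) {
    fx <- do.call(model_fixture, opts)
    aggs <- lapply(fx$mv$views, intercell:::build_aggregator,
                   arch = fx$mc$gnn_arch)
    setup <- intercell:::build_training_setup(fx$Tmat, aggs, fx$masks,
                                              fx$mc)
    fw_fast <- intercell:::forward_pass(fx$Tmat, setup, fx$params, fx$mc,
                                        want_components = TRUE)
    fw_ref <- intercell:::model_forward(fx$Tmat, aggs, fx$masks,
                                        fx$params, fx$mc,
                                        want_components = TRUE)
    expect_equal(fw_fast$X_hat, fw_ref$X_hat, tolerance = 1e-12)
    expect_equal(fw_fast$components, fw_ref$components, tolerance = 1e-12)

    idx <- which(fx$X != 0)
    dX <- matrix(0, nrow(fx$X), ncol(fx$X))
    dX[idx] <- 2 * (fw_fast$X_hat[idx] - fx$X[idx]) / length(idx)
    g_fast <- intercell:::backward_pass(dX, fx$Tmat, setup, fx$params,
                                        fx$mc, fw_fast)
    g_ref <- intercell:::model_backward(dX, fx$Tmat, aggs, fx$masks,
                                        fx$params, fx$mc, fw_ref)
    expect_equal(unlist(g_fast), unlist(g_ref), tolerance = 1e-12)
  }
})

test_that("training is reproducible, early-stops, and decomposes exactly", {
  fx <- model_fixture(max_epochs = 80)
  r1 <- train_imputation(fx$ds$data, fx$mv, fx$masks, fx$mc)
  r2 <- train_imputation(fx$ds$data, fx$mv, fx$masks, fx$mc)
  expect_identical(r1$training_log, r2$training_log)

  # loss at the stopping epoch does not exceed the first epoch's
  log <- r1$training_log$train_loss
  expect_lte(log[length(log)], log[1])

  # decomposition identity and non-negative parts
  resid <- r1$X_hat - r1$X_hat_b - Reduce(`+`, r1$components)
  expect_lt(max(abs(resid)), 1e-5)
  expect_true(all(r1$X_hat_b >= 0))

  # masking conservation: genes masked in all views get exactly zero
  # micro-environment contribution
  all_masked <- which(Reduce(`+`, lapply(fx$masks, `[[`, "mask")) == 0)
  if (length(all_masked) > 0) {
    micro <- r1$X_hat - r1$X_hat_b
    expect_true(all(micro[, all_masked] == 0))
  }
  for (id in names(fx$masks)) {
    zero_cols <- which(fx$masks[[id]]$mask == 0)
    expect_true(all(r1$components[[id]][, zero_cols] == 0))
  }
})

test_that("a type with constant expression and silenced views recovers it", {
  # all views fully masked: the model reduces to the cell-type baseline
  n <- 40
  types <- rep(1:2, each = n / 2)
  Tm <- matrix(0, n, 2); Tm[cbind(1:n, types)] <- 1
  mu <- c(6, 2)
  X <- matrix(rep(mu[types], 3), n, 3)
  co <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  d <- spatial_expression(X, co, Tm)
  lr <- lr_table("p", "G1", "G2")
  mv <- assemble_multiview(d, lr, theta = 0.1, k = 3)
  masks <- list(p = structure(list(lr_id = "p", mask = c(G1 = 0, G2 = 0,
                                                         G3 = 0)),
                              class = "gene_mask"))
  mc <- model_config(d = 8, seed = 3, max_epochs = 400, patience = 25)
  r <- train_imputation(d, mv, masks, mc)
  expect_true(all(r$X_hat == r$X_hat_b))
  expect_equal(mean(r$X_hat_b[types == 1, ]), 6, tolerance = 0.3)
  expect_equal(mean(r$X_hat_b[types == 2, ]), 2, tolerance = 0.3)
})

test_that("trained imputation beats the column-mean predictor on held-out entries", {
  ds <- small_sim(seed = 13, n_cells = 80, n_lr_pairs = 6, n_genes = 16)
  split <- make_splits(ds$data$X, 1, seed = 4)[[1]]
  mv <- assemble_multiview(ds$data, ds$lr, theta = 0.1, k = 5)
  masks <- derive_gene_masks(ds$prior, ds$lr, names(mv$views),
                             ds$data$gene_names, hops = 2)
  mc <- model_config(seed = 1, max_epochs = 300)
  r <- train_imputation(ds$data, mv, masks, mc,
                        split = split[c("train", "val")])
  X <- as.matrix(ds$data$X)
  rmse <- function(pred) sqrt(mean((pred - X[split$test])^2))
  model_rmse <- rmse(r$X_hat[split$test])
  # column means computed from training entries only
  Xtr <- X; Xtr[c(split$val, split$test)] <- NA
  cm <- colMeans(Xtr, na.rm = TRUE)
  col_of <- ((split$test - 1) %/% nrow(X)) + 1
  expect_lt(model_rmse, rmse(cm[col_of]))
})

test_that("training rejects degenerate inputs", {
  fx <- model_fixture()
  empty_mv <- fx$mv; empty_mv$views <- list()
  expect_error(train_imputation(fx$ds$data, empty_mv, fx$masks, fx$mc),
               "at least one")
})
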