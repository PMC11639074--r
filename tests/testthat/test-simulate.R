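test_that("cell-type territories are Voronoi regions that mix with k_b", {
  out <- assign_cell_types(200, 100, 2, 1, seed = 1)
  expect_length(out$types, 200)
  expect_true(all(out$types %in% 1:2))
  expect_true(all(out$coords >= 0 & out$coords <= 100))

  # contiguity at k_b = 1: territory count equals anchor count on average;
  # higher k_b fragments territories (counted as connected components of
  # the same-type 5-NN graph, averaged over seeds)
  components_of <- function(k_b, seed) {
    o <- assign_cell_types(150, 100, 3, k_b, seed = seed)
    D <- compute_distance_matrix(o$coords)
    nn <- intercell:::knn_index(D, 5)
    edges <- do.call(rbind, lapply(seq_len(nrow(nn)), function(i) {
      js <- nn[i, o$types[nn[i, ]] == o$types[i]]
      if (length(js) == 0) NULL else cbind(i, js)
    }))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, 150 - igraph::vcount(g)))
    igraph::count_components(g)
  }
  lo <- mean(vapply(1:5, function(s) components_of(2, s), numeric(1)))
  hi <- mean(vapply(1:5, function(s) components_of(20, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("expression follows the stated negative-binomial means", {
  cfg <- simulation_config(n_cells = 1000, n_genes = 20, n_cell_types = 4,
                           seed = 2)
  types <- rep(1:4, each = 250)
  sampled <- sample_expression(types, cfg, seed = 2)
  X <- sampled$X
  expect_true(all(X >= 0), all(X == round(X)))

  nb_mean <- function(np) np[1] * (1 - np[2]) / np[2]
  nb_se <- function(np, n) sqrt(np[1] * (1 - np[2]) / np[2]^2 / n)
  # marker gene within its own type
  g <- which(sampled$marker_map == 1)[1]
  vals <- X[types == 1, g]
  expect_lt(abs(mean(vals) - nb_mean(cfg$nb_high)),
            3 * nb_se(cfg$nb_high, length(vals)))
  # the same gene outside its type is background
  out <- X[types != 1, g]
  expect_lt(abs(mean(out) - nb_mean(cfg$nb_low)),
            3 * nb_se(cfg$nb_low, length(out)))
})

test_that("communication zones elevate target genes inside the zone", {
  ds <- small_sim(seed = 5, n_cells = 250, n_lr_pairs = 6, n_genes = 15)
  X <- as.matrix(ds$dense$X)
  info <- ds$lr_info
  gene_idx <- match(unique(ds$truth$gene), ds$dense$gene_names)
  deltas <- vapply(seq_len(nrow(info)), function(p) {
    tg <- info$target[p]
    inside <- ds$truth$cell_id[ds$truth$lr_id == info$id[p]]
    if (length(inside) < 3) return(NA_real_)
    inside_i <- match(inside, ds$dense$cell_ids)
    mean(X[inside_i, tg]) - mean(X[-inside_i, tg])
  }, numeric(1))
  expect_gt(mean(deltas > 0, na.rm = TRUE), 0.5)
  expect_equal(nrow(ds$zones), 6)
  # cells outside every zone never appear in truth
  far <- setdiff(ds$dense$cell_ids, ds$truth$cell_id)
  expect_false(any(far %in% ds$truth$cell_id))
})

test_that("masking hits the target density exactly and only removes", {
  set.seed(3)
  X <- matrix(rpois(500, 3), 25, 20)
  M <- mask_to_density(X, 0.2, seed = 1)
  expect_lte(abs(mean(M != 0) - 0.2), 1 / length(X))
  expect_true(all(M[X == 0] == 0))          # zeros never switch on
  expect_true(all(M[M != 0] == X[M != 0]))  # survivors unchanged
  dense <- matrix(1, 5, 5)
  expect_identical(mask_to_density(dense, 1, seed = 1), dense)
  expect_error(mask_to_density(matrix(0:1, 2, 2), 0.9, seed = 1),
               "achievable")
})

test_that("generation is deterministic and presets differ as documented", {
  cfg <- simulation_setting(1, n_cells = 80, n_lr_pairs = 5,
                            n_genes = 12, seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.matrix(d1$data$X), as.matrix(d2$data$X))
  expect_identical(d1$truth, d2$truth)

  s8 <- simulation_setting(8)
  s9 <- simulation_setting(9)
  expect_identical(s9$k_b, 20L)
  expect_identical(s8$k_b, 10L)
  s8$k_b <- s9$k_b <- 0L
  expect_identical(unclass(s8), unclass(s9))
  expect_error(simulation_setting(99), "usage error")
})

test_that("all nine presets generate at reduced scale with usable truth", {
  for (id in 1:9) {
    ds <- simulate_dataset(simulation_setting(
      id, n_cells = 150, n_lr_pairs = 8, n_genes = 20, seed = id))
    expect_gt(nrow(ds$truth), 0)
    expect_lte(abs(Matrix::nnzero(ds$data$X) / prod(dim(ds$data$X)) - 0.2),
               1 / prod(dim(ds$data$X)))
  }
})

test_that("the planted ground truth is self-consistent (oracle precision 1)", {
  ds <- small_sim(seed = 12, n_cells = 150, n_lr_pairs = 6, n_genes = 15)
  hits <- vapply(seq_len(nrow(ds$truth)), function(i) {
    r <- oracle_ranking(ds, ds$truth$cell_id[i], ds$truth$gene[i])
    r$lr_id[1] == ds$truth$lr_id[i] ||
      r$psi[match(ds$truth$lr_id[i], r$lr_id)] == 1
  }, logical(1))
  expect_true(all(hits))
})
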