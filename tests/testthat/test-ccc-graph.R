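test_that("ligand/receptor summaries use per-cell geometric means", {
  d <- tiny_dataset()
  # single-subunit: levels are the gene's own expression
  s <- summarize_lr_expression(d, lr_table("p", "g1", "g2")[[1]])
  expect_equal(s$E_l, c(0, 4, 0, 9))
  expect_equal(s$xi_l, 0.5)
  # two subunits: sqrt of the product per cell; zero annihilates
  s2 <- summarize_lr_expression(d, lr_table("p", "g1+g4", "g2")[[1]])
  expect_equal(s2$E_l, c(0, sqrt(4 * 2), 0, sqrt(9 * 4)))
  expect_equal(s2$xi_l, 0.5)
  s3 <- summarize_lr_expression(d, lr_table("p", "g1+g5", "g2")[[1]])
  expect_equal(s3$E_l, c(0, 0, 0, sqrt(18)))
  expect_equal(s3$xi_l, 0.25)
  expect_error(summarize_lr_expression(d, lr_table("p", "nope", "g2")[[1]]),
               "nope")
})

test_that("active-pair filter uses strict inequalities on both sides", {
  mk <- function(id, xl, xr) {
    structure(list(lr = list(id = id), xi_l = xl, xi_r = xr),
              class = "lr_summary")
  }
  sums <- list(mk("a", 0.20, 0.20), mk("b", 0.15, 0.90),
               mk("c", 0.90, 0.15), mk("d", 0.16, 0.16))
  expect_setequal(filter_expressed_pairs(sums, 0.15), c("a", "d"))
  expect_identical(filter_expressed_pairs(list(), 0.15), character(0))
  expect_error(filter_expressed_pairs(sums, 1))
})

test_that("distance matrix is Euclidean, symmetric, clamped", {
  co <- rbind(c(0, 0), c(3, 4))
  D <- compute_distance_matrix(co)
  expect_equal(D[1, 2], 5)
  expect_equal(D[2, 1], 5)
  expect_equal(diag(D), c(0, 0), ignore_attr = TRUE)
  expect_error(compute_distance_matrix(co[1, , drop = FALSE]), "2 cells")

  # coincident cells: off-diagonal clamped, diagonal untouched
  co2 <- rbind(c(0, 0), c(0, 0), c(1, 1))
  D2 <- compute_distance_matrix(co2)
  expect_gt(D2[1, 2], 0)
  expect_equal(diag(D2), rep(0, 3), ignore_attr = TRUE)

  set.seed(1)
  co3 <- matrix(runif(20), 10, 2)
  D3 <- compute_distance_matrix(co3)
  expect_equal(D3, t(D3))
})

test_that("view weights follow ligand x receptor over distance", {
  co <- rbind(c(0, 0), c(0, 2))
  D <- compute_distance_matrix(co)
  s <- structure(list(lr = list(id = "p"), E_l = c(1, 2), E_r = c(3, 4)),
                 class = "lr_summary")
  v <- build_ccc_view(s, D, k = 1)
  expect_equal(v$edges[1, 2], 1 * 4 / 2)
  expect_equal(v$edges[2, 1], 2 * 3 / 2)
  expect_equal(Matrix::diag(v$edges), c(0, 0), ignore_attr = TRUE)

  # zero ligand silences all outgoing edges of that cell
  s0 <- structure(list(lr = list(id = "p"), E_l = c(0, 2), E_r = c(3, 4)),
                  class = "lr_summary")
  v0 <- build_ccc_view(s0, D, k = 1)
  expect_equal(Matrix::nnzero(v0$edges[1, ]), 0)
})

test_that("kNN retention keeps k outgoing edges, ties to smaller index", {
  co <- cbind(c(0, 1, 2), 0)          # collinear, equally spaced
  D <- compute_distance_matrix(co)
  s <- structure(list(lr = list(id = "p"), E_l = rep(1, 3),
                      E_r = rep(1, 3)), class = "lr_summary")
  v <- build_ccc_view(s, D, k = 1)
  # middle cell is tied between both ends; smaller index wins
  expect_equal(Matrix::rowSums(v$edges != 0), c(1, 1, 1),
               ignore_attr = TRUE)
  expect_true(v$edges[2, 1] > 0)
  expect_equal(v$edges[2, 3], 0)
})

test_that("sparse view equals the dense entrywise formula when k = n - 1", {
  set.seed(42)
  for (n in c(5, 10)) {
    co <- matrix(runif(2 * n, 0, 10), n, 2)
    E_l <- rpois(n, 3); E_r <- rpois(n, 3)
    D <- compute_distance_matrix(co)
    s <- structure(list(lr = list(id = "p"), E_l = E_l, E_r = E_r),
                   class = "lr_summary")
    v <- build_ccc_view(s, D, k = n - 1)
    dense <- outer(E_l, E_r) / D
    diag(dense) <- 0
    expect_equal(as.matrix(v$edges), dense, ignore_attr = TRUE)
  }
})

test_that("edge weights scale inversely with a coordinate rescaling", {
  set.seed(3)
  co <- matrix(runif(16, 0, 10), 8, 2)
  E <- rpois(8, 4) + 1
  s <- structure(list(lr = list(id = "p"), E_l = E, E_r = rev(E)),
                 class = "lr_summary")
  v1 <- build_ccc_view(s, compute_distance_matrix(co), k = 3)
  v2 <- build_ccc_view(s, compute_distance_matrix(co * 2.5), k = 3)
  expect_equal(as.matrix(v2$edges) * 2.5, as.matrix(v1$edges))
})

test_that("multiview assembly is deterministic and errors when empty", {
  ds <- small_sim()
  mv1 <- assemble_multiview(ds$data, ds$lr, theta = 0.15, k = 5)
  mv2 <- assemble_multiview(ds$data, ds$lr, theta = 0.15, k = 5)
  expect_identical(names(mv1$views), sort(names(mv1$views)))
  expect_identical(lapply(mv1$views, `[[`, "edges"),
                   lapply(mv2$views, `[[`, "edges"))
  expect_gte(length(mv1$views), 1)
  expect_error(assemble_multiview(ds$data, ds$lr, theta = 0.999),
               "no active LR pairs")

  # lowering theta never shrinks the active set
  lo <- assemble_multiview(ds$data, ds$lr, theta = 0.05)
  expect_true(all(names(mv1$views) %in% names(lo$views)))
})
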