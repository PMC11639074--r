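test_that("splits hold out 10% + 10% of non-zeros and partition them", {
  X <- matrix(0, 10, 20)
  X[sample(200, 100)] <- 1
  splits <- make_splits(X, 3, seed = 2)
  nz <- which(X != 0)
  for (s in splits) {
    expect_length(s$test, 10)
    expect_length(s$val, 10)
    expect_length(s$train, 80)
    expect_length(intersect(s$test, s$val), 0)
    expect_length(intersect(s$test, s$train), 0)
    expect_setequal(c(s$train, s$val, s$test), nz)
  }
  expect_false(identical(sort(splits[[1]]$test), sort(splits[[2]]$test)))
  expect_error(make_splits(matrix(c(1, rep(0, 8)), 3, 3), 1, 1), "too few")
})

test_that("imputation metrics match hand values", {
  m <- imputation_metrics(matrix(1), matrix(3), 1)
  expect_equal(m$l1, 2); expect_equal(m$rmse, 2); expect_equal(m$cosine, 1)
  m2 <- imputation_metrics(rbind(c(0, 1)), rbind(c(1, 0)), 1:2)
  expect_equal(m2$l1, 1); expect_equal(m2$rmse, 1)
  expect_equal(m2$cosine, 0)
  full <- matrix(rnorm(6), 2, 3)
  m3 <- imputation_metrics(full, full, 1:6)
  expect_equal(unlist(m3), c(l1 = 0, rmse = 0, cosine = 1))
  expect_error(imputation_metrics(matrix(0), matrix(1), 1), "zero-norm")
  # permutation invariance in the index set
  idx <- c(5, 2, 4)
  a <- matrix(rnorm(6), 2, 3); b <- matrix(rnorm(6), 2, 3)
  expect_equal(imputation_metrics(a, b, idx),
               imputation_metrics(a, b, rev(idx)))
})

test_that("ranking metrics match hand values on small lists", {
  rk <- function(ids) data.frame(lr_id = ids,
                                 psi = rev(seq_along(ids)))
  perfect <- ranking_metrics(rk(c("b", "a")), "b", K = 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$ndcg, 1)
  worst <- ranking_metrics(rk(c("a", "b")), "b", K = 1)
  expect_equal(worst$precision, 0)
  expect_equal(worst$ndcg, 1 / log2(3))
  expect_equal(worst$kendall, -1)
  expect_equal(ranking_metrics(rk(c("b", "a")), "b", K = 1)$kendall, 1)
  expect_error(ranking_metrics(rk(c("a", "b")), "zzz"), "no relevant")
})

test_that("ranking metrics agree with brute force over all permutations", {
  ids <- c("a", "b", "c", "d")
  relevant <- c("b", "d")
  perms <- combinat_perms <- NULL
  allp <- as.matrix(expand.grid(rep(list(1:4), 4)))
  allp <- allp[apply(allp, 1, function(r) length(unique(r)) == 4), ]
  for (i in seq_len(nrow(allp))) {
    ord <- allp[i, ]
    ranking <- data.frame(lr_id = ids[ord], psi = rev(seq_along(ids)))
    got <- ranking_metrics(ranking, relevant, K = 2)
    rel <- as.numeric(ids[ord] %in% relevant)
    # brute force: definitional DCG / IDCG and precision
    dcg <- sum(rel / log2(1 + seq_along(rel)))
    idcg <- sum(1 / log2(1 + seq_len(sum(rel))))
    expect_equal(got$ndcg, dcg / idcg)
    expect_equal(got$precision, sum(rel[1:2]) / 2)
    expect_equal(got$spearman, suppressWarnings(
      cor(rev(seq_along(ids)), rel, method = "spearman")))
    expect_equal(got$kendall, suppressWarnings(
      cor(rev(seq_along(ids)), rel, method = "kendall")))
  }
})

test_that("metrics hit their ideal and floor values", {
  ids <- paste0("p", 1:6)
  relevant <- c("p1", "p2")
  best <- data.frame(lr_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
                     psi = 6:1)
  worst <- data.frame(lr_id = c("p3", "p4", "p5", "p6", "p1", "p2"),
                      psi = 6:1)
  b <- ranking_metrics(best, relevant, K = 2)
  expect_equal(b$precision, 1); expect_equal(b$ndcg, 1)
  expect_equal(b$spearman > 0, TRUE)
  w <- ranking_metrics(worst, relevant, K = 2)
  floor_ndcg <- (1 / log2(6) + 1 / log2(7)) / (1 / log2(2) + 1 / log2(3))
  expect_equal(w$ndcg, floor_ndcg)
  expect_equal(w$precision, 0)
  expect_lt(w$kendall, 0)
})

test_that("the random baseline lands near its expected precision", {
  ds <- small_sim(seed = 30, n_cells = 200, n_lr_pairs = 10, n_genes = 20)
  rb <- score_random_baseline(ds, K = 5, seed = 1)
  # one relevant pair among 10, K = 5: expected precision 0.5/5 = 0.1
  expect_equal(rb$precision, 0.1, tolerance = 0.05)
  expect_lt(rb$ndcg, 0.6)
})

test_that("benchmark produces a full report and beats the random arm", {
  ds <- small_sim(seed = 31, n_cells = 90, n_lr_pairs = 5, n_genes = 15)
  cfg <- run_config(seed = 1, max_epochs = 120, max_iterations = 2)
  bench <- benchmark_run(ds, cfg, n_replicates = 2, K = 3, seed = 4)
  expect_setequal(unique(bench$report$arm), c("model", "random"))
  expect_equal(sum(bench$report$arm == "model"),
               2 * 7)  # 3 imputation + 4 ranking metrics per replicate
  get <- function(arm, metric)
    bench$summary$mean[bench$summary$arm == arm &
                       bench$summary$metric == metric]
  expect_gt(get("model", "ndcg"), get("random", "ndcg"))
})
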