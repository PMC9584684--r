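test_that("the transfer function is the slope-2 logistic", {
  expect_equal(transfer(0), 0.5)
  expect_equal(transfer(1), 0.8807971, tolerance = 1e-6)
  x <- seq(-6, 6, by = 0.25)
  expect_equal(transfer(-x), 1 - transfer(x))
  expect_true(all(diff(transfer(x)) > 0))
})

test_that("binarization follows the printed threshold rule and repairs empty rows", {
  pos <- matrix(c(-2, 0, 3, 1), 2, 2)
  # u = 1 everywhere: 1 >= T(x) always, so all bits on
  expect_equal(binarize(pos, u = matrix(1, 2, 2)),
               matrix(1L, 2, 2))
  # u = 0 everywhere: 0 < T(x) always, all rows empty, each repaired to
  # exactly one selected feature
  set.seed(1)
  rep_bits <- binarize(matrix(0, 3, 5), u = matrix(0, 3, 5))
  expect_true(all(rep_bits %in% c(0L, 1L)))
  expect_equal(unname(rowSums(rep_bits)), rep(1, 3))

  # x = 0 selects with probability 1 - T(0) = 0.5
  set.seed(2)
  bits <- binarize(matrix(0, 1, 1e5))
  phat <- mean(bits)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 1e5))

  # large positive coordinates are selected rarely (the printed direction)
  set.seed(3)
  expect_lt(mean(binarize(matrix(4, 1, 1e4))), 0.01)
})

test_that("euclidean distance matches the brute-force oracle", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(1:5, 1:5), 0)
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(10)
    y <- rnorm(10)
    acc <- 0
    for (k in 1:10) acc <- acc + (x[k] - y[k])^2
    expect_equal(euclidean_distance(x, y), sqrt(acc))
  }
  expect_error(euclidean_distance(1:3, 1:4), "equal length")
})

test_that("fold assignment is stratified, seeded, and shrinks with tiny classes", {
  labels <- factor(rep(c("a", "b"), each = 20))
  f1 <- make_cv_folds(labels, 10, seed = 3)
  f2 <- make_cv_folds(labels, 10, seed = 3)
  expect_identical(f1, f2)
  expect_equal(f1$folds, 10)
  # each fold holds 2 per class
  tab <- table(f1$fold_id, labels)
  expect_true(all(tab == 2))

  small <- factor(c(rep("a", 12), rep("b", 3)))
  expect_warning(fs <- make_cv_folds(small, 10, seed = 1), "reducing folds")
  expect_equal(fs$folds, 3)
})

test_that("knn CV error agrees with the brute-force oracle and known cases", {
  ds <- make_separable_dataset()
  mask_inf <- c(rep(1, 3), rep(0, 7))
  # disjoint supports with a wide margin: zero error on informative features
  expect_equal(knn_cv_error(ds, mask_inf, k = 1, folds = 4, seed = 1), 0)

  # random masks against the oracle
  set.seed(21)
  fold_id <- make_cv_folds(ds$labels, 4, seed = 5)$fold_id
  for (i in 1:5) {
    mask <- as.integer(runif(10) < 0.5)
    if (!any(mask == 1)) mask[1] <- 1L
    expect_equal(knn_cv_error(ds, mask, k = 1, fold_id = fold_id),
                 oracle_knn1_cv(ds$matrix, ds$labels, fold_id, mask))
  }

  # feature-order invariance: permuting columns and the mask together
  perm <- sample(10)
  ds_perm <- list(matrix = ds$matrix[, perm], labels = ds$labels)
  expect_equal(knn_cv_error(ds_perm, mask_inf[perm], fold_id = fold_id),
               knn_cv_error(ds, mask_inf, fold_id = fold_id))

  expect_error(knn_cv_error(ds, rep(0, 10)), "no features")
})

test_that("a duplicated training point forces a correct 1-NN prediction", {
  X <- rbind(c(0, 0), c(0, 0), c(9, 9), c(9, 9), c(0.1, 0), c(9.1, 9))
  labels <- factor(c("a", "a", "b", "b", "a", "b"))
  # folds chosen so every test point has an exact duplicate in training
  fold_id <- c(1, 2, 1, 2, 1, 2)
  err <- knn_cv_error(list(matrix = X, labels = labels), c(1, 1),
                      fold_id = fold_id)
  expect_equal(err, 0)
})

test_that("subset fitness is the stated linear trade-off and is monotone", {
  expect_equal(subset_fitness(0, 1, 2000), 2.5e-5)
  expect_equal(subset_fitness(1, 2000, 2000), 1)
  expect_equal(subset_fitness(0.1, 50, 2000), 0.09625)

  w <- fitness_weights()
  expect_lt(subset_fitness(0.1, 10, 100, w), subset_fitness(0.1, 11, 100, w))
  expect_lt(subset_fitness(0.1, 10, 100, w), subset_fitness(0.2, 10, 100, w))

  expect_error(fitness_weights(0.9, 0.2), "equal 1")
  expect_error(subset_fitness(0.5, 0, 10))
})

test_that("the wrapper returns a self-consistent, reproducible result", {
  ds <- make_separable_dataset(n = 30, p = 12, n_inf = 3, gap = 8, seed = 4)
  cfg <- glsma_config(pop_size = 10, max_evals = 800, seed = 11)
  res <- run_bglsma(ds, cfg, folds = 5)
  expect_s3_class(res, "feature_selection_result")
  expect_gte(res$n_selected, 1)
  expect_equal(res$n_selected, sum(res$mask))
  # reported fitness must equal the trade-off recomputed from the mask
  expect_equal(res$fitness,
               subset_fitness(res$cv_error, res$n_selected, 12),
               tolerance = 1e-12)
  expect_true(all(diff(res$trace$best_fitness) <= 0))
  expect_identical(selected_genes(res), names(res$mask)[res$mask])

  res2 <- run_bglsma(ds, cfg, folds = 5)
  expect_identical(res$mask, res2$mask)
  expect_identical(res$fitness, res2$fitness)
})

test_that("degenerate inputs to the wrapper are rejected", {
  ds <- make_separable_dataset()
  one_class <- list(matrix = ds$matrix, labels = factor(rep("a", 24)))
  expect_error(run_bglsma(one_class, glsma_config(max_evals = 200)),
               "2 classes")
})
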