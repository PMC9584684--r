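# Shared fixtures: tiny objectives and independent oracles used across tests.

sphere <- function(x) sum(x^2)

# small, clearly separable two-class dataset: class means differ only on the
# first `n_inf` features
make_separable_dataset <- function(n = 24, p = 10, n_inf = 3, gap = 8,
                                   seed = 1) {
  set.seed(seed)
  labels <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(rnorm(n * p), n, p)
  X[labels == "b", seq_len(n_inf)] <- X[labels == "b", seq_len(n_inf)] + gap
  colnames(X) <- paste0("g", seq_len(p))
  list(matrix = X, labels = labels)
}

# brute-force 1-NN CV error: loops over every test point and every training
# point with the plain distance formula (independent of the package's
# distance-matrix path)
oracle_knn1_cv <- function(X, labels, fold_id, mask) {
  X <- X[, as.logical(mask), drop = FALSE]
  n <- nrow(X)
  wrong <- 0
  for (i in seq_len(n)) {
    train <- which(fold_id != fold_id[i])
    dists <- vapply(train, function(j) sqrt(sum((X[i, ] - X[j, ])^2)),
                    numeric(1))
    pred <- labels[train[which.min(dists)]]
    if (pred != labels[i]) wrong <- wrong + 1
  }
  wrong / n
}

# exact two-sided signed-rank p value by enumerating every sign assignment
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  t_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t_all <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(t_all <= t_obs), mean(t_all >= t_obs)))
}
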