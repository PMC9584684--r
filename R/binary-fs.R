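# Binary wrapper feature selection (BGLSMA): the continuous optimizer
# searches a D-dimensional box, each agent is mapped to a gene subset by a
# logistic transfer rule, and subsets are scored by the stratified
# cross-validated error of a k-nearest-neighbour classifier combined with
# the selected-feature fraction.

#' Fitness weights for wrapper feature selection
#'
#' The subset fitness is `alpha_w * error + beta_w * selected / total`;
#' accuracy is weighted far above subset size (0.95 / 0.05 by default).
#'
#' @param alpha_w weight of the cross-validated error rate.
#' @param beta_w weight of the selected-feature fraction.
#' @return An object of class `fitness_weights`.
#' @export
fitness_weights <- function(alpha_w = 0.95, beta_w = 0.05) {
  stopifnot(alpha_w >= 0, alpha_w <= 1, beta_w >= 0, beta_w <= 1)
  if (abs(alpha_w + beta_w - 1) > 1e-12) {
    stop("alpha_w + beta_w must equal 1", call. = FALSE)
  }
  structure(list(alpha_w = alpha_w, beta_w = beta_w),
            class = "fitness_weights")
}

#' Logistic transfer function
#'
#' `T(x) = 1 / (1 + exp(-2 x))`: strictly increasing, range (0, 1),
#' `T(0) = 0.5`. Maps a continuous coordinate to the threshold against
#' which a uniform draw decides the corresponding bit.
#'
#' @param x numeric vector.
#' @return Values in (0, 1).
#' @export
transfer <- function(x) 1 / (1 + exp(-2 * x))

#' Binarize continuous positions into feature masks
#'
#' Per element, the bit is 1 iff a fresh uniform(0, 1) draw is `>= T(x)`,
#' so *large positive* coordinates give low selection probability — the
#' rule's direction is what drives the strong sparsity of the selected
#' subsets. Any all-zero row is repaired by switching one uniformly chosen
#' bit on (the classifier needs at least one feature).
#'
#' @param positions numeric matrix (agents x features) or vector.
#' @param u optional matrix of uniform draws, for deterministic testing.
#' @return An integer 0/1 matrix of the same shape.
#' @export
binarize <- function(positions, u = NULL) {
  if (!is.matrix(positions)) positions <- matrix(positions, nrow = 1)
  n <- nrow(positions)
  d <- ncol(positions)
  if (is.null(u)) u <- matrix(stats::runif(n * d), n, d)
  stopifnot(all(dim(u) == dim(positions)))
  bits <- matrix(as.integer(u >= transfer(positions)), n, d)
  empty <- which(rowSums(bits) == 0L)
  for (i in empty) bits[i, sample.int(d, 1)] <- 1L
  bits
}

#' Euclidean distance between two vectors
#'
#' The classifier's distance, `sqrt(sum((x - y)^2))`.
#'
#' @param x,y numeric vectors of equal length.
#' @return A non-negative scalar.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  sqrt(sum((x - y)^2))
}

#' Stratified cross-validation fold assignment
#'
#' Shuffles within each class and deals samples round-robin into folds, so
#' fold class proportions match the data. When the smallest class has fewer
#' members than `folds`, the fold count is reduced with a warning.
#'
#' @param labels factor of class labels.
#' @param folds requested fold count.
#' @param seed integer seed for the shuffle.
#' @return A list with `fold_id` (integer vector) and `folds` (the count
#'   actually used).
#' @export
make_cv_folds <- function(labels, folds = 10, seed = 1) {
  labels <- as.factor(labels)
  min_class <- min(table(labels))
  if (min_class < folds) {
    warning(sprintf("smallest class has %d members; reducing folds from %d to %d",
                    min_class, folds, min_class))
    folds <- min_class
  }
  if (folds < 2) stop("need at least 2 folds", call. = FALSE)
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  list(fold_id = fold_id, folds = folds)
}

# k-NN CV error from a precomputed full distance matrix and fold ids.
# k = 1 takes the single nearest training sample; for k > 1, majority vote
# with ties broken by the nearest neighbour among the tied classes.
.knn_cv_from_dist <- function(Dm, labels, fold_id, k = 1) {
  n <- length(labels)
  errors <- 0L
  for (f in unique(fold_id)) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    sub <- Dm[te, tr, drop = FALSE]
    if (k == 1) {
      pred <- labels[tr[max.col(-sub, ties.method = "first")]]
    } else {
      pred <- labels[vapply(seq_along(te), function(i) {
        nn <- tr[order(sub[i, ])[seq_len(min(k, length(tr)))]]
        votes <- table(as.integer(labels[nn]))
        top <- as.integer(names(votes)[votes == max(votes)])
        if (length(top) > 1) {
          # nearest neighbour among tied classes decides
          first_of_tied <- nn[as.integer(labels[nn]) %in% top][1]
          as.integer(labels[first_of_tied])
        } else top
      }, integer(1))]
    }
    errors <- errors + sum(pred != labels[te])
  }
  errors / n
}

#' Cross-validated k-NN error of a feature subset
#'
#' Stratified k-fold cross-validation of a k-nearest-neighbour classifier
#' restricted to the masked features, using Euclidean distance.
#' Deterministic given `seed` (or an explicit `fold_id`).
#'
#' @param data an [expression_dataset][generate_expression_dataset], or any
#'   list with a numeric `matrix` (samples x features) and `labels`.
#' @param mask logical or 0/1 vector selecting features; must select at
#'   least one.
#' @param k neighbour count (1 by default).
#' @param folds fold count (10 by default).
#' @param seed seed for the fold shuffle.
#' @param fold_id optional precomputed fold assignment (overrides
#'   `folds`/`seed`); used to share one partition across many subset
#'   evaluations so fitness comparisons are paired.
#' @return The misclassification rate in `[0, 1]`.
#' @export
knn_cv_error <- function(data, mask, k = 1, folds = 10, seed = 1,
                         fold_id = NULL) {
  X <- data$matrix
  labels <- as.factor(data$labels)
  mask <- as.logical(mask)
  stopifnot(length(mask) == ncol(X))
  if (!any(mask)) stop("mask selects no features", call. = FALSE)
  if (is.null(fold_id)) {
    fold_id <- make_cv_folds(labels, folds, seed)$fold_id
  }
  Dm <- as.matrix(stats::dist(X[, mask, drop = FALSE]))
  .knn_cv_from_dist(Dm, labels, fold_id, k)
}

#' Subset fitness
#'
#' `alpha_w * cv_error + beta_w * n_selected / n_total`: the scalarized
#' trade-off between classification error and subset size that the binary
#' optimizer minimizes.
#'
#' @param cv_error error rate in `[0, 1]`.
#' @param n_selected number of selected features (>= 1).
#' @param n_total total number of features.
#' @param w a [fitness_weights()] object.
#' @return The fitness value.
#' @export
subset_fitness <- function(cv_error, n_selected, n_total,
                           w = fitness_weights()) {
  stopifnot(cv_error >= 0, cv_error <= 1, n_selected >= 1,
            n_selected <= n_total)
  w$alpha_w * cv_error + w$beta_w * n_selected / n_total
}

#' Binary GLSMA wrapper feature selection
#'
#' Runs the boosted slime mould optimizer over a continuous box of one
#' coordinate per gene (bounds `[-4, 4]`, spanning the transfer function's
#' effective range); before each fitness evaluation the agent is binarized
#' by the stochastic transfer rule, and the resulting subset is scored by
#' `alpha_w * knn_cv_error + beta_w * n_selected / D`. One stratified fold
#' partition, fixed by the run seed, is shared by all evaluations so subset
#' fitnesses are paired. Returns the best subset ever evaluated.
#'
#' @param data an [expression_dataset][generate_expression_dataset] (or
#'   compatible list) with at least 2 classes.
#' @param cfg a [glsma_config()]; `NULL` gives the defaults
#'   `pop_size = 30`, `max_evals = 10000`, bounds `[-4, 4]`, `seed = 1`.
#'   `dim`, `lower` and `upper` are always taken from the data / the
#'   transfer rule.
#' @param w a [fitness_weights()] object.
#' @param k neighbour count for the classifier.
#' @param folds cross-validation fold count.
#' @return An object of class `feature_selection_result`: `mask` (logical,
#'   named by gene), `n_selected`, `cv_error`, `fitness`, a per-iteration
#'   fitness `trace`, and fold/seed metadata.
#' @examples
#' ds <- generate_expression_dataset(40, 50, 2, 4, 4, 1, seed = 1)
#' res <- run_bglsma(ds, glsma_config(max_evals = 1200, seed = 1))
#' res$n_selected
#' @export
run_bglsma <- function(data, cfg = NULL, w = fitness_weights(), k = 1,
                       folds = 10) {
  X <- data$matrix
  labels <- as.factor(data$labels)
  D <- ncol(X)
  if (D < 1) stop("data has no features", call. = FALSE)
  if (nlevels(labels) < 2) {
    stop("feature selection needs at least 2 classes", call. = FALSE)
  }
  if (is.null(cfg)) cfg <- glsma_config(max_evals = 10000)
  cfg$dim <- D
  cfg$lower <- -4
  cfg$upper <- 4

  fold_id <- make_cv_folds(labels, folds, cfg$seed)$fold_id

  state <- new.env(parent = emptyenv())
  state$fitness <- Inf
  Xsq <- X * X
  objective <- function(x) {
    mask <- as.logical(binarize(matrix(x, nrow = 1))[1, ])
    R <- sum(mask)
    # squared masked Euclidean distances via the Gram matrix; neighbour
    # ranking is invariant to the square root
    Xm <- X[, mask, drop = FALSE]
    s <- rowSums(Xsq[, mask, drop = FALSE])
    D2 <- outer(s, s, "+") - 2 * tcrossprod(Xm)
    E <- .knn_cv_from_dist(D2, labels, fold_id, k)
    fit <- w$alpha_w * E + w$beta_w * R / D
    if (fit < state$fitness) {
      state$fitness <- fit
      state$mask <- mask
      state$cv_error <- E
    }
    fit
  }

  res <- run_glsma(objective, cfg)
  stopifnot(isTRUE(all.equal(res$best_fitness, state$fitness)))
  mask <- state$mask
  names(mask) <- colnames(X)
  structure(list(mask = mask,
                 n_selected = sum(mask),
                 cv_error = state$cv_error,
                 fitness = state$fitness,
                 trace = res$trace[, c("iteration", "evals", "best_fitness")],
                 weights = w, k = k,
                 folds = length(unique(fold_id)),
                 fold_id = fold_id,
                 n_evals = res$n_evals,
                 seed = cfg$seed),
            class = "feature_selection_result")
}

#' @export
print.feature_selection_result <- function(x, ...) {
  cat(sprintf("<feature selection: %d gene(s) selected, CV error %.4f, fitness %.6f (%d evaluations, seed %d)>\n",
              x$n_selected, x$cv_error, x$fitness, x$n_evals, x$seed))
  invisible(x)
}

#' Selected gene identifiers
#'
#' @param result a `feature_selection_result`.
#' @return Character vector of selected gene names.
#' @export
selected_genes <- function(result) {
  names(result$mask)[result$mask]
}
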