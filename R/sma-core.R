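# Core slime mould algorithm (SMA): oscillation weights W, control parameters
# a/b, decision parameter p, and the three-branch position update. The shared
# engine also hosts the Gaussian-mutation and Levy-flight operators so that
# the boosted variant and the plain algorithm follow identical draw
# discipline; run_sma() simply disables both operators.

#' Optimizer configuration
#'
#' Bundles the parameters of a slime mould run. Defaults follow the standard
#' experimental protocol: a population of 30 searchers, a budget of 300,000
#' objective-function evaluations, and reinitialization probability
#' `z = 0.03`.
#'
#' @param pop_size population size (>= 2).
#' @param max_evals total objective-evaluation budget (the unit in which
#'   search effort is fixed; iterations are derived from it).
#' @param z probability that an agent is reinitialized uniformly in the
#'   search box, in (0, 1).
#' @param lower,upper scalar box bounds (applied to every coordinate) or
#'   vectors of length `dim`.
#' @param dim problem dimension.
#' @param seed integer RNG seed; every source of randomness in a run flows
#'   from it.
#' @param log_evals keep a log of every objective value evaluated (memory
#'   heavy; intended for small diagnostic runs).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(pop_size = 30, max_evals = 300000, z = 0.03,
                             lower = -100, upper = 100, dim = 30, seed = 1,
                             log_evals = FALSE) {
  stopifnot(pop_size >= 2, max_evals >= pop_size, z > 0, z < 1, dim >= 1)
  if (any(upper <= lower)) stop("upper bound must exceed lower bound")
  structure(list(pop_size = as.integer(pop_size),
                 max_evals = as.integer(max_evals),
                 z = z, lower = lower, upper = upper,
                 dim = as.integer(dim), seed = as.integer(seed),
                 log_evals = isTRUE(log_evals)),
            class = "optimizer_config")
}

#' Control parameters a and b of the oscillation schedule
#'
#' `a = arctanh(1 - t / max_t)` bounds the exploration velocity `vb`;
#' `b = 1 - t / max_t` bounds the contraction velocity `vc`. Both decay to 0
#' at the final iteration. `t` is clamped to `[1, max_t]` so the schedule is
#' finite at every iteration.
#'
#' @param t current iteration (1-based).
#' @param max_t total number of iterations.
#' @return Named numeric vector `c(a = , b = )`, both non-negative.
#' @export
compute_control_params <- function(t, max_t) {
  stopifnot(max_t >= 1)
  t <- min(max(t, 1), max_t)
  frac <- 1 - t / max_t
  c(a = atanh(frac), b = frac)
}

#' Decision parameter p
#'
#' `p = tanh(|S_i - DF|)`: the probability threshold that routes an agent to
#' the best-position-guided branch. Agents whose fitness is far from the
#' best-so-far `DF` take guided steps almost surely; agents at the optimum
#' (p = 0) contract instead.
#'
#' @param S_i fitness of the agent.
#' @param DF best fitness attained over all iterations.
#' @return A value in `[0, 1)`.
#' @export
compute_p <- function(S_i, DF) tanh(abs(S_i - DF))

#' Oscillation weights W
#'
#' Given the population fitness sorted ascending (best first for
#' minimization), the better half receives weights
#' `1 + r * log10((bF - S) / (bF - wF + eps) + 1)` and the rest
#' `1 - r * log10(...)`, with `r` a fresh uniform(0, 1) draw per element and
#' `eps = 2.2e-16` guarding the degenerate all-equal-fitness case.
#'
#' @param sorted_fitness numeric vector, ascending.
#' @param dim dimension (number of weight columns per agent).
#' @param r optional matrix of `length(sorted_fitness) x dim` uniform draws,
#'   for deterministic testing; by default drawn from the current RNG stream.
#' @return A `length(sorted_fitness) x dim` weight matrix whose rows are in
#'   sorted-fitness order.
#' @export
compute_weights <- function(sorted_fitness, dim, r = NULL) {
  n <- length(sorted_fitness)
  bF <- sorted_fitness[1]
  wF <- sorted_fitness[n]
  if (is.null(r)) r <- matrix(stats::runif(n * dim), n, dim)
  ratio <- (bF - sorted_fitness) / (bF - wF + 2.2e-16)
  # the eps guard targets bF == wF; when bF - wF is a tiny negative number of
  # eps's magnitude the ratio degenerates (0/0, negative, or infinite) -- the
  # correct limit there is a unit weight, so clamp those elements to 0
  ratio[!is.finite(ratio) | ratio < 0] <- 0
  lg <- log10(ratio + 1)
  W <- matrix(1, n, dim)
  half <- seq_len(floor(n / 2))
  rest <- setdiff(seq_len(n), half)
  W[half, ] <- 1 + r[half, , drop = FALSE] * lg[half]
  W[rest, ] <- 1 - r[rest, , drop = FALSE] * lg[rest]
  W
}

#' Three-branch SMA position update
#'
#' Per agent: with probability `z` the agent is reinitialized uniformly in
#' the box. Otherwise each coordinate `j` independently takes the guided
#' step `X_b[j] + vb[j] * (W[i, j] * X_A[j] - X_B[j])` with probability `p`
#' (computed from the agent's fitness), or contracts as `vc[j] * X[i, j]`,
#' with `vb ~ U[-a, a]`, `vc ~ U[-b, b]` per dimension and `X_A`, `X_B`
#' drawn with replacement from the population per dimension. Results are
#' clipped to the box.
#'
#' @param X `n x dim` matrix of current positions.
#' @param fitness length-`n` fitness vector for the rows of `X`.
#' @param W `n x dim` weight matrix in agent order (not sorted order).
#' @param Xb best position found so far.
#' @param DF best fitness found so far.
#' @param a,b control parameters for the current iteration.
#' @param z reinitialization probability.
#' @param lower,upper box bounds.
#' @return `n x dim` matrix of updated, in-bounds positions.
#' @export
sma_position_update <- function(X, fitness, W, Xb, DF, a, b, z,
                                lower, upper) {
  n <- nrow(X)
  d <- ncol(X)
  lb <- rep_len(lower, d)
  ub <- rep_len(upper, d)
  Xnew <- X
  for (i in seq_len(n)) {
    if (stats::runif(1) < z) {
      # one shared draw across coordinates, as in the update equation:
      # restarts sample the main diagonal of the box
      Xnew[i, ] <- lb + stats::runif(1) * (ub - lb)
    } else {
      p <- compute_p(fitness[i], DF)
      vb <- stats::runif(d, -a, a)
      vc <- stats::runif(d, -b, b)
      r <- stats::runif(d)
      A <- sample.int(n, d, replace = TRUE)
      B <- sample.int(n, d, replace = TRUE)
      guided <- Xb + vb * (W[i, ] * X[cbind(A, seq_len(d))] -
                             X[cbind(B, seq_len(d))])
      Xnew[i, ] <- ifelse(r < p, guided, vc * X[i, ])
    }
  }
  clip_to_bounds(Xnew, lb, ub)
}

# clip a position matrix (or vector) into [lower, upper]
clip_to_bounds <- function(X, lower, upper) {
  if (is.matrix(X)) {
    d <- ncol(X)
    lb <- rep_len(lower, d)
    ub <- rep_len(upper, d)
    X <- pmax(X, matrix(lb, nrow(X), d, byrow = TRUE))
    pmin(X, matrix(ub, nrow(X), d, byrow = TRUE))
  } else {
    pmin(pmax(X, rep_len(lower, length(X))), rep_len(upper, length(X)))
  }
}

# resolve an objective argument: benchmark_function or plain function
.resolve_objective <- function(objective, cfg) {
  if (inherits(objective, "benchmark_function")) {
    if (is.null(cfg)) {
      cfg <- optimizer_config(lower = objective$lower,
                              upper = objective$upper,
                              dim = objective$dim)
    }
    list(fn = objective$fn, cfg = cfg)
  } else {
    stopifnot(is.function(objective), !is.null(cfg))
    list(fn = objective, cfg = cfg)
  }
}

# Shared engine. `ops` carries the operator switches; both run_sma and
# run_glsma call this, so disabling both operators reproduces plain SMA
# draw-for-draw.
.sma_engine <- function(objective, cfg, gaussian = FALSE, levy = FALSE,
                        beta_levy = 1.5, patience = 5L,
                        levy_mode = c("triggered", "always"),
                        algorithm = "sma") {
  levy_mode <- match.arg(levy_mode)
  pop <- cfg$pop_size
  d <- cfg$dim
  lb <- rep_len(cfg$lower, d)
  ub <- rep_len(cfg$upper, d)
  budget <- cfg$max_evals
  if (budget < 2L * pop) {
    stop("max_evals must cover at least initialization plus one generation (2 * pop_size)",
         call. = FALSE)
  }
  set.seed(cfg$seed)

  eval_rows <- function(X, idx) {
    vapply(idx, function(i) objective(X[i, ]), numeric(1))
  }

  # nominal iteration count used by the a/b schedule; operator evaluations
  # are charged to the same budget, so the loop may stop earlier
  max_t <- max(1L, as.integer(floor(budget / (pop * (1L + as.integer(gaussian))))))

  X <- matrix(stats::runif(pop * d, rep(lb, each = pop), rep(ub, each = pop)),
              pop, d)
  fit <- eval_rows(X, seq_len(pop))
  evals <- pop
  eval_log <- if (cfg$log_evals) fit else NULL

  best_i <- which.min(fit)
  DF <- fit[best_i]
  Xb <- X[best_i, ]
  stagnation <- 0L

  n_alloc <- max_t + 2L
  tr_t <- integer(n_alloc)
  tr_evals <- integer(n_alloc)
  tr_best <- numeric(n_alloc)
  tr_gauss <- logical(n_alloc)
  tr_levy <- logical(n_alloc)

  phi <- if (levy) levy_phi(beta_levy) else NA_real_

  t <- 0L
  while (evals + pop <= budget) {
    t <- t + 1L
    ab <- compute_control_params(t, max_t)

    ord <- order(fit)
    Wsorted <- compute_weights(fit[ord], d)
    W <- Wsorted
    W[ord, ] <- Wsorted

    X <- sma_position_update(X, fit, W, Xb, DF, ab["a"], ab["b"], cfg$z,
                             lb, ub)
    fit <- eval_rows(X, seq_len(pop))
    evals <- evals + pop
    if (cfg$log_evals) eval_log <- c(eval_log, fit)

    improved <- FALSE
    if (min(fit) < DF) {
      best_i <- which.min(fit)
      DF <- fit[best_i]
      Xb <- X[best_i, ]
      improved <- TRUE
    }

    gauss_fired <- FALSE
    if (gaussian && evals < budget) {
      m <- min(pop, budget - evals)
      G <- matrix(stats::rnorm(m * d), m, d)
      Xg <- clip_to_bounds(X[seq_len(m), , drop = FALSE] * (1 + G), lb, ub)
      fg <- eval_rows(Xg, seq_len(m))
      evals <- evals + m
      if (cfg$log_evals) eval_log <- c(eval_log, fg)
      acc <- fg < fit[seq_len(m)]
      if (any(acc)) {
        X[which(acc), ] <- Xg[which(acc), , drop = FALSE]
        fit[which(acc)] <- fg[which(acc)]
      }
      if (min(fit) < DF) {
        best_i <- which.min(fit)
        DF <- fit[best_i]
        Xb <- X[best_i, ]
        improved <- TRUE
      }
      gauss_fired <- TRUE
    }

    stagnation <- if (improved) 0L else stagnation + 1L

    levy_fired <- FALSE
    if (levy && evals < budget &&
        (levy_mode == "always" || stagnation >= patience)) {
      m <- min(pop, budget - evals)
      S <- t(vapply(seq_len(m), function(i) levy_sample(beta_levy, d, phi = phi),
                    numeric(d)))
      if (d == 1L) S <- matrix(S, m, 1L)
      Xl <- clip_to_bounds(X[seq_len(m), , drop = FALSE] * (1 + S), lb, ub)
      fl <- eval_rows(Xl, seq_len(m))
      evals <- evals + m
      if (cfg$log_evals) eval_log <- c(eval_log, fl)
      acc <- fl < fit[seq_len(m)]
      if (any(acc)) {
        X[which(acc), ] <- Xl[which(acc), , drop = FALSE]
        fit[which(acc)] <- fl[which(acc)]
      }
      if (min(fit) < DF) {
        best_i <- which.min(fit)
        DF <- fit[best_i]
        Xb <- X[best_i, ]
      }
      levy_fired <- TRUE
      stagnation <- 0L
    }

    tr_t[t] <- t
    tr_evals[t] <- evals
    tr_best[t] <- DF
    tr_gauss[t] <- gauss_fired
    tr_levy[t] <- levy_fired
  }

  keep <- seq_len(t)
  res <- list(best_position = Xb,
              best_fitness = DF,
              trace = data.frame(iteration = tr_t[keep],
                                 evals = tr_evals[keep],
                                 best_fitness = tr_best[keep],
                                 gaussian_fired = tr_gauss[keep],
                                 levy_fired = tr_levy[keep]),
              n_evals = evals,
              max_evals = budget,
              population = X,
              fitness = fit,
              seed = cfg$seed,
              algorithm = algorithm)
  if (cfg$log_evals) res$eval_log <- eval_log
  class(res) <- "sma_result"
  res
}

#' @export
print.sma_result <- function(x, ...) {
  cat(sprintf("<%s run: best fitness %.6g after %d evaluations (%d iterations), seed %d>\n",
              toupper(x$algorithm), x$best_fitness, x$n_evals,
              nrow(x$trace), x$seed))
  invisible(x)
}

#' Run the original slime mould algorithm
#'
#' Minimizes `objective` over the box in `cfg` with the plain three-branch
#' SMA update (no mutation operators). Fully reproducible from `cfg$seed`.
#'
#' @param objective a function mapping a numeric vector to a scalar, or a
#'   [benchmark_function][new_benchmark] (whose bounds and dimension supply
#'   the defaults when `cfg` is omitted).
#' @param cfg an [optimizer_config()]; may be `NULL` when `objective` is a
#'   benchmark.
#' @return An object of class `sma_result`: best position and fitness, a
#'   per-iteration best-so-far trace, the evaluation count, and the final
#'   population.
#' @examples
#' f1 <- get_benchmark("F1")
#' cfg <- optimizer_config(max_evals = 3000, dim = 30,
#'                         lower = -100, upper = 100, seed = 1)
#' res <- run_sma(f1, cfg)
#' res$best_fitness
#' @export
run_sma <- function(objective, cfg = NULL) {
  ro <- .resolve_objective(objective, cfg)
  .sma_engine(ro$fn, ro$cfg, gaussian = FALSE, levy = FALSE,
              algorithm = "sma")
}
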