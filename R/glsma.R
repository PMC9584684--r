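# Boosted slime mould algorithm: a Gaussian mutation operator that diversifies
# the population every generation, and a Levy-flight escape move invoked when
# the best-so-far fitness stagnates. Both operators are multiplicative
# (x * (1 + step)), are accepted greedily agent-by-agent, and charge their
# objective evaluations against the same budget as the base update.

#' Configuration for the boosted slime mould algorithm
#'
#' Extends [optimizer_config()] with the operator parameters: the Levy
#' stability index `beta_levy` (1.5 by default), the stagnation `patience`
#' (generations without best-fitness improvement before the Levy escape
#' fires), and switches that enable each operator independently, realizing
#' the GSMA (Gaussian only), LSMA (Levy only) and GLSMA (both) variants.
#'
#' @inheritParams optimizer_config
#' @param beta_levy Levy stability index, in (0, 2].
#' @param patience generations of unimproved best fitness before the Levy
#'   escape triggers (>= 1).
#' @param gaussian enable the Gaussian mutation operator.
#' @param levy enable the Levy flight operator.
#' @param levy_mode `"triggered"` fires Levy flight only on stagnation;
#'   `"always"` applies it every generation.
#' @return An object of class `glsma_config` (inherits `optimizer_config`).
#' @export
glsma_config <- function(pop_size = 30, max_evals = 300000, z = 0.03,
                         lower = -100, upper = 100, dim = 30, seed = 1,
                         beta_levy = 1.5, patience = 5, gaussian = TRUE,
                         levy = TRUE, levy_mode = c("triggered", "always"),
                         log_evals = FALSE) {
  stopifnot(beta_levy > 0, beta_levy <= 2, patience >= 1)
  cfg <- optimizer_config(pop_size = pop_size, max_evals = max_evals, z = z,
                          lower = lower, upper = upper, dim = dim,
                          seed = seed, log_evals = log_evals)
  cfg$beta_levy <- beta_levy
  cfg$patience <- as.integer(patience)
  cfg$gaussian <- isTRUE(gaussian)
  cfg$levy <- isTRUE(levy)
  cfg$levy_mode <- match.arg(levy_mode)
  class(cfg) <- c("glsma_config", class(cfg))
  cfg
}

#' Gaussian mutation
#'
#' Multiplicative perturbation `x * (1 + g)` with `g` drawn per dimension
#' from the standard normal. The caller clips the result to the search box.
#' Note the multiplicative form fixes the all-zero position.
#'
#' @param x numeric position vector.
#' @param g optional vector of normal draws (for deterministic testing); by
#'   default drawn from the current RNG stream.
#' @return The perturbed position.
#' @export
gaussian_perturb <- function(x, g = NULL) {
  if (is.null(g)) g <- stats::rnorm(length(x))
  stopifnot(length(g) == length(x))
  x * (1 + g)
}

#' Greedy acceptance
#'
#' Keeps the mutant only on strict improvement; ties retain the incumbent,
#' so every accepted move strictly lowers fitness.
#'
#' @param x_old,x_new incumbent and candidate positions.
#' @param objective objective function.
#' @param f_old,f_new optional precomputed fitness values (each `NULL` value
#'   triggers one objective evaluation).
#' @return A list with `position`, `fitness` (matching the returned
#'   position) and `accepted`.
#' @export
greedy_accept <- function(x_old, x_new, objective, f_old = NULL,
                          f_new = NULL) {
  if (is.null(f_old)) f_old <- objective(x_old)
  if (is.null(f_new)) f_new <- objective(x_new)
  if (f_new < f_old) {
    list(position = x_new, fitness = f_new, accepted = TRUE)
  } else {
    list(position = x_old, fitness = f_old, accepted = FALSE)
  }
}

#' Levy step scale
#'
#' The Mantegna scale
#' \deqn{\varphi = \left[\frac{\Gamma(1+\beta)\sin(\pi\beta/2)}
#'   {\Gamma((1+\beta)/2)\,\beta\,2^{(\beta-1)/2}}\right]^{1/\beta}}
#' used to generate heavy-tailed steps with stability index `beta`.
#'
#' @param beta stability index in (0, 2].
#' @return A strictly positive scalar.
#' @export
levy_phi <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0 || beta > 2) {
    stop("beta must be a scalar in (0, 2]", call. = FALSE)
  }
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Draw a vector of Levy-distributed steps
#'
#' Mantegna's algorithm: `s = phi * mu / |v|^(1/beta)` with `mu`, `v`
#' independent standard normals per dimension. The tail of `|s|` decays as
#' `c^(-beta)`.
#'
#' @param beta stability index in (0, 2].
#' @param dim number of steps.
#' @param mu,v optional normal draws (for deterministic testing).
#' @param phi optional precomputed [levy_phi()] value.
#' @return Numeric vector of length `dim`.
#' @export
levy_sample <- function(beta, dim, mu = NULL, v = NULL, phi = NULL) {
  if (is.null(phi)) phi <- levy_phi(beta)
  if (is.null(mu)) mu <- stats::rnorm(dim)
  if (is.null(v)) v <- stats::rnorm(dim)
  phi * mu / abs(v)^(1 / beta)
}

#' Levy flight perturbation
#'
#' Multiplicative heavy-tailed move `x * (1 + Levy(beta))`; occasional large
#' steps let an agent leave the basin it is trapped in. The caller clips to
#' bounds.
#'
#' @param x numeric position vector.
#' @param beta stability index.
#' @param steps optional precomputed Levy steps (for deterministic testing).
#' @return The perturbed position.
#' @export
levy_perturb <- function(x, beta = 1.5, steps = NULL) {
  if (is.null(steps)) steps <- levy_sample(beta, length(x))
  stopifnot(length(steps) == length(x))
  x * (1 + steps)
}

#' Run the boosted slime mould algorithm
#'
#' Per generation: the base SMA position update, then Gaussian mutation of
#' every agent with greedy acceptance, and — when the best-so-far fitness has
#' not improved for `patience` consecutive generations — a Levy-flight move
#' of every agent, also greedily accepted, after which the stagnation counter
#' resets. All operator evaluations are charged against `max_evals`.
#'
#' With both operators disabled the run reduces exactly to [run_sma()]
#' (identical trace under the same seed).
#'
#' @param objective a function or a [benchmark_function][new_benchmark].
#' @param cfg a [glsma_config()]; may be `NULL` when `objective` is a
#'   benchmark (defaults are then taken from it).
#' @return An `sma_result`; its `trace` records which operators fired each
#'   iteration.
#' @examples
#' f16 <- get_benchmark("F16")
#' cfg <- glsma_config(max_evals = 6000, dim = 2, lower = -5, upper = 5,
#'                     seed = 1)
#' run_glsma(f16, cfg)$best_fitness
#' @export
run_glsma <- function(objective, cfg = NULL) {
  if (inherits(objective, "benchmark_function") && is.null(cfg)) {
    cfg <- glsma_config(lower = objective$lower, upper = objective$upper,
                        dim = objective$dim)
  }
  if (!inherits(cfg, "glsma_config")) {
    stop("cfg must be a glsma_config()", call. = FALSE)
  }
  ro <- .resolve_objective(objective, cfg)
  algo <- if (cfg$gaussian && cfg$levy) "glsma"
          else if (cfg$gaussian) "gsma"
          else if (cfg$levy) "lsma"
          else "sma"
  .sma_engine(ro$fn, ro$cfg, gaussian = cfg$gaussian, levy = cfg$levy,
              beta_levy = cfg$beta_levy, patience = cfg$patience,
              levy_mode = cfg$levy_mode, algorithm = algo)
}
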