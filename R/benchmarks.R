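# Classical box-bounded test functions F1-F23 used to evaluate continuous
# metaheuristics: 7 unimodal (F1-F7, 30-D), 6 multimodal (F8-F13, 30-D) and
# 10 fixed-dimension multimodal functions (F14-F23, 2-6 D). Constant matrices
# for the foxholes, Kowalik, Hartmann and Shekel families follow the canonical
# De Jong / Dixon-Szego values.

# penalty term shared by F12/F13
.u_penalty <- function(x, a, k, m) {
  out <- numeric(length(x))
  hi <- x > a
  lo <- x < -a
  out[hi] <- k * (x[hi] - a)^m
  out[lo] <- k * (-x[lo] - a)^m
  out
}

# foxholes: a_ij, 2 x 25
.foxholes_a <- rbind(
  rep(c(-32, -16, 0, 16, 32), times = 5),
  rep(c(-32, -16, 0, 16, 32), each = 5)
)

# Kowalik: a_i and b_i (b given as inverse values)
.kowalik_a <- c(0.1957, 0.1947, 0.1735, 0.16, 0.0844, 0.0627,
                0.0456, 0.0342, 0.0323, 0.0235, 0.0246)
.kowalik_b <- 1 / c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16)

# Hartmann 3-D
.hart3_a <- matrix(c(3, 10, 30,
                     0.1, 10, 35,
                     3, 10, 30,
                     0.1, 10, 35), 4, 3, byrow = TRUE)
.hart3_c <- c(1, 1.2, 3, 3.2)
.hart3_p <- matrix(c(0.3689, 0.1170, 0.2673,
                     0.4699, 0.4387, 0.7470,
                     0.1091, 0.8732, 0.5547,
                     0.03815, 0.5743, 0.8828), 4, 3, byrow = TRUE)

# Hartmann 6-D
.hart6_a <- matrix(c(10, 3, 17, 3.5, 1.7, 8,
                     0.05, 10, 17, 0.1, 8, 14,
                     3, 3.5, 1.7, 10, 17, 8,
                     17, 8, 0.05, 10, 0.1, 14), 4, 6, byrow = TRUE)
.hart6_c <- c(1, 1.2, 3, 3.2)
.hart6_p <- matrix(c(0.1312, 0.1696, 0.5569, 0.0124, 0.8283, 0.5886,
                     0.2329, 0.4135, 0.8307, 0.3736, 0.1004, 0.9991,
                     0.2348, 0.1451, 0.3522, 0.2883, 0.3047, 0.6650,
                     0.4047, 0.8828, 0.8732, 0.5743, 0.1091, 0.0381),
                   4, 6, byrow = TRUE)

# Shekel: a_i (10 x 4) and c_i; F21/F22/F23 use the first 5/7/10 rows
.shekel_a <- matrix(c(4, 4, 4, 4,
                      1, 1, 1, 1,
                      8, 8, 8, 8,
                      6, 6, 6, 6,
                      3, 7, 3, 7,
                      2, 9, 2, 9,
                      5, 5, 3, 3,
                      8, 1, 8, 1,
                      6, 2, 6, 2,
                      7, 3.6, 7, 3.6), 10, 4, byrow = TRUE)
.shekel_c <- c(0.1, 0.2, 0.2, 0.4, 0.4, 0.6, 0.3, 0.7, 0.5, 0.5)

.shekel_fn <- function(m) {
  a <- .shekel_a[seq_len(m), , drop = FALSE]
  cc <- .shekel_c[seq_len(m)]
  function(x) {
    d2 <- colSums((t(a) - x)^2)
    -sum(1 / (d2 + cc))
  }
}

#' Construct one benchmark function
#'
#' @param name identifier such as `"F1"`.
#' @param dim dimension of the search space.
#' @param lower,upper scalar box bounds, applied to every coordinate.
#' @param fn evaluator mapping a `dim`-length numeric vector to a scalar.
#' @param fmin reference global minimum value.
#' @param xmin optional known minimizer (numeric vector of length `dim`).
#' @param stochastic `TRUE` when the evaluator draws random noise (F7).
#' @param fmin_decimals number of printed decimal places of `fmin`, used by
#'   consistency checks.
#' @return An object of class `benchmark_function`.
#' @keywords internal
new_benchmark <- function(name, dim, lower, upper, fn, fmin, xmin = NULL,
                          stochastic = FALSE, fmin_decimals = 4L) {
  structure(list(name = name, dim = as.integer(dim),
                 lower = lower, upper = upper,
                 fn = fn, fmin = fmin, xmin = xmin,
                 stochastic = stochastic,
                 fmin_decimals = as.integer(fmin_decimals)),
            class = "benchmark_function")
}

#' @export
print.benchmark_function <- function(x, ...) {
  cat(sprintf("<benchmark %s: dim %d, bounds [%g, %g], f_min %g>\n",
              x$name, x$dim, x$lower, x$upper, x$fmin))
  invisible(x)
}

#' The 23 classical benchmark functions
#'
#' Returns the standard suite of 23 box-bounded test problems: unimodal
#' F1-F7 (30-D), multimodal F8-F13 (30-D) and fixed-dimension multimodal
#' F14-F23. Each entry records its search range and reference minimum
#' (`fmin`), plus a known minimizer where one is standard.
#'
#' F7 adds uniform(0, 1) noise to each evaluation and is therefore the one
#' stochastic member of the suite. F16 is the six-hump camel-back with the
#' usual \eqn{-2.1 x_1^4} term.
#'
#' @return A named list of [benchmark_function][new_benchmark] objects,
#'   `"F1"` ... `"F23"`.
#' @examples
#' suite <- make_classical_suite()
#' evaluate_benchmark(suite$F1, rep(0, 30))
#' @export
make_classical_suite <- function() {
  fns <- list(
    # --- unimodal, 30-D ---
    new_benchmark("F1", 30, -100, 100, function(x) sum(x^2),
                  0, rep(0, 30), fmin_decimals = 0L),
    new_benchmark("F2", 30, -10, 10, function(x) sum(abs(x)) + prod(abs(x)),
                  0, rep(0, 30), fmin_decimals = 0L),
    new_benchmark("F3", 30, -100, 100, function(x) sum(cumsum(x)^2),
                  0, rep(0, 30), fmin_decimals = 0L),
    new_benchmark("F4", 30, -100, 100, function(x) max(abs(x)),
                  0, rep(0, 30), fmin_decimals = 0L),
    new_benchmark("F5", 30, -30, 30, function(x) {
      n <- length(x)
      sum(100 * (x[-1] - x[-n]^2)^2 + (x[-n] - 1)^2)
    }, 0, rep(1, 30), fmin_decimals = 0L),
    new_benchmark("F6", 30, -100, 100, function(x) sum(floor(x + 0.5)^2),
                  0, rep(0, 30), fmin_decimals = 0L),
    new_benchmark("F7", 30, -128, 128, function(x) {
      sum(seq_along(x) * x^4) + stats::runif(1)
    }, 0, NULL, stochastic = TRUE, fmin_decimals = 0L),
    # --- multimodal, 30-D ---
    new_benchmark("F8", 30, -500, 500, function(x) sum(-x * sin(sqrt(abs(x)))),
                  -418.9829 * 30, rep(420.9687, 30)),
    new_benchmark("F9", 30, -5.12, 5.12, function(x) {
      sum(x^2 - 10 * cos(2 * pi * x) + 10)
    }, 0, rep(0, 30), fmin_decimals = 0L),
    new_benchmark("F10", 30, -32, 32, function(x) {
      n <- length(x)
      # evaluation order fixed so the floating-point floor is 8.88e-16 at 0
      -20 * exp(-0.2 * sqrt(sum(x^2) / n)) - exp(sum(cos(2 * pi * x)) / n) +
        20 + exp(1)
    }, 0, rep(0, 30), fmin_decimals = 0L),
    new_benchmark("F11", 30, -600, 600, function(x) {
      sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1
    }, 0, rep(0, 30), fmin_decimals = 0L),
    new_benchmark("F12", 30, -50, 50, function(x) {
      n <- length(x)
      y <- 1 + (x + 1) / 4
      pi / n * (10 * sin(pi * y[1])^2 +
                  sum((y[-n] - 1)^2 * (1 + 10 * sin(pi * y[-1])^2)) +
                  (y[n] - 1)^2) +
        sum(.u_penalty(x, 10, 100, 4))
    }, 0, rep(-1, 30), fmin_decimals = 0L),
    new_benchmark("F13", 30, -50, 50, function(x) {
      n <- length(x)
      0.1 * (sin(3 * pi * x[1])^2 +
               sum((x - 1)^2 * (1 + sin(3 * pi * x + 1)^2)) +
               (x[n] - 1)^2 * (1 + sin(2 * pi * x[n])^2)) +
        sum(.u_penalty(x, 5, 100, 4))
    }, 0, rep(1, 30), fmin_decimals = 0L),
    # --- fixed-dimension multimodal ---
    new_benchmark("F14", 2, -65, 65, function(x) {
      denom <- 1:25 + colSums((x - .foxholes_a)^6)
      1 / (1 / 500 + sum(1 / denom))
    }, 1, c(-32, -32), fmin_decimals = 0L),
    new_benchmark("F15", 4, -5, 5, function(x) {
      b <- .kowalik_b
      pred <- x[1] * (b^2 + b * x[2]) / (b^2 + b * x[3] + x[4])
      sum((.kowalik_a - pred)^2)
    }, 0.00030, c(0.19283329, 0.19083559, 0.12311697, 0.13576613),
    fmin_decimals = 5L),
    new_benchmark("F16", 2, -5, 5, function(x) {
      4 * x[1]^2 - 2.1 * x[1]^4 + x[1]^6 / 3 + x[1] * x[2] -
        4 * x[2]^2 + 4 * x[2]^4
    }, -1.0316, c(0.08984201, -0.71265640)),
    new_benchmark("F17", 2, -5, 5, function(x) {
      (x[2] - 5.1 / (4 * pi^2) * x[1]^2 + 5 / pi * x[1] - 6)^2 +
        10 * (1 - 1 / (8 * pi)) * cos(x[1]) + 10
    }, 0.398, c(pi, 2.275), fmin_decimals = 3L),
    new_benchmark("F18", 2, -2, 2, function(x) {
      (1 + (x[1] + x[2] + 1)^2 *
         (19 - 14 * x[1] + 3 * x[1]^2 - 14 * x[2] + 6 * x[1] * x[2] +
            3 * x[2]^2)) *
        (30 + (2 * x[1] - 3 * x[2])^2 *
           (18 - 32 * x[1] + 12 * x[1]^2 + 48 * x[2] - 36 * x[1] * x[2] +
              27 * x[2]^2))
    }, 3, c(0, -1), fmin_decimals = 0L),
    new_benchmark("F19", 3, 1, 3, function(x) {
      -sum(.hart3_c * exp(-rowSums(.hart3_a *
        (matrix(x, 4, 3, byrow = TRUE) - .hart3_p)^2)))
    }, -3.86, c(0.11461434, 0.55564885, 0.85254695), fmin_decimals = 2L),
    new_benchmark("F20", 6, 0, 1, function(x) {
      -sum(.hart6_c * exp(-rowSums(.hart6_a *
        (matrix(x, 4, 6, byrow = TRUE) - .hart6_p)^2)))
    }, -3.32, c(0.20168952, 0.15001069, 0.47687398, 0.27533243,
                0.31165162, 0.65730054), fmin_decimals = 2L),
    new_benchmark("F21", 4, 0, 10, .shekel_fn(5),
                  -10.1532, c(4.00003715, 4.00013327, 4.00003715, 4.00013327)),
    new_benchmark("F22", 4, 0, 10, .shekel_fn(7),
                  -10.4028, c(4.00057291, 4.00069020, 3.99948997, 3.99960620)),
    new_benchmark("F23", 4, 0, 10, .shekel_fn(10),
                  -10.5363, c(4.00074671, 4.00059326, 3.99966290, 3.99950981))
  )
  names(fns) <- vapply(fns, `[[`, character(1), "name")
  fns
}

#' Look up one benchmark by name
#'
#' @param name `"F1"` ... `"F23"`.
#' @return A `benchmark_function`.
#' @export
get_benchmark <- function(name) {
  suite <- make_classical_suite()
  if (!name %in% names(suite)) {
    stop("unknown benchmark '", name, "'; expected one of F1..F23",
         call. = FALSE)
  }
  suite[[name]]
}

#' Evaluate a benchmark function at a point
#'
#' @param fn a `benchmark_function`.
#' @param x numeric vector of length `fn$dim`.
#' @return The scalar function value. F7 consumes one uniform draw from the
#'   current RNG stream per call.
#' @export
evaluate_benchmark <- function(fn, x) {
  stopifnot(inherits(fn, "benchmark_function"))
  if (length(x) != fn$dim) {
    stop(sprintf("%s expects a vector of length %d, got %d",
                 fn$name, fn$dim, length(x)), call. = FALSE)
  }
  fn$fn(as.numeric(x))
}

#' Reference global minimum of a benchmark
#'
#' @param fn a `benchmark_function`.
#' @return A list with `value` (the reference minimum, at the precision it is
#'   conventionally printed) and `minimizer` (a known minimizer, or `NULL`).
#' @export
global_minimum <- function(fn) {
  stopifnot(inherits(fn, "benchmark_function"))
  list(value = fn$fmin, minimizer = fn$xmin)
}
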