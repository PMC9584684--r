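# Experiment harness: repeated seeded trials, Avg/Std summaries, Wilcoxon
# signed-rank pairwise comparisons at the 0.05 level, and Friedman
# average-rank (ARV) rankings across functions. Externally produced result
# vectors (e.g. from competitor optimizers) can be compared by passing them
# straight to the statistics functions.

.algo_cfg <- function(algorithm, cfg, seed) {
  base <- unclass(cfg)
  base$seed <- as.integer(seed)
  flags <- switch(algorithm,
    sma = list(gaussian = FALSE, levy = FALSE),
    gsma = list(gaussian = TRUE, levy = FALSE),
    lsma = list(gaussian = FALSE, levy = TRUE),
    glsma = list(gaussian = TRUE, levy = TRUE),
    stop("unknown algorithm '", algorithm,
         "'; expected sma, gsma, lsma or glsma", call. = FALSE))
  do.call(glsma_config, c(
    base[c("pop_size", "max_evals", "z", "lower", "upper", "dim", "seed",
           "log_evals")],
    list(beta_levy = base$beta_levy %||% 1.5,
         patience = base$patience %||% 5,
         levy_mode = base$levy_mode %||% "triggered"),
    flags))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Repeated independent optimizer runs
#'
#' Runs one algorithm on one objective `n_runs` times with seeds
#' `base_seed, base_seed + 1, ...` and collects the final best fitnesses
#' (plus the convergence traces).
#'
#' @param algorithm `"sma"`, `"gsma"`, `"lsma"` or `"glsma"`.
#' @param objective a [benchmark_function][new_benchmark] or plain function.
#' @param cfg an [optimizer_config()] or [glsma_config()] template; its seed
#'   is overridden per run.
#' @param n_runs number of independent runs.
#' @param base_seed seed of the first run.
#' @return An object of class `trial_result` with `final` (numeric vector of
#'   final best fitnesses), `traces` (list of per-run traces), `algorithm`,
#'   and `seeds`.
#' @export
run_trials <- function(algorithm, objective, cfg, n_runs = 30,
                       base_seed = 1) {
  stopifnot(n_runs >= 1)
  seeds <- base_seed + seq_len(n_runs) - 1L
  runs <- lapply(seeds, function(s) {
    run_glsma(objective, .algo_cfg(algorithm, cfg, s))
  })
  structure(list(final = vapply(runs, `[[`, numeric(1), "best_fitness"),
                 traces = lapply(runs, `[[`, "trace"),
                 algorithm = algorithm,
                 seeds = seeds),
            class = "trial_result")
}

#' Build a trial table over algorithms and functions
#'
#' @param algorithms character vector of algorithm names
#'   (see [run_trials()]).
#' @param functions character vector of benchmark names (`"F1"` ...) or a
#'   named list of `benchmark_function`s.
#' @param cfg configuration template (bounds/dim are taken from each
#'   benchmark).
#' @param n_runs runs per cell.
#' @param base_seed first seed; all cells share the same seed sequence.
#' @return An object of class `trial_table`: `results[[function]][[algorithm]]`
#'   numeric vectors of final best fitnesses.
#' @export
run_trial_table <- function(algorithms, functions, cfg = NULL, n_runs = 5,
                            base_seed = 1) {
  if (is.character(functions)) {
    functions <- stats::setNames(lapply(functions, get_benchmark), functions)
  }
  results <- lapply(functions, function(fn) {
    cell_cfg <- if (is.null(cfg)) {
      glsma_config(lower = fn$lower, upper = fn$upper, dim = fn$dim)
    } else {
      tmp <- cfg
      tmp$lower <- fn$lower
      tmp$upper <- fn$upper
      tmp$dim <- fn$dim
      tmp
    }
    stats::setNames(lapply(algorithms, function(alg) {
      run_trials(alg, fn, cell_cfg, n_runs, base_seed)$final
    }), algorithms)
  })
  structure(list(results = results, algorithms = algorithms,
                 functions = names(functions), n_runs = n_runs,
                 base_seed = base_seed),
            class = "trial_table")
}

#' Wilcoxon signed-rank test for paired result vectors
#'
#' Two-sided paired comparison of final-fitness vectors. Zero differences
#' are dropped (or kept in the ranking under Pratt handling). With fewer
#' than 5 informative pairs the result is "=" with p = 1. The exact null
#' distribution is used for n <= 25 without ties; otherwise a tie-corrected
#' normal approximation without continuity correction.
#'
#' @param a,b equal-length numeric vectors, `a` the proposed method
#'   (minimization: smaller is better).
#' @param alpha significance level for the win/tie/loss label.
#' @param zero_method `"drop"` removes zero differences before ranking;
#'   `"pratt"` ranks them and then discards their ranks.
#' @return A list: `p` (two-sided p value), `label` (`"+"` when `a` is
#'   significantly better, `"-"` when worse, `"="` otherwise), `n_effective`
#'   (pairs used), `statistic` (rank sum of positive differences).
#' @export
wilcoxon_signed_rank <- function(a, b, alpha = 0.05,
                                 zero_method = c("drop", "pratt")) {
  zero_method <- match.arg(zero_method)
  if (length(a) != length(b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  d <- a - b
  if (zero_method == "drop") {
    d <- d[d != 0]
    n <- length(d)
    if (n < 5) {
      return(list(p = 1, label = "=", n_effective = n,
                  statistic = NA_real_))
    }
    rk <- rank(abs(d))
    t_plus <- sum(rk[d > 0])
    t_minus <- sum(rk[d < 0])
    ties <- any(duplicated(abs(d)))
    if (n <= 25 && !ties) {
      p <- min(1, 2 * stats::psignrank(min(t_plus, t_minus), n))
    } else {
      tie_tab <- table(rk)
      sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
        sum(tie_tab^3 - tie_tab) / 48
      zstat <- (t_plus - n * (n + 1) / 4) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(zstat))
    }
  } else {
    nz <- d != 0
    n <- sum(nz)
    if (n < 5) {
      return(list(p = 1, label = "=", n_effective = n,
                  statistic = NA_real_))
    }
    rk <- rank(abs(d))  # zeros included in the ranking
    t_plus <- sum(rk[d > 0])
    t_minus <- sum(rk[d < 0])
    n_all <- length(d)
    n0 <- n_all - n
    tie_tab <- table(rk[nz])
    mu <- (n_all * (n_all + 1) - n0 * (n0 + 1)) / 4
    sigma2 <- (n_all * (n_all + 1) * (2 * n_all + 1) -
                 n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    zstat <- (t_plus - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(zstat))
  }
  label <- if (p >= alpha) "=" else if (t_plus < t_minus) "+" else "-"
  list(p = p, label = label, n_effective = n, statistic = t_plus)
}

#' Friedman average rank values
#'
#' Ranks algorithms per function by their average final fitness (ascending,
#' minimization; ties get mid-ranks) and averages the ranks across
#' functions. Lower ARV is better. Ranks sum to `k (k + 1) / 2` per
#' function, so the ARVs of `k` algorithms always sum to that constant.
#'
#' @param avg_matrix numeric matrix, functions x algorithms (e.g. of Avg
#'   values), with algorithm names as column names.
#' @return Named numeric vector of average rank values.
#' @export
friedman_average_ranks <- function(avg_matrix) {
  avg_matrix <- as.matrix(avg_matrix)
  stopifnot(ncol(avg_matrix) >= 2, nrow(avg_matrix) >= 1)
  ranks <- t(apply(avg_matrix, 1, rank))
  colMeans(ranks)
}

#' Summarize a trial table
#'
#' Computes the Avg/Std of every (function, algorithm) cell, marks the best
#' Avg per function, runs pairwise Wilcoxon signed-rank tests of the
#' reference algorithm against every other, and ranks algorithms by
#' Friedman ARV.
#'
#' @param table a [run_trial_table()] result.
#' @param reference algorithm name the pairwise tests compare against
#'   (default: the first).
#' @param alpha significance level for the win/tie/loss labels.
#' @return An object of class `trial_summary` with data frames `stats`
#'   (function, algorithm, avg, std, best), `wilcoxon` (absent when only
#'   one algorithm), and `arv`.
#' @export
summarize_trials <- function(table, reference = NULL, alpha = 0.05) {
  stopifnot(inherits(table, "trial_table"))
  algorithms <- table$algorithms
  functions <- table$functions
  if (is.null(reference)) reference <- algorithms[1]
  stopifnot(reference %in% algorithms)

  stats_df <- do.call(rbind, lapply(functions, function(fn) {
    cell <- table$results[[fn]]
    avg <- vapply(cell, mean, numeric(1))
    std <- vapply(cell, function(v) if (length(v) > 1) stats::sd(v) else 0,
                  numeric(1))
    data.frame(func = fn, algorithm = algorithms,
               avg = avg, std = std,
               best = seq_along(avg) == which.min(avg),
               row.names = NULL)
  }))

  wil <- NULL
  if (length(algorithms) > 1) {
    others <- setdiff(algorithms, reference)
    wil <- do.call(rbind, lapply(functions, function(fn) {
      cell <- table$results[[fn]]
      do.call(rbind, lapply(others, function(alg) {
        res <- wilcoxon_signed_rank(cell[[reference]], cell[[alg]],
                                    alpha = alpha)
        data.frame(func = fn, reference = reference, algorithm = alg,
                   p = res$p, label = res$label, row.names = NULL)
      }))
    }))
  }

  avg_matrix <- do.call(rbind, lapply(functions, function(fn) {
    vapply(table$results[[fn]], mean, numeric(1))
  }))
  rownames(avg_matrix) <- functions
  arv <- if (length(algorithms) > 1) {
    v <- friedman_average_ranks(avg_matrix)
    data.frame(algorithm = names(v), arv = as.numeric(v),
               rank = rank(v, ties.method = "min"), row.names = NULL)
  } else {
    data.frame(algorithm = algorithms, arv = 1, rank = 1L)
  }

  structure(list(stats = stats_df, wilcoxon = wil, arv = arv,
                 reference = reference, n_runs = table$n_runs),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("Trial summary (%d runs per cell; reference: %s)\n\n",
              x$n_runs, x$reference))
  s <- x$stats
  s$avg <- sprintf("%s%.6g%s", ifelse(s$best, "*", ""), s$avg,
                   ifelse(s$best, "*", ""))
  s$std <- sprintf("%.3g", s$std)
  s$best <- NULL
  print(s, row.names = FALSE)
  if (!is.null(x$wilcoxon)) {
    cat("\nPairwise Wilcoxon signed-rank (", x$reference, " vs):\n",
        sep = "")
    w <- x$wilcoxon
    w$p <- sprintf("%.3g", w$p)
    print(w[, c("func", "algorithm", "p", "label")], row.names = FALSE)
  }
  cat("\nFriedman average rank values:\n")
  print(x$arv, row.names = FALSE)
  invisible(x)
}

#' Write a trial summary to disk
#'
#' Emits `stats.csv`, `wilcoxon.csv` (when present), `arv.csv` and a
#' combined `summary.md` replica of the usual Avg/Std + ARV report layout.
#'
#' @param summary a [summarize_trials()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "trial_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(summary$stats, file.path(dir, "stats.csv"),
                   row.names = FALSE)
  if (!is.null(summary$wilcoxon)) {
    utils::write.csv(summary$wilcoxon, file.path(dir, "wilcoxon.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(summary$arv, file.path(dir, "arv.csv"),
                   row.names = FALSE)

  md <- c("# Trial summary", "",
          sprintf("%d runs per cell; reference algorithm: %s", summary$n_runs,
                  summary$reference), "",
          "| Function | Algorithm | Avg | Std |",
          "|---|---|---|---|",
          sprintf("| %s | %s | %s | %.3g |",
                  summary$stats$func, summary$stats$algorithm,
                  ifelse(summary$stats$best,
                         sprintf("*%.6g*", summary$stats$avg),
                         sprintf("%.6g", summary$stats$avg)),
                  summary$stats$std),
          "")
  if (!is.null(summary$wilcoxon)) {
    md <- c(md,
            sprintf("## Wilcoxon signed-rank (%s vs others, alpha = 0.05)",
                    summary$reference), "",
            "| Function | Algorithm | p | label |",
            "|---|---|---|---|",
            sprintf("| %s | %s | %.3g | %s |",
                    summary$wilcoxon$func, summary$wilcoxon$algorithm,
                    summary$wilcoxon$p, summary$wilcoxon$label),
            "")
  }
  md <- c(md, "## Friedman average rank values", "",
          "| Algorithm | ARV | Rank |", "|---|---|---|",
          sprintf("| %s | %.6g | %d |", summary$arv$algorithm,
                  summary$arv$arv, summary$arv$rank))
  writeLines(md, file.path(dir, "summary.md"))
  invisible(dir)
}
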