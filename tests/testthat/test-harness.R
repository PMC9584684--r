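test_that("a single trial equals a direct seeded run", {
  f16 <- get_benchmark("F16")
  cfg <- glsma_config(pop_size = 8, max_evals = 640, dim = 2, lower = -5,
                      upper = 5)
  tr <- run_trials("glsma", f16, cfg, n_runs = 1, base_seed = 77)
  expect_length(tr$final, 1)
  direct <- run_glsma(f16, glsma_config(pop_size = 8, max_evals = 640,
                                        dim = 2, lower = -5, upper = 5,
                                        seed = 77))
  expect_identical(tr$final, direct$best_fitness)

  # Avg/Std of a constant vector
  v <- rep(4.2, 6)
  expect_equal(mean(v), 4.2)
  expect_equal(sd(v), 0)
})

test_that("the algorithm switch maps onto the operator flags", {
  cfg <- glsma_config(pop_size = 6, max_evals = 300, dim = 2, lower = -5,
                      upper = 5)
  f16 <- get_benchmark("F16")
  for (alg in c("sma", "gsma", "lsma", "glsma")) {
    tr <- run_trials(alg, f16, cfg, n_runs = 1, base_seed = 1)
    expect_identical(tr$algorithm, alg)
  }
  expect_error(run_trials("pso", f16, cfg, 1, 1), "unknown algorithm")
})

test_that("wilcoxon handles identity, enumeration, and reference cases", {
  a <- c(1, 2, 3, 4, 5, 6)
  res_id <- wilcoxon_signed_rank(a, a)
  expect_equal(res_id$p, 1)
  expect_identical(res_id$label, "=")

  # 6 pairs, all differences favoring b: exact p = 2/64 by enumeration
  b <- a + c(1, 2, 3, 4, 5, 6) / 10
  res <- wilcoxon_signed_rank(a, b)
  expect_equal(res$p, 0.03125)
  expect_identical(res$label, "+")
  expect_equal(res$p, oracle_signed_rank_p(a - b))

  # textbook-size example against the independent reference implementation
  set.seed(14)
  x <- rnorm(10)
  y <- x + rnorm(10, sd = 2)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-6)

  # large-n normal approximation against the reference without continuity
  # correction
  set.seed(15)
  x2 <- rnorm(40)
  y2 <- x2 + rnorm(40, sd = 1)
  ours2 <- wilcoxon_signed_rank(x2, y2)
  ref2 <- stats::wilcox.test(x2, y2, paired = TRUE, exact = FALSE,
                             correct = FALSE)
  expect_equal(ours2$p, ref2$p.value, tolerance = 1e-9)
})

test_that("wilcoxon is symmetric and degenerates gracefully", {
  set.seed(16)
  a <- rnorm(12)
  b <- a + rnorm(12)
  r1 <- wilcoxon_signed_rank(a, b)
  r2 <- wilcoxon_signed_rank(b, a)
  expect_equal(r1$p, r2$p)
  flip <- c("+" = "-", "-" = "+", "=" = "=")
  expect_identical(unname(flip[r1$label]), r2$label)
  expect_gt(r1$p, 0)
  expect_lte(r1$p, 1)

  # fewer than 5 informative pairs
  short <- wilcoxon_signed_rank(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(short$p, 1)
  expect_identical(short$label, "=")
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")

  # pratt handling keeps zeros in the ranking but still yields a valid p
  pr <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6, 7),
                             c(1, 3, 4, 5, 6, 7, 8),
                             zero_method = "pratt")
  expect_gt(pr$p, 0)
  expect_lte(pr$p, 1)
})

test_that("friedman ranks conserve mass and break ties at mid-rank", {
  m <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 3, 2))
  colnames(m) <- c("A", "B", "C")
  arv <- friedman_average_ranks(m)
  expect_equal(unname(arv["A"]), 1)
  expect_equal(sum(arv), 3 * 4 / 2)

  m2 <- rbind(c(1, 1, 5), c(1, 2, 3))
  colnames(m2) <- c("A", "B", "C")
  arv2 <- friedman_average_ranks(m2)
  expect_equal(unname(arv2["A"]), (1.5 + 1) / 2)
  expect_equal(unname(arv2["B"]), (1.5 + 2) / 2)

  # invariance under a monotone transform of each row
  set.seed(17)
  m3 <- matrix(runif(20), 5, 4)
  expect_equal(friedman_average_ranks(exp(m3)),
               friedman_average_ranks(m3))
  # rank-sum conservation for random inputs
  expect_equal(sum(friedman_average_ranks(m3)), 4 * 5 / 2)
})

test_that("summaries mark the best cell and produce the report files", {
  tt <- structure(list(
    results = list(
      FX = list(alg1 = c(3, 3, 3), alg2 = c(1, 1.5, 2), alg3 = c(5, 6, 7)),
      FY = list(alg1 = c(0, 0, 0), alg2 = c(2, 2, 2), alg3 = c(1, 1, 1))
    ),
    algorithms = c("alg1", "alg2", "alg3"),
    functions = c("FX", "FY"), n_runs = 3, base_seed = 1),
    class = "trial_table")
  s <- summarize_trials(tt)
  best_fx <- s$stats$algorithm[s$stats$func == "FX" & s$stats$best]
  best_fy <- s$stats$algorithm[s$stats$func == "FY" & s$stats$best]
  expect_identical(best_fx, "alg2")
  expect_identical(best_fy, "alg1")
  expect_equal(nrow(s$wilcoxon), 4)
  expect_equal(sum(s$arv$arv), 6)

  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_trial_summary(s, dir)
  expect_true(all(file.exists(file.path(dir,
    c("stats.csv", "wilcoxon.csv", "arv.csv", "summary.md")))))

  # single algorithm: no pairwise section
  tt1 <- structure(list(results = list(FX = list(alg1 = c(1, 2))),
                        algorithms = "alg1", functions = "FX",
                        n_runs = 2, base_seed = 1),
                   class = "trial_table")
  s1 <- summarize_trials(tt1)
  expect_null(s1$wilcoxon)
})

test_that("a reduced four-variant table has the published report shape", {
  tt <- run_trial_table(c("glsma", "sma", "gsma", "lsma"),
                        c("F16", "F18"),
                        cfg = glsma_config(pop_size = 8, max_evals = 1000),
                        n_runs = 3, base_seed = 5)
  s <- summarize_trials(tt)
  expect_equal(nrow(s$arv), 4)
  expect_equal(sum(s$arv$arv), 10)
  expect_setequal(s$arv$algorithm, c("glsma", "sma", "gsma", "lsma"))
  expect_equal(nrow(s$stats), 8)
})
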