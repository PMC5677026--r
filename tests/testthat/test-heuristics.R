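test_that("zero-loss searches are deterministic and count as expected", {
  cfg <- game_config(1 / 4, loss_rate = 0, sectioning_order = 2)
  # target 0.9: level 1 queries [0,.5) no then [.5,1) yes; level 2 likewise
  tr <- run_qsectioning(cfg, 0.9)
  expect_identical(tr$total_queries, 4L)
  expect_identical(tr$per_level_queries, c(2L, 2L))
  expect_equal(unclass(tr$final_interval), c(lower = 0.75, upper = 1))

  # target at 0: the first subdomain verifies at every level
  for (q in 2:5) {
    cfg <- game_config(1e-4, loss_rate = 0, sectioning_order = q)
    tr <- run_qsectioning(cfg, 0)
    expect_identical(tr$total_queries, cfg$levels)
    expect_true(all(tr$per_level_queries == 1L))
  }

  # per-level counts are bounded by q at zero loss
  cfg <- game_config(1 / 100, loss_rate = 0, sectioning_order = 3)
  set.seed(3)
  for (x in runif(20)) {
    tr <- run_qsectioning(cfg, x)
    expect_true(all(tr$per_level_queries <= 3L))
  }
})

test_that("every completed trial is fidelitous", {
  set.seed(42)
  grid <- expand.grid(
    q = c(2, 3, 4), alpha = c(0, 0.3, 0.8), eps = c(1 / 8, 1e-3, 1e-6)
  )
  for (i in seq_len(nrow(grid))) {
    cfg <- game_config(grid$eps[i], grid$alpha[i], grid$q[i])
    for (x in runif(8)) {
      tr <- run_qsectioning(cfg, x)
      lo <- tr$final_interval[["lower"]]
      hi <- tr$final_interval[["upper"]]
      expect_true(lo <= x && x < hi + 1e-12)
      expect_lte(hi - lo, cfg$precision * cfg$domain_length * (1 + 1e-12))
      expect_identical(tr$total_queries, sum(tr$per_level_queries))
      expect_identical(tr$levels, cfg$levels)
      expect_identical(length(tr$per_level_queries), as.integer(cfg$levels))
    }
  }
  # deep recursion: 21 levels of integer index tracking stay consistent
  cfg <- game_config(1e-10, loss_rate = 0, sectioning_order = 3)
  tr <- run_qsectioning(cfg, 0.123456789)
  expect_true(tr$final_interval[["lower"]] <= 0.123456789 &&
    0.123456789 < tr$final_interval[["upper"]])
  expect_lte(diff(unclass(tr$final_interval)), 1e-10)
  # a target on a subdomain-boundary lattice point (measure zero under the
  # uniform prior) is localized to within representation precision
  tr <- run_qsectioning(cfg, 2 / 3)
  expect_lte(tr$final_interval[["lower"]] - 2 / 3, 4e-16)
  expect_lte(2 / 3 - tr$final_interval[["upper"]], 4e-16)
})

test_that("a trial is replayable in isolation from its seed", {
  cfg <- game_config(1e-4, 0.9, 3)
  a <- run_qsectioning(cfg, 0.37, seed = 99)
  b <- run_qsectioning(cfg, 0.37, seed = 99)
  expect_identical(a, b)
})

test_that("fast sampler matches the exact per-level enumeration oracle", {
  # exact pmf: level cost (k-1)q + l with l uniform, k geometric
  pmf <- qsection_count_pmf_oracle(q = 2, levels = 1, loss_rate = 0.5)
  expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
  # P(1) = 1/4 (l=1,k=1), P(2) = 1/4, P(3) = 1/8 (l=1,k=2), P(4) = 1/8 ...
  expect_equal(pmf$prob[1:4], c(1 / 4, 1 / 4, 1 / 8, 1 / 8), tolerance = 1e-12)

  cfg <- game_config(1 / 2, loss_rate = 0.5, sectioning_order = 2)
  set.seed(5)
  draws <- sample_query_count_fast(cfg, 2e4)
  emp <- tabulate(draws) / length(draws)
  for (m in 1:6) {
    p <- pmf$prob[m]
    expect_lt(abs(emp[m] - p), 4 * sqrt(p * (1 - p) / 2e4))
  }

  # two-level convolution against the oracle, via the mean and a chi-square
  pmf2 <- qsection_count_pmf_oracle(q = 3, levels = 2, loss_rate = 0.3)
  cfg2 <- game_config(1 / 9, loss_rate = 0.3, sectioning_order = 3)
  set.seed(6)
  draws2 <- sample_query_count_fast(cfg2, 2e4)
  expect_equal(
    mean(draws2),
    sum(pmf2$count * pmf2$prob),
    tolerance = 5 * sqrt(sum(pmf2$count^2 * pmf2$prob) / 2e4) /
      sum(pmf2$count * pmf2$prob)
  )
  keep <- pmf2$prob > 5e-4
  obs <- tabulate(draws2, nbins = max(pmf2$count))[pmf2$count[keep]]
  chi <- sum((obs - 2e4 * pmf2$prob[keep])^2 / (2e4 * pmf2$prob[keep]))
  expect_lt(chi, stats::qchisq(0.999, df = sum(keep) - 1))
})

test_that("naive simulator and fast sampler are distributionally equivalent", {
  for (cs in list(
    list(q = 2, eps = 1 / 4, alpha = 0),
    list(q = 3, eps = 1 / 27, alpha = 0.3),
    list(q = 4, eps = 1 / 16, alpha = 0.6)
  )) {
    cfg <- game_config(cs$eps, cs$alpha, cs$q)
    n <- 3000
    naive <- run_trials(cfg, n, seed = 1, engine = "naive")$counts
    fast <- run_trials(cfg, n, seed = 2, engine = "fast")$counts
    # means agree with each other and with the closed-form expectation
    pred <- mean_queries(cs$q, 1 / cs$eps, cs$alpha)
    se <- sqrt(stats::var(naive) / n + stats::var(fast) / n)
    expect_lt(abs(mean(naive) - mean(fast)), 4 * max(se, 1e-9))
    expect_lt(abs(mean(naive) - pred), 4 * max(sqrt(stats::var(naive) / n), 1e-9))
    # and the full distributions pass a two-sample rank test
    if (cs$alpha > 0) {
      p <- suppressWarnings(stats::wilcox.test(naive, fast)$p.value)
      expect_gt(p, 1e-4)
    }
  }
})

test_that("sample means converge on the closed-form expectation", {
  # alpha = 0: expected total is levels * (q + 1) / 2 exactly
  cfg <- game_config(1 / 64, loss_rate = 0, sectioning_order = 2)
  set.seed(8)
  draws <- sample_query_count_fast(cfg, 5e4)
  expect_equal(mean(draws), 6 * 1.5, tolerance = 0.02)

  cfg <- game_config(1e-10, loss_rate = 0.99, sectioning_order = 3)
  set.seed(9)
  draws <- sample_query_count_fast(cfg, 1e5)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mean_queries(3, 1e10, 0.99)), 3 * se)
})
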