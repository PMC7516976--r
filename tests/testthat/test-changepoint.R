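test_that("gradient partial sums match a brute-force double loop", {
  set.seed(15)
  G <- matrix(stats::rnorm(15), 5, 3)
  S <- gradient_partial_sums(G)
  brute <- matrix(0, 5, 3)
  for (k in 1:5) for (j in 1:3) brute[k, j] <- sum(G[1:k, j])
  expect_identical(S, brute)
  expect_equal(S[5, ], colSums(G))
  # single row
  g <- matrix(1:3, 1, 3)
  expect_equal(unname(gradient_partial_sums(g)[1, ]), as.numeric(1:3))
  # rows summing to zero cancel
  G0 <- rbind(G, -G[5:1, , drop = FALSE])
  expect_equal(unname(gradient_partial_sums(G0)[10, ]), rep(0, 3))
})

test_that("partial-sum form equals the k^2/n mean-gradient form exactly", {
  m <- pois_model()
  y <- simulate_ingarch(m, c(1, 0.2, 0.3), 400, seed = 9)$y
  fit <- fit_mdpde(y, 0.2, m, fast_cfg)
  tt <- dpd_test(y, 0.2, m, fit = fit)
  n <- fit$n_obs
  S <- gradient_partial_sums(fit$per_t_grad)
  Kinv <- solve(fit$K_hat)
  alt <- vapply(1:n, function(k) {
    gbar <- S[k, ] / k                      # mean gradient over 1..k
    (k^2 / n) * drop(t(gbar) %*% Kinv %*% gbar)
  }, numeric(1))
  expect_equal(max(alt), tt$statistic, tolerance = 1e-12)
  expect_equal(alt, as.numeric(tt$process), tolerance = 1e-12)
})

test_that("the CUSUM process ends at zero, stays non-negative, and peaks at the statistic", {
  m <- pois_model()
  y <- simulate_ingarch(m, c(1, 0.2, 0.2), 600, seed = 10)$y
  for (tt in list(dpd_test(y, 0.3, m, config = fast_cfg),
                  score_cusum_test(y, m, config = fast_cfg))) {
    expect_true(all(tt$process >= 0))
    expect_equal(tt$statistic, max(tt$process))
    expect_lt(tt$process[length(tt$process)], 1e-6)
    expect_equal(tt$change_index, which.max(tt$process))
  }
})

test_that("score normalization and DPD(alpha=0) normalization nearly coincide on clean data", {
  # information identity J ~ K at the CMLE makes both statistics agree
  m <- pois_model()
  y <- simulate_ingarch(m, c(1, 0.2, 0.2), 3000, seed = 33)$y
  fit <- fit_mdpde(y, 0, m, fast_cfg)
  t_dpd <- dpd_test(y, 0, m, fit = fit)
  t_score <- score_cusum_test(y, m, fit = fit)
  expect_lt(abs(t_dpd$statistic - t_score$statistic) /
              t_score$statistic, 0.1)
})

test_that("a mid-sample parameter change is detected near its true location", {
  m <- pois_model()
  hits <- vapply(1:3, function(i) {
    y <- simulate_ingarch(m, c(1, 0.2, 0.2), 1000, seed = 50 + i,
                          theta1 = c(1, 0.2, 0.5))$y
    tt <- dpd_test(y, 0.2, m, config = fast_cfg, crit_val = 3.004)
    expect_true(tt$reject)
    abs(tt$change_index - 500) / 1000
  }, numeric(1))
  expect_lte(stats::median(hits), 0.1)
})

test_that("critical values are monotone and match the shipped table", {
  expect_equal(critical_value(3, 0.05), 3.0085)
  for (lv in c(0.10, 0.05, 0.01)) {
    v <- vapply(1:6, critical_value, numeric(1), level = lv)
    expect_true(all(diff(v) > 0))       # increasing in dimension
  }
  for (d in 1:6) {
    v <- vapply(c(0.10, 0.05, 0.01), function(l) critical_value(d, l),
                numeric(1))
    expect_true(all(diff(v) > 0))       # decreasing in level
  }
  expect_error(critical_value(3, 0.033), "simulate")
  expect_error(critical_value(9, 0.05), "simulate")
})

test_that("bridge supremum simulation is seed-reproducible and dimension-monotone", {
  q1 <- simulate_bb_sup(1, grid_size = 200, reps = 3000, seed = 5,
                        probs = 0.95)
  q1b <- simulate_bb_sup(1, grid_size = 200, reps = 3000, seed = 5,
                         probs = 0.95)
  expect_identical(as.numeric(q1), as.numeric(q1b))
  q2 <- simulate_bb_sup(2, grid_size = 200, reps = 3000, seed = 5,
                        probs = 0.95)
  q4 <- simulate_bb_sup(4, grid_size = 200, reps = 3000, seed = 5,
                        probs = 0.95)
  expect_true(as.numeric(q1) < as.numeric(q2))
  expect_true(as.numeric(q2) < as.numeric(q4))
  # simulate mode of critical_value agrees with the direct call
  expect_equal(critical_value(2, 0.05, method = "simulate",
                              reps = 3000, grid_size = 200, seed = 5),
               as.numeric(q2))
})

test_that("process_table exports the per-k process", {
  m <- pois_model()
  y <- simulate_ingarch(m, c(1, 0.2, 0.2), 200, seed = 2)$y
  tt <- dpd_test(y, 0.1, m, config = fast_cfg)
  pt <- process_table(tt)
  expect_equal(names(pt), c("k", "value"))
  expect_equal(nrow(pt), 200)
  expect_equal(pt$value, as.numeric(tt$process))
})
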