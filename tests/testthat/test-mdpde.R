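# independent reference implementation of the conditional negative
# log-likelihood (alpha = 0 objective), written directly from the model
# definition: used as an oracle for the C++ loss path
ref_nll <- function(y, theta, model, x_init) {
  n <- length(y)
  x <- numeric(n); x[1] <- x_init
  for (t in 2:n) x[t] <- theta[1] + theta[2] * x[t - 1] +
      theta[3] * y[t - 1]
  fam <- model$family
  ll <- switch(fam$name,
    poisson = stats::dpois(y, x, log = TRUE),
    negbin = stats::dnbinom(y, size = fam$r, mu = x, log = TRUE),
    geometric = stats::dgeom(y - 1L, prob = 1 / pmax(x, 1 + 1e-8),
                             log = TRUE))
  -mean(ll)
}

test_that("DPD loss terms match closed forms and a brute-force sum", {
  pois <- dpd_family("poisson")
  geo <- dpd_family("geometric")
  # alpha = 0 is the negative log pmf
  expect_equal(dpd_loss_term(0, 0, 0, pois), 1)
  # geometric series closed form at alpha = 1, p = 0.5, y = 1:
  # sum_y p^2 (1-p)^(2(y-1)) = p^2 / (1 - (1-p)^2) = 1/3
  expect_equal(dpd_loss_term(1, log(0.5), 1, geo), 1 / 3 - 2 * 0.5,
               tolerance = 1e-12)
  # poisson alpha = 1: oracle = brute-force sum far into the tail
  brute <- sum(exp(-2) / factorial(0:170)^2) - 2 * exp(-1)
  expect_equal(dpd_loss_term(0, 0, 1, pois), brute, tolerance = 1e-12)
})

test_that("geometric closed form agrees with the forced truncation path", {
  geo <- dpd_family("geometric")
  for (p in c(0.8, 0.5, 0.2, 0.05)) {
    for (alpha in c(0.1, 0.25, 0.5, 1)) {
      for (yv in c(1, 2, 7)) {
        eta <- log(1 - p)
        expect_equal(dpd_loss_term(yv, eta, alpha, geo),
                     dpd_loss_term(yv, eta, alpha, geo,
                                   closed_form = FALSE),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("objective reduces to a single loss term and to the reference NLL", {
  m <- pois_model()
  th <- c(1, 0.2, 0.3)
  expect_equal(dpd_objective(5L, th, 0.4, m, x_init = 2),
               dpd_loss_term(5, log(2), 0.4, m$family))
  for (setup in list(list(m = pois_model(), th = c(1, 0.2, 0.3)),
                     list(m = nb_model(), th = c(1, 0.3, 0.3)))) {
    y <- simulate_ingarch(setup$m, setup$th, 300, seed = 12)$y
    expect_equal(dpd_objective(y, setup$th, 0, setup$m, mean(y)),
                 ref_nll(y, setup$th, setup$m, mean(y)),
                 tolerance = 1e-12)
  }
})

test_that("analytic loss gradients match finite differences", {
  for (setup in list(
    list(m = pois_model(), th = c(0.9, 0.25, 0.3), alphas = c(0, 0.3, 1)),
    list(m = nb_model(), th = c(1.1, 0.2, 0.35), alphas = c(0, 0.5)),
    list(m = int_model(l = 1), th = c(1, 0.2, 0.35, 0.1),
         alphas = c(0.25)))) {
    m <- setup$m
    y <- simulate_ingarch(m, setup$th, 60, seed = 21)$y
    xi <- mean(y)
    for (a in setup$alphas) {
      G <- dpd_gradient_terms(y, setup$th, a, m, xi)
      g <- colMeans(G)
      gfd <- fd_grad(function(v) dpd_objective(y, v, a, m, xi),
                     setup$th)
      expect_equal(unname(g), gfd, tolerance = 1e-6)
    }
  }
  # the score vanishes observation-wise at the conditional mean:
  # alpha = 0, poisson, row t proportional to (x_t - y_t)
  m <- pois_model()
  y <- c(2L, 2L, 2L)
  G <- dpd_gradient_terms(y, c(2, 0, 0), 0, m, x_init = 2)
  expect_equal(unname(G), matrix(0, 3, 3))
})

test_that("mean analytic loss Hessian matches finite differences of the gradient", {
  for (setup in list(list(m = pois_model(), th = c(0.9, 0.25, 0.3)),
                     list(m = nb_model(), th = c(1.1, 0.2, 0.35)))) {
    m <- setup$m
    y <- simulate_ingarch(m, setup$th, 60, seed = 31)$y
    xi <- mean(y)
    for (a in c(0, 0.4)) {
      b <- dpdcusum:::.bundle(y, setup$th, a, m, xi, 2L)
      Jfd <- fd_jacobian(function(v)
        colMeans(dpd_gradient_terms(y, v, a, m, xi)), setup$th,
        h = 1e-5)
      expect_equal(unname(b$J), unname((Jfd + t(Jfd)) / 2),
                   tolerance = 1e-5)
      expect_equal(b$J, t(b$J), tolerance = 1e-10)
    }
  }
})

test_that("estimating equations are continuous in alpha at zero", {
  m <- pois_model()
  set.seed(3)
  for (i in 1:3) {
    y <- simulate_ingarch(m, c(1, 0.2, 0.3), 150, seed = 40 + i)$y
    th <- c(stats::runif(1, 0.5, 2), stats::runif(1, 0.05, 0.4),
            stats::runif(1, 0.05, 0.4))
    g0 <- colMeans(dpd_gradient_terms(y, th, 0, m, mean(y)))
    geps <- colMeans(dpd_gradient_terms(y, th, 1e-6, m, mean(y)))
    expect_lt(max(abs(geps - g0)), 1e-4)
  }
})

test_that("the alpha = 0 fit coincides with an independent CMLE", {
  m <- pois_model()
  y <- simulate_ingarch(m, c(1, 0.2, 0.3), 500, seed = 77)$y
  fit <- fit_mdpde(y, 0, m,
                   dpd_config(n_multistart = 1, optimizer_tol = 1e-13))
  ref <- stats::optim(c(mean(y) * 0.5, 0.1, 0.2),
                      function(v) ref_nll(y, v, m, mean(y)),
                      method = "L-BFGS-B",
                      lower = c(1e-4, 0, 0), upper = c(1e4, 0.99, 0.99),
                      control = list(factr = 10, maxit = 1000,
                                     ndeps = rep(1e-6, 3)))
  expect_lt(max(abs(unname(coef(fit)) - ref$par)), 1e-5)
})

test_that("fit diagnostics satisfy first-order and psd conditions", {
  m <- pois_model()
  y <- simulate_ingarch(m, c(1, 0.2, 0.2), 800, seed = 5)$y
  fit <- fit_mdpde(y, 0.25, m, fast_cfg)
  expect_true(fit$converged)
  # interior optimum: per-observation gradients sum to ~0
  expect_lt(max(abs(colSums(fit$per_t_grad))), 1e-3)
  ev <- eigen(fit$K_hat, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  expect_equal(fit$K_hat, t(fit$K_hat))
  # alpha = 0 on a correctly specified clean model: J ~ K
  fit0 <- fit_mdpde(y, 0, m, fast_cfg)
  expect_equal(fit0$J_hat, fit0$K_hat, tolerance = 0.2)
  jk <- estimate_JK(fit0)
  expect_equal(jk$J_hat, fit0$J_hat, tolerance = 1e-10)
})

test_that("iid data drive the autoregressive terms to zero", {
  m <- pois_model()
  y <- simulate_ingarch(m, c(2, 0, 0), 1500, seed = 8)$y
  fit <- fit_mdpde(y, 0.1, m, fast_cfg)
  th <- coef(fit)
  expect_lt(th["a"] + th["b"], 0.12)
  expect_equal(unname(th["d"] / (1 - th["a"] - th["b"])), mean(y),
               tolerance = 0.1)
})

test_that("sandwich variance reduces correctly and scales with n", {
  # identity algebra: J = K = I with n observations gives V = I / n
  fake <- structure(list(J_hat = diag(3), K_hat = diag(3),
                         n_obs = 50L), class = "mdpde_fit")
  av <- asymptotic_variance(fake)
  expect_equal(av$vcov, diag(3) / 50)
  expect_equal(av$se, rep(sqrt(1 / 50), 3))
  # root-n rate: median se * sqrt(n) comparable across sample sizes
  # (medians because a rare near-boundary fit at small n can blow a
  # single sandwich estimate up)
  m <- pois_model()
  se_at <- function(n, seed) {
    y <- simulate_ingarch(m, c(1, 0.2, 0.2), n, seed = seed)$y
    fit_mdpde(y, 0.25, m, fast_cfg)$se * sqrt(n)
  }
  r1 <- apply(vapply(1:15, function(i) se_at(300, 900 + i),
                     numeric(3)), 1, stats::median)
  r2 <- apply(vapply(1:15, function(i) se_at(1200, 950 + i),
                     numeric(3)), 1, stats::median)
  expect_true(all(r1 / r2 > 0.5 & r1 / r2 < 2))
})

test_that("alpha selection reports the AMSE decomposition and steers away from the CMLE under outliers", {
  m <- pois_model()
  grid <- c(0.1, 0.25, 0.5, 0.75, 1)
  # under heavy contamination the estimated AMSE must flag the
  # non-robust alpha = 0 endpoint as worse than a moderate alpha
  cs <- contamination_spec(0.1, "poisson", gamma = 10)
  flagged <- vapply(1:8, function(i) {
    yc <- contaminate(simulate_ingarch(m, c(1, 0.2, 0.3), 600,
                                       seed = 600 + i)$y, cs,
                      seed = 700 + i)
    tab <- select_alpha(yc, m, grid, fast_cfg)$table
    tab$amse[tab$alpha == 0] >
      min(tab$amse[tab$alpha >= 0.25], na.rm = TRUE)
  }, logical(1))
  expect_gte(sum(flagged), 7)
  # table structure: alpha = 0 present for reference, excluded from
  # the argmin; trace decomposes into squared bias + variance
  y <- simulate_ingarch(m, c(1, 0.2, 0.3), 400, seed = 1234)$y
  sel <- select_alpha(y, m, grid, fast_cfg)
  expect_true(0 %in% sel$table$alpha)
  expect_gt(sel$alpha_star, 0)
  expect_true(sel$alpha_star %in% grid)
  expect_equal(sel$table$amse,
               sel$table$amse_bias + sel$table$amse_var)
  # the pilot anchors the bias term: it vanishes at alpha = 1
  expect_equal(sel$table$amse_bias[sel$table$alpha == 1], 0)
})

test_that("robust fits resist additive outliers better than the CMLE", {
  m <- pois_model()
  th0 <- c(1, 0.2, 0.2)
  cs <- contamination_spec(0.03, "poisson", gamma = 10)
  errs <- t(vapply(1:60, function(i) {
    y <- contaminate(simulate_ingarch(m, th0, 500, seed = 2000 + i)$y,
                     cs)
    e0 <- tryCatch(sqrt(sum((coef(fit_mdpde(y, 0, m, fast_cfg)) -
                               th0)^2)), error = function(e) NA_real_)
    e5 <- tryCatch(sqrt(sum((coef(fit_mdpde(y, 0.5, m, fast_cfg)) -
                               th0)^2)), error = function(e) NA_real_)
    c(e0, e5)
  }, numeric(2)))
  errs <- errs[stats::complete.cases(errs), ]
  expect_lt(stats::median(errs[, 2]), stats::median(errs[, 1]))
})
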