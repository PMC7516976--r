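#' Simulate an INGARCH-type count series
#'
#' Draws a series from the model: the intensity recursion is advanced
#' with the realised counts, and each count is drawn from the family's
#' conditional distribution at the current intensity (Poisson mean
#' \eqn{X_t}; negative binomial with \eqn{p_t = r/(r + X_t)}; geometric
#' with \eqn{p_t = 1/X_t}).  The generation starts from `x1 = 0` by
#' convention, which makes the first draw degenerate at the support
#' floor; the effect washes out immediately.
#'
#' An optional mid-sample parameter change is supported: with `theta1`
#' set, the recursion switches from `theta` to `theta1` for
#' `t > change_at` while the intensity is carried through continuously.
#'
#' @param model an [ingarch_model()].
#' @param theta parameter vector (feasible).
#' @param n series length.
#' @param seed optional integer seed.
#' @param x1 starting intensity for the generation (default 0).
#' @param theta1 optional post-change parameter vector.
#' @param change_at change location (default `floor(n/2)`); the switch
#'   applies to the recursion for `t > change_at`.
#' @return A list with `y` (integer counts) and `x` (the intensities).
#' @examples
#' m <- ingarch_model(dpd_family("poisson"))
#' s <- simulate_ingarch(m, c(1, 0.2, 0.2), n = 200, seed = 1)
#' mean(s$y)   # close to d / (1 - a - b) = 5/3
#' @export
simulate_ingarch <- function(model, theta, n, seed = NULL, x1 = 0,
                             theta1 = NULL, change_at = floor(n / 2)) {
  .check_model(model)
  theta <- .check_theta(theta, model)
  if (!is.null(theta1)) theta1 <- .check_theta(theta1, model)
  stopifnot(n >= 1, is.finite(x1), x1 >= 0)
  if (!is.null(seed)) set.seed(seed)
  fam <- model$family
  l <- model$threshold_l
  y <- integer(n)
  x <- numeric(n)
  xt <- x1
  draw <- switch(fam$name,
    poisson = function(m) stats::rpois(1L, m),
    negbin = function(m) stats::rnbinom(1L, size = fam$r, mu = m),
    geometric = function(m) stats::rgeom(1L, prob = 1 / max(m, 1)) + 1L)
  for (t in seq_len(n)) {
    if (t > 1L) {
      th <- if (!is.null(theta1) && t > change_at) theta1 else theta
      xt <- if (model$form == "ingarch11")
        th[1L] + th[2L] * x[t - 1L] + th[3L] * y[t - 1L]
      else
        th[1L] + th[2L] * x[t - 1L] + th[3L] * max(y[t - 1L] - l, 0) +
          th[4L] * min(y[t - 1L], l)
    }
    x[t] <- xt
    y[t] <- draw(xt)
  }
  list(y = y, x = x)
}

#' Additive outlier contamination specification
#'
#' Describes the contamination mechanism
#' \eqn{Y_{c,t} = Y_t + P_t Y_{o,t}} with \eqn{P_t} iid Bernoulli(`p`)
#' and \eqn{Y_{o,t}} iid outlier counts, all independent of the clean
#' series.
#'
#' @param p outlier probability in \[0, 1\].
#' @param family outlier distribution: `"poisson"` with mean `gamma`, or
#'   `"negbin"` with size `r` and success probability `kappa`.
#' @param gamma Poisson outlier mean.
#' @param r,kappa negative binomial outlier parameters.
#' @return An object of class `contamination_spec`.
#' @export
contamination_spec <- function(p, family = c("poisson", "negbin"),
                               gamma = 10, r = 10, kappa = 0.5) {
  family <- match.arg(family)
  stopifnot(p >= 0, p <= 1)
  if (family == "poisson") stopifnot(gamma >= 0)
  else stopifnot(r > 0, kappa > 0, kappa < 1)
  structure(list(p = p, family = family, gamma = gamma, r = r,
                 kappa = kappa),
            class = "contamination_spec")
}

#' Contaminate a count series with additive outliers
#'
#' Applies \eqn{Y_{c,t} = Y_t + P_t Y_{o,t}} elementwise, drawing the
#' Bernoulli indicators and the outlier magnitudes freshly (and
#' independently of `y`).
#'
#' @param y clean integer count series.
#' @param spec a [contamination_spec()].
#' @param seed optional integer seed.
#' @return The contaminated integer series.
#' @export
contaminate <- function(y, spec, seed = NULL) {
  stopifnot(inherits(spec, "contamination_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  P <- stats::rbinom(n, 1L, spec$p)
  Yo <- if (spec$family == "poisson") stats::rpois(n, spec$gamma)
        else stats::rnbinom(n, size = spec$r, prob = spec$kappa)
  as.integer(y + P * Yo)
}

#' Configuration for a size/power experiment
#'
#' Bundles everything one Monte Carlo cell needs: the model, the null
#' (and optionally post-change) parameters, the sample size, the
#' estimators to run, contamination, and seeding.  Replicates are
#' seeded individually (`seed + replicate index`), so results do not
#' depend on how the replicate loop is partitioned.
#'
#' @param model an [ingarch_model()].
#' @param theta0 null parameter vector.
#' @param theta1 optional post-change parameters (change at
#'   `floor(n/2)`).
#' @param n sample size per replicate.
#' @param reps number of replicates.
#' @param alphas DPD tuning parameters to test (may be empty).
#' @param level nominal level.
#' @param contamination optional [contamination_spec()].
#' @param include_score also run the score-vector CUSUM test.
#' @param crit_val optional fixed critical value for all tests
#'   (otherwise the table value for the model dimension).
#' @param seed base seed.
#' @param fit_config [dpd_config()] used for every fit; the default
#'   uses a single moment-based optimizer start, appropriate for large
#'   replicate counts.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(model, theta0, theta1 = NULL, n = 500L,
                              reps = 1000L,
                              alphas = c(0.1, 0.2, 0.3, 0.5, 1),
                              level = 0.05, contamination = NULL,
                              include_score = TRUE, crit_val = NULL,
                              seed = 1L,
                              fit_config = dpd_config(n_multistart = 1L)) {
  .check_model(model)
  theta0 <- .check_theta(theta0, model)
  if (!is.null(theta1)) theta1 <- .check_theta(theta1, model)
  stopifnot(reps >= 1, n >= 20, level > 0, level < 1,
            all(alphas >= 0))
  if (!is.null(contamination))
    stopifnot(inherits(contamination, "contamination_spec"))
  structure(list(model = model, theta0 = theta0, theta1 = theta1,
                 n = as.integer(n), reps = as.integer(reps),
                 alphas = alphas, level = level,
                 contamination = contamination,
                 include_score = include_score, crit_val = crit_val,
                 seed = as.integer(seed), fit_config = fit_config),
            class = "experiment_config")
}

#' Run a Monte Carlo size/power experiment
#'
#' For each replicate: simulate the series (with the mid-sample
#' parameter switch if configured), optionally contaminate it, set the
#' filter start to the sample mean, run the requested tests, and record
#' rejections.  Replicates whose fit fails are dropped and counted; a
#' cell with more than 5\% failures is flagged.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print a progress line every 100 replicates.
#' @return A data frame with one row per estimator: `estimator`,
#'   `alpha`, `n`, `reps`, `used`, `rejections`, `rate`, `mc_se`,
#'   `flagged`.  The 0/1 rejection matrix is attached as attribute
#'   `"rejections"`.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  ests <- c(if (cfg$include_score) "score",
            if (length(cfg$alphas)) paste0("dpd", cfg$alphas))
  R <- matrix(NA_real_, nrow = cfg$reps, ncol = length(ests),
              dimnames = list(NULL, ests))
  for (i in seq_len(cfg$reps)) {
    sim <- simulate_ingarch(cfg$model, cfg$theta0, cfg$n,
                            seed = cfg$seed + i, x1 = 0,
                            theta1 = cfg$theta1)
    y <- sim$y
    if (!is.null(cfg$contamination))
      y <- contaminate(y, cfg$contamination)
    xi <- mean(y)
    if (cfg$include_score) {
      R[i, "score"] <- tryCatch(
        as.numeric(score_cusum_test(y, cfg$model, cfg$level,
                                    cfg$fit_config, x_init = xi,
                                    crit_val = cfg$crit_val)$reject),
        error = function(e) NA_real_)
    }
    for (a in cfg$alphas) {
      R[i, paste0("dpd", a)] <- tryCatch(
        as.numeric(dpd_test(y, a, cfg$model, cfg$level,
                            cfg$fit_config, x_init = xi,
                            crit_val = cfg$crit_val)$reject),
        error = function(e) NA_real_)
    }
    if (verbose && i %% 100L == 0L)
      message("replicate ", i, "/", cfg$reps)
  }
  used <- colSums(!is.na(R))
  rej <- colSums(R, na.rm = TRUE)
  rate <- rej / used
  out <- data.frame(
    estimator = ifelse(ests == "score", "score", "dpd"),
    alpha = ifelse(ests == "score", NA_real_,
                   suppressWarnings(as.numeric(sub("^dpd", "", ests)))),
    n = cfg$n, reps = cfg$reps, used = used, rejections = rej,
    rate = rate, mc_se = sqrt(pmax(rate * (1 - rate), 0) / used),
    flagged = (cfg$reps - used) / cfg$reps > 0.05,
    row.names = NULL)
  attr(out, "rejections") <- R
  attr(out, "config") <- cfg
  out
}

#' Return times of extreme events
#'
#' Converts a real-valued series (e.g. daily log-returns) into a count
#' series of waiting times between extreme observations: the hitting
#' times \eqn{\tau_1 < \tau_2 < \dots} are the indices where the series
#' falls strictly outside its empirical (`q_low`, `q_high`) quantile
#' band, and the return times are \eqn{Y_t = \tau_t - \tau_{t-1}} with
#' \eqn{\tau_0 = 0}.  The resulting counts are at least 1, matching the
#' geometric (total-trials) family.
#'
#' @param x real-valued series (length >= 2).
#' @param q_low,q_high quantile band (empirical, linear-interpolation
#'   type; exceedance is strict).
#' @param drop_first drop the first return time (whose baseline is
#'   \eqn{\tau_0 = 0} by convention).
#' @return Integer vector of return times; empty (with a warning) if no
#'   observation is extreme.
#' @export
return_times <- function(x, q_low = 0.05, q_high = 0.95,
                         drop_first = FALSE) {
  stopifnot(length(x) >= 2L, q_low < q_high, q_low >= 0, q_high <= 1)
  qs <- stats::quantile(x, c(q_low, q_high), names = FALSE)
  idx <- which(x < qs[1L] | x > qs[2L])
  if (!length(idx)) {
    warning("no extreme events in the series")
    return(integer(0))
  }
  y <- diff(c(0L, idx))
  if (drop_first) y <- y[-1L]
  as.integer(y)
}
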