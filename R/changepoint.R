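#' Cumulative gradient sums
#'
#' \eqn{S_k = \sum_{t \le k} \partial\tilde l_{\alpha,t}/\partial\theta}
#' from a matrix of per-observation gradient rows.  Because
#' \eqn{k\,\partial\tilde L_{\alpha,k}/\partial\theta = S_k}, these
#' partial sums carry the whole CUSUM construction.
#'
#' @param per_t_grad an `n x d` matrix of gradient rows.
#' @return An `n x d` matrix of cumulative sums.
#' @export
gradient_partial_sums <- function(per_t_grad) {
  G <- as.matrix(per_t_grad)
  if (any(!is.finite(G))) stop("non-finite gradient rows")
  S <- apply(G, 2L, cumsum)
  if (nrow(G) == 1L) S <- matrix(S, nrow = 1L,
                                 dimnames = list(NULL, colnames(G)))
  S
}

# quadratic-form process (1/n) S_k' M^{-1} S_k for all k
.cusum_process <- function(G, M) {
  n <- nrow(G)
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-12)
    stop("singular normalizer matrix in the CUSUM statistic")
  S <- gradient_partial_sums(G)
  Minv <- solve((M + t(M)) / 2)
  proc <- rowSums((S %*% Minv) * S) / n
  pmax(proc, 0)
}

.new_cpt_result <- function(process, alpha, level, cv, variant, fit) {
  stat <- max(process)
  structure(list(statistic = stat, process = process, alpha = alpha,
                 critical_value = cv, level = level,
                 reject = stat > cv,
                 change_index = which.max(process),
                 variant = variant, n_obs = length(process),
                 fit = fit),
            class = "dpd_cpt_test")
}

#' DPD-based change-point test
#'
#' Tests the constancy of the model parameter over the sample against an
#' arbitrary change, using the statistic
#' \deqn{\hat T_n^\alpha = \max_{1\le k\le n} \frac{k^2}{n}
#'   \Big(\frac{\partial\tilde L_{\alpha,k}(\hat\theta_{\alpha,n})}
#'   {\partial\theta}\Big)^T \hat K_\alpha^{-1}
#'   \frac{\partial\tilde L_{\alpha,k}(\hat\theta_{\alpha,n})}
#'   {\partial\theta},}
#' computed here in the algebraically identical partial-sum form
#' \eqn{\max_k n^{-1} S_k^T \hat K_\alpha^{-1} S_k}.  Under the null
#' the statistic converges to \eqn{\sup_{0\le s\le 1}\|B^\circ_d(s)\|^2}
#' for a d-dimensional standard Brownian bridge, so rejection compares
#' against [critical_value()].  When a change is flagged its location is
#' estimated by the argmax of the per-k process.
#'
#' @inheritParams fit_mdpde
#' @param level nominal test level (0.10, 0.05 or 0.01 for the shipped
#'   critical-value table).
#' @param crit_val optional explicit critical value, overriding the
#'   table lookup (e.g. a published value).
#' @param fit optionally, an existing [fit_mdpde()] result for this
#'   series (skips refitting).
#' @return An object of class `dpd_cpt_test` with the statistic, the
#'   per-k process, the rejection decision and the estimated change
#'   location.
#' @examples
#' m <- ingarch_model(dpd_family("poisson"))
#' y <- simulate_ingarch(m, c(1, 0.2, 0.2), n = 300, seed = 11)$y
#' dpd_test(y, alpha = 0.2, m, config = dpd_config(n_multistart = 1))
#' @export
dpd_test <- function(y, alpha, model, level = 0.05,
                     config = dpd_config(), x_init = mean(y),
                     crit_val = NULL, fit = NULL) {
  if (is.null(fit))
    fit <- fit_mdpde(y, alpha, model, config, x_init)
  stopifnot(inherits(fit, "mdpde_fit"))
  if (!fit$converged)
    stop("MDPDE fit did not converge; cannot run the test")
  proc <- .cusum_process(fit$per_t_grad, fit$K_hat)
  cv <- if (is.null(crit_val))
    critical_value(fit$model$n_par, level) else crit_val
  .new_cpt_result(proc, alpha, level, cv, "dpd", fit)
}

#' Score-vector CUSUM change-point test
#'
#' The classical comparator: the same cumulative construction as
#' [dpd_test()] at \eqn{\alpha = 0} (i.e. built from conditional
#' log-likelihood scores at the CMLE), but normalized by the observed
#' information average
#' \eqn{\hat I_n = n^{-1}\sum_t \partial^2\tilde l_{0,t}
#' (\hat\theta_{0,n})/\partial\theta\partial\theta^T}
#' instead of the score outer-product matrix.  Efficient under a clean
#' model, but its size is badly distorted by additive outliers.
#'
#' @inheritParams dpd_test
#' @return An object of class `dpd_cpt_test` with `variant = "score"`.
#' @export
score_cusum_test <- function(y, model, level = 0.05,
                             config = dpd_config(), x_init = mean(y),
                             crit_val = NULL, fit = NULL) {
  if (is.null(fit))
    fit <- fit_mdpde(y, 0, model, config, x_init)
  stopifnot(inherits(fit, "mdpde_fit"), fit$alpha == 0)
  if (!fit$converged)
    stop("CMLE fit did not converge; cannot run the test")
  proc <- .cusum_process(fit$per_t_grad, fit$J_hat)
  cv <- if (is.null(crit_val))
    critical_value(fit$model$n_par, level) else crit_val
  .new_cpt_result(proc, 0, level, cv, "score", fit)
}

#' @export
print.dpd_cpt_test <- function(x, ...) {
  lab <- if (x$variant == "score") "score-vector CUSUM test" else
    sprintf("DPD-based change-point test (alpha = %s)",
            format(x$alpha))
  cat(lab, "\n", sep = "")
  cat(sprintf("  statistic = %.4f, critical value = %.4f (level %.2f)\n",
              x$statistic, x$critical_value, x$level))
  if (x$reject)
    cat(sprintf("  parameter change detected; estimated location k = %d (n = %d)\n",
                x$change_index, x$n_obs))
  else
    cat("  no parameter change detected\n")
  invisible(x)
}

#' Per-k CUSUM process as a table
#'
#' Two-column table (`k`, `value`) of the test's per-k process, suitable
#' for plotting the score and DPD processes against each other or for
#' CSV export.
#'
#' @param test a [dpd_test()] or [score_cusum_test()] result.
#' @return A data frame with columns `k` and `value`.
#' @export
process_table <- function(test) {
  stopifnot(inherits(test, "dpd_cpt_test"))
  data.frame(k = seq_along(test$process), value = test$process)
}

# --- critical values of sup ||B(s)||^2 -------------------------------

.cv_env <- new.env(parent = emptyenv())

.cv_table <- function() {
  if (is.null(.cv_env$table)) {
    path <- system.file("extdata", "bb_critical_values.csv",
                        package = "dpdcusum", mustWork = TRUE)
    .cv_env$table <- utils::read.csv(path, comment.char = "#")
  }
  .cv_env$table
}

#' Critical values for the change-point tests
#'
#' Quantiles of \eqn{\sup_{0\le s\le 1} \|B^\circ_d(s)\|^2}, the limiting
#' null distribution of the CUSUM statistics, where \eqn{B^\circ_d} is a
#' d-dimensional standard Brownian bridge.  The shipped table covers
#' dimensions 1--6 at levels 0.10, 0.05 and 0.01, simulated once with
#' [simulate_bb_sup()] (200000 replicates, grid 2000; the generation
#' seed and settings are recorded in the table file).  For other
#' dimensions or levels use `method = "simulate"`.
#'
#' @param dim dimension of the parameter (Brownian bridge dimension).
#' @param level test level (upper-tail probability).
#' @param method `"table"` (shipped values) or `"simulate"`.
#' @param reps,grid_size,seed simulation settings for
#'   `method = "simulate"`.
#' @return The critical value (scalar).
#' @examples
#' critical_value(3, 0.05)  # approx. 3.004
#' @export
critical_value <- function(dim, level = 0.05,
                           method = c("table", "simulate"),
                           reps = 100000L, grid_size = 2000L,
                           seed = NULL) {
  method <- match.arg(method)
  stopifnot(dim >= 1, dim == round(dim), level > 0, level < 1)
  if (method == "table") {
    tab <- .cv_table()
    row <- tab[tab$dim == dim & abs(tab$level - level) < 1e-9, ]
    if (nrow(row) != 1L)
      stop("no table entry for dim = ", dim, ", level = ", level,
           "; use method = \"simulate\"")
    return(row$value)
  }
  q <- simulate_bb_sup(dim, grid_size = grid_size, reps = reps,
                       seed = seed, probs = 1 - level)
  as.numeric(q)
}

#' Simulate the supremum of a squared Brownian bridge norm
#'
#' Each replicate builds `dim` independent Gaussian random walks on a
#' uniform grid (increments scaled by `1/sqrt(grid_size)`), bridges them
#' as \eqn{W(s) - sW(1)}, and records the maximum over the grid of the
#' squared Euclidean norm.  Empirical quantiles of these maxima estimate
#' the critical values used by the tests.
#'
#' @param dim bridge dimension.
#' @param grid_size number of grid points (>= 1000 recommended for
#'   table-quality values).
#' @param reps number of replicates (>= 10000 recommended).
#' @param seed optional integer seed.
#' @param probs quantile levels to return.
#' @return Named vector of empirical quantiles; the full vector of
#'   simulated suprema is attached as attribute `"sups"`.
#' @export
simulate_bb_sup <- function(dim, grid_size = 2000L, reps = 10000L,
                            seed = NULL, probs = c(0.90, 0.95, 0.99)) {
  stopifnot(dim >= 1, grid_size >= 1, reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  sups <- bb_sup_cpp(as.integer(dim), as.integer(grid_size),
                     as.integer(reps))
  q <- stats::quantile(sups, probs, names = TRUE)
  attr(q, "sups") <- sups
  q
}
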