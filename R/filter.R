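#' Conditional intensity filter
#'
#' Runs the intensity recursion \eqn{\tilde X_t(\theta) =
#' f_\theta(\tilde X_{t-1}(\theta), Y_{t-1})} from an arbitrary starting
#' value \eqn{\tilde X_1}.  The starting value is treated as fixed (not
#' a function of \eqn{\theta}); the estimation theory makes the
#' initialization asymptotically irrelevant.
#'
#' @param y integer count series.
#' @param theta parameter vector inside the model's feasible region.
#' @param model an [ingarch_model()].
#' @param x_init positive starting intensity \eqn{\tilde X_1}
#'   (conventionally the sample mean of `y`).
#' @return A list with `x_tilde` (length `n` intensities) and `x_init`.
#' @examples
#' m <- ingarch_model(dpd_family("poisson"))
#' intensity_filter(c(3, 1, 4), c(1, 0.2, 0.2), m, x_init = 8/3)$x_tilde
#' @export
intensity_filter <- function(y, theta, model, x_init) {
  .check_model(model)
  y <- .check_counts(y, model$family)
  theta <- .check_theta(theta, model)
  stopifnot(is.finite(x_init), x_init >= 0)
  res <- ingarch_filter_cpp(y, theta, model$form_code,
                            model$threshold_l, x_init, 0L)
  x <- as.numeric(res$x)
  if (any(x <= 0 & seq_along(x) > 1L))
    stop("non-positive filtered intensity; infeasible parameters")
  list(x_tilde = x, x_init = x_init)
}

#' Intensity filter with analytic derivatives
#'
#' Same recursion as [intensity_filter()], additionally propagating the
#' chain-rule recursions for \eqn{\partial \tilde X_t/\partial\theta}
#' and \eqn{\partial^2 \tilde X_t/\partial\theta\partial\theta^T}.  For
#' the linear recursion these are
#' \eqn{g_t = (1, \tilde X_{t-1}, Y_{t-1})^T + a\, g_{t-1}} and
#' \eqn{H_t = a H_{t-1} + e_a g_{t-1}^T + g_{t-1} e_a^T}, with
#' \eqn{g_1 = 0, H_1 = 0} because the starting value carries no
#' \eqn{\theta}-dependence.
#'
#' @inheritParams intensity_filter
#' @return A list with `x_tilde`, `grad` (an `n x d` matrix whose row t
#'   is \eqn{\partial\tilde X_t/\partial\theta}), `hess` (a
#'   `d x d x n` array) and `x_init`.
#' @export
intensity_derivatives <- function(y, theta, model, x_init) {
  .check_model(model)
  y <- .check_counts(y, model$family)
  theta <- .check_theta(theta, model)
  stopifnot(is.finite(x_init), x_init >= 0)
  res <- ingarch_filter_cpp(y, theta, model$form_code,
                            model$threshold_l, x_init, 2L)
  G <- res$grad
  colnames(G) <- model$param_names
  list(x_tilde = as.numeric(res$x), grad = G, hess = res$hess,
       x_init = x_init)
}
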