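#' INGARCH-type model specification
#'
#' Couples an exponential family with a conditional-intensity recursion.
#' Two recursions are available:
#' \describe{
#'   \item{`"ingarch11"`}{\eqn{X_t = d + a X_{t-1} + b Y_{t-1}}, with
#'     parameters \eqn{\theta = (d, a, b)} and stationarity region
#'     \eqn{a + b \le 1 - \epsilon}.}
#'   \item{`"intgarch11"`}{the threshold variant
#'     \eqn{X_t = d + a X_{t-1} + b_1 \max(Y_{t-1}-l, 0) +
#'     b_2 \min(Y_{t-1}, l)} with \eqn{\theta = (d, a, b_1, b_2)} and
#'     \eqn{a + \max(b_1, b_2) \le 1 - \epsilon}.}
#' }
#'
#' The parameter space is a compact box: \eqn{d \in [d_L, d_U]} with
#' \eqn{d_L > 0}, slopes in \eqn{[0, 1-\epsilon]}, plus the linear
#' stationarity constraint above.  The defaults are wide; the theory
#' only requires some compact set of this shape.
#'
#' @param family a [dpd_family()].
#' @param form intensity recursion, `"ingarch11"` or `"intgarch11"`.
#' @param threshold_l non-negative integer threshold (intgarch11 only).
#' @param d_lower,d_upper box for the intercept `d` (defaults 1e-4, 1e4).
#' @param eps stationarity margin \eqn{\epsilon > 0} (default 1e-3).
#' @return An object of class `ingarch_model`.
#' @examples
#' m <- ingarch_model(dpd_family("poisson"))
#' m$param_names
#' @export
ingarch_model <- function(family, form = c("ingarch11", "intgarch11"),
                          threshold_l = 1L, d_lower = 1e-4,
                          d_upper = 1e4, eps = 1e-3) {
  .check_family(family)
  form <- match.arg(form)
  stopifnot(d_lower > 0, d_upper > d_lower, eps > 0, eps < 0.5)
  if (form == "intgarch11") {
    stopifnot(length(threshold_l) == 1L, threshold_l >= 0,
              threshold_l == round(threshold_l))
    if (family$name != "poisson")
      stop("the threshold recursion is defined for the poisson family")
  }
  pn <- if (form == "ingarch11") c("d", "a", "b") else
    c("d", "a", "b1", "b2")
  structure(list(family = family, form = form,
                 form_code = if (form == "ingarch11") 1L else 2L,
                 threshold_l = as.integer(threshold_l),
                 param_names = pn, n_par = length(pn),
                 d_lower = d_lower, d_upper = d_upper, eps = eps),
            class = "ingarch_model")
}

#' @export
print.ingarch_model <- function(x, ...) {
  cat("<ingarch_model> ", x$form, ", family ", x$family$name,
      if (x$family$name == "negbin") paste0("(r=", x$family$r, ")") else "",
      if (x$form == "intgarch11") paste0(", l=", x$threshold_l) else "",
      "\n  parameters: ", paste(x$param_names, collapse = ", "),
      "  (d in [", format(x$d_lower), ", ", format(x$d_upper),
      "], margin eps = ", format(x$eps), ")\n", sep = "")
  invisible(x)
}

.check_model <- function(model) {
  if (!inherits(model, "ingarch_model"))
    stop("'model' must be an ingarch_model object")
  model
}

# box + stationarity feasibility; returns NULL or an error message
.theta_violation <- function(theta, model) {
  if (length(theta) != model$n_par)
    return(sprintf("theta must have length %d", model$n_par))
  if (any(!is.finite(theta))) return("theta must be finite")
  d <- theta[1L]
  if (d < model$d_lower || d > model$d_upper)
    return("intercept d outside [d_lower, d_upper]")
  if (any(theta[-1L] < 0)) return("slope parameters must be >= 0")
  s <- if (model$form == "ingarch11") theta[2L] + theta[3L] else
    theta[2L] + max(theta[3L], theta[4L])
  if (s > 1 - model$eps)
    return("stationarity constraint a + b <= 1 - eps violated")
  NULL
}

.check_theta <- function(theta, model) {
  msg <- .theta_violation(theta, model)
  if (!is.null(msg)) stop(msg)
  as.numeric(theta)
}

.check_counts <- function(y, family) {
  y <- as.numeric(y)
  if (length(y) < 1L || any(!is.finite(y)) || any(y != round(y)))
    stop("'y' must be a series of finite integers")
  if (any(y < family$support_min))
    stop("counts below the family support floor (",
         family$support_min, ")")
  as.integer(y)
}
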