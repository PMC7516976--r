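#' One-parameter exponential family for count responses
#'
#' Defines the conditional distribution used by the INGARCH-type models:
#' a pmf of the form \eqn{p(y|\eta) = \exp\{\eta y - A(\eta)\} h(y)} with
#' natural parameter \eqn{\eta}.  The derivative \eqn{B = A'} maps
#' \eqn{\eta} to the conditional mean and \eqn{B' = A''} to the
#' conditional variance, so \eqn{\eta_t = B^{-1}(X_t)} links the
#' intensity process to the distribution.
#'
#' Three families are supported:
#' \describe{
#'   \item{`"poisson"`}{\eqn{A(\eta)=e^\eta}, support \eqn{\{0,1,\dots\}}.}
#'   \item{`"negbin"`}{negative binomial with known dispersion `r`,
#'     counting failures before the r-th success;
#'     \eqn{A(\eta)=r\log(r/(1-e^\eta))}, support \eqn{\{0,1,\dots\}}.}
#'   \item{`"geometric"`}{geometric counting the total number of trials,
#'     so the support is \eqn{\{1,2,\dots\}} and the mean is \eqn{1/p};
#'     \eqn{A(\eta)=\eta-\log(1-e^\eta)}.  Intended for series that are
#'     bounded below by 1, such as return times of extreme events.}
#' }
#'
#' @param name family name; `"geometric_trials"` is accepted as an alias
#'   for `"geometric"`.
#' @param r known dispersion parameter of the negative binomial family
#'   (a positive integer, never estimated).  Ignored otherwise.
#' @return An object of class `dpd_family` with elements `name`, `r`,
#'   `support_min` and the internal family code.
#' @examples
#' fam <- dpd_family("negbin", r = 10)
#' natural_param(10, fam)            # log(10/20)
#' expfam_mean_var(log(0.5), fam)    # mean 10, variance 20
#' @export
dpd_family <- function(name = c("poisson", "negbin", "geometric",
                                "geometric_trials"), r = NULL) {
  name <- match.arg(name)
  if (name == "geometric_trials") name <- "geometric"
  if (name == "negbin") {
    if (is.null(r) || length(r) != 1L || !is.finite(r) || r <= 0 ||
        r != round(r))
      stop("the negbin family needs a known positive integer 'r'")
    r <- as.numeric(r)
  } else {
    r <- NA_real_
  }
  structure(list(name = name,
                 r = r,
                 support_min = if (name == "geometric") 1L else 0L,
                 code = switch(name, poisson = 1L, negbin = 2L,
                               geometric = 3L)),
            class = "dpd_family")
}

#' @export
print.dpd_family <- function(x, ...) {
  cat("<dpd_family> ", x$name,
      if (x$name == "negbin") paste0(" (r = ", x$r, ")") else "",
      ", support {", x$support_min, ", ", x$support_min + 1L, ", ...}\n",
      sep = "")
  invisible(x)
}

.check_family <- function(family) {
  if (!inherits(family, "dpd_family"))
    stop("'family' must be a dpd_family object")
  family
}

#' Natural parameter for a given conditional mean
#'
#' Computes \eqn{\eta = B^{-1}(x)}: `log(x)` for Poisson,
#' `log(x/(x+r))` for negative binomial, and `log(1 - 1/x)` for the
#' geometric (total-trials) family, whose valid means are \eqn{x > 1}.
#'
#' @param x conditional mean(s), strictly above the family's lower mean
#'   bound (0, or 1 for the geometric family).
#' @param family a [dpd_family()].
#' @return Natural parameter(s) \eqn{\eta}.
#' @export
natural_param <- function(x, family) {
  .check_family(family)
  lo <- if (family$name == "geometric") 1 else 0
  if (any(!is.finite(x)) || any(x <= lo))
    stop("mean out of range for family '", family$name,
         "': need x > ", lo)
  switch(family$name,
         poisson = log(x),
         negbin = log(x / (x + family$r)),
         geometric = log1p(-1 / x))
}

.eta_valid <- function(eta, family) {
  if (any(!is.finite(eta)))
    stop("non-finite natural parameter")
  if (family$name != "poisson" && any(eta >= 0))
    stop("natural parameter must be negative for family '",
         family$name, "'")
  invisible(TRUE)
}

.mean_of_eta <- function(eta, family) {
  switch(family$name,
         poisson = exp(eta),
         negbin = family$r * exp(eta) / (1 - exp(eta)),
         geometric = 1 / (1 - exp(eta)))
}

#' Exponential-family pmf
#'
#' Evaluates \eqn{p(y|\eta) = \exp\{\eta y - A(\eta)\}h(y)}.  Values of
#' `y` below the family's support floor return 0.
#'
#' @param y non-negative integer count(s).
#' @param eta natural parameter (must be negative for the negative
#'   binomial and geometric families).
#' @inheritParams natural_param
#' @return Probabilities in \[0, 1\].
#' @export
expfam_pmf <- function(y, eta, family) {
  .check_family(family)
  .eta_valid(eta, family)
  out <- numeric(length(y))
  ok <- y >= family$support_min & y == round(y)
  if (!any(ok)) return(out)
  q <- exp(eta)
  out[ok] <- switch(family$name,
    poisson = stats::dpois(y[ok], q),
    negbin = stats::dnbinom(y[ok], size = family$r, prob = 1 - q),
    geometric = stats::dgeom(y[ok] - 1L, prob = 1 - q))
  out
}

#' Conditional mean and variance of the family
#'
#' Returns \eqn{(B(\eta), B'(\eta))}, i.e. the conditional mean and
#' variance of the count given the past.
#'
#' @inheritParams expfam_pmf
#' @return Numeric vector `c(mean, var)` (for scalar `eta`), or a
#'   two-column matrix for vector input.
#' @export
expfam_mean_var <- function(eta, family) {
  .check_family(family)
  .eta_valid(eta, family)
  q <- exp(eta)
  mv <- switch(family$name,
    poisson = cbind(q, q),
    negbin = cbind(family$r * q / (1 - q), family$r * q / (1 - q)^2),
    geometric = cbind(1 / (1 - q), q / (1 - q)^2))
  colnames(mv) <- c("mean", "var")
  if (length(eta) == 1L) drop(mv) else mv
}
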