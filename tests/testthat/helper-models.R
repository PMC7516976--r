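# shared fixtures: model constructors, a fast single-start fit config,
# and a central finite-difference helper

pois_model <- function(...) ingarch_model(dpd_family("poisson"), ...)
nb_model <- function(r = 10, ...) ingarch_model(dpd_family("negbin", r = r), ...)
geo_model <- function(...) ingarch_model(dpd_family("geometric"), ...)
int_model <- function(l = 2, ...) ingarch_model(dpd_family("poisson"),
                                                form = "intgarch11",
                                                threshold_l = l, ...)

fast_cfg <- dpd_config(n_multistart = 1L)

fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

fd_jacobian <- function(f, x, h = 1e-6) {
  cols <- lapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  })
  do.call(cbind, cols)
}
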