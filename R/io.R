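#' Read a count series from a single-column file
#'
#' Accepts a plain text file with one non-negative integer per line
#' (CSV/TSV with a single column); an optional non-numeric header line
#' is skipped.  Parsing errors name the offending line.
#'
#' @param path file path.
#' @param family optional [dpd_family()]; when given, the series is
#'   checked against the family's support floor (e.g. >= 1 for the
#'   geometric family).
#' @return Integer vector of counts.
#' @export
read_count_series <- function(path, family = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("empty file: ", path)
  vals <- trimws(lines[keep])
  # single-column CSV/TSV: strip a trailing delimiter, reject multiples
  fields <- strsplit(vals, "[,\t;]")
  nf <- lengths(fields)
  if (any(nf > 1L))
    stop("line ", keep[which(nf > 1L)[1L]],
         ": expected a single column")
  vals <- vapply(fields, `[`, "", 1L)
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(vals[1L])))) start <- 2L
  if (start > length(vals)) stop("no data rows in ", path)
  v <- suppressWarnings(as.numeric(vals[start:length(vals)]))
  lineno <- keep[start:length(vals)]
  bad <- which(is.na(v))
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": not a number ('",
         vals[start:length(vals)][bad[1L]], "')")
  bad <- which(v != round(v) | v < 0)
  if (length(bad))
    stop("line ", lineno[bad[1L]],
         ": not a non-negative integer ('", v[bad[1L]], "')")
  y <- as.integer(v)
  if (!is.null(family)) {
    .check_family(family)
    if (any(y < family$support_min))
      stop("counts below the support floor (", family$support_min,
           ") of family '", family$name, "'")
  }
  y
}

#' Write deterministic example datasets
#'
#' Generates a bundle of small synthetic fixtures for demonstrations and
#' smoke tests: clean Poisson / negative binomial / geometric INGARCH
#' series (n = 500), contaminated twins of the Poisson and negative
#' binomial series, one series with a mid-sample parameter change, and
#' one synthetic heavy-tailed "log-return-like" real-valued series for
#' [return_times()].  A JSON manifest records the true parameters and
#' seeds.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed; the same seed reproduces the files
#'   byte-for-byte.
#' @return Invisibly, the manifest as a list.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- 500L
  th <- c(1, 0.2, 0.2)
  pois <- ingarch_model(dpd_family("poisson"))
  nb <- ingarch_model(dpd_family("negbin", r = 10))
  geo <- ingarch_model(dpd_family("geometric"), d_lower = 0.05)
  gth <- c(1.2, 0.3, 0.3)

  wr <- function(y, name) {
    writeLines(c("count", format(y, scientific = FALSE)),
               file.path(out_dir, name))
  }
  y_pois <- simulate_ingarch(pois, th, n, seed = seed)$y
  y_nb <- simulate_ingarch(nb, th, n, seed = seed + 1L)$y
  y_geo <- simulate_ingarch(geo, gth, n, seed = seed + 2L, x1 = 2)$y
  cs <- contamination_spec(p = 0.03, family = "poisson", gamma = 10)
  y_pois_c <- contaminate(y_pois, cs, seed = seed + 3L)
  csnb <- contamination_spec(p = 0.03, family = "negbin", kappa = 0.5)
  y_nb_c <- contaminate(y_nb, csnb, seed = seed + 4L)
  y_chg <- simulate_ingarch(pois, th, n, seed = seed + 5L,
                            theta1 = c(1, 0.2, 0.4))$y
  set.seed(seed + 6L)
  ret <- stats::rt(2000L, df = 4) * 0.02   # heavy-tailed pseudo-returns
  wr(y_pois, "poisson_clean.csv")
  wr(y_nb, "negbin_clean.csv")
  wr(y_geo, "geometric_clean.csv")
  wr(y_pois_c, "poisson_contaminated.csv")
  wr(y_nb_c, "negbin_contaminated.csv")
  wr(y_chg, "poisson_change.csv")
  writeLines(c("value", format(ret, digits = 8, scientific = FALSE)),
             file.path(out_dir, "synthetic_returns.csv"))
  manifest <- list(
    seed = seed, n = n,
    poisson_clean = list(theta = th, family = "poisson"),
    negbin_clean = list(theta = th, family = "negbin", r = 10),
    geometric_clean = list(theta = gth, family = "geometric"),
    poisson_contaminated = list(theta = th, p = 0.03, gamma = 10),
    negbin_contaminated = list(theta = th, p = 0.03, r = 10,
                               kappa = 0.5),
    poisson_change = list(theta = th, theta1 = c(1, 0.2, 0.4),
                          change_at = n %/% 2L),
    synthetic_returns = list(dist = "t4 scaled by 0.02", n = 2000L))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
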