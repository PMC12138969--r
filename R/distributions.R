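#' Log-Gumbel (inverse Weibull) distribution
#'
#' Density, distribution function, quantile function and random
#' generation for the log-Gumbel distribution: the Gumbel (type-I
#' extreme value, maximum convention) distribution applied to the
#' natural log of a positive variate.  On the raw scale this is the
#' inverse Weibull (Frechet) distribution, one of the five candidate
#' families used for species sensitivity distributions.
#'
#' The CDF is `exp(-exp(-(log(x) - location) / scale))`.
#'
#' @param x,q vector of positive quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param location location parameter on the log-concentration scale.
#' @param scale scale parameter on the log-concentration scale
#'   (must be positive).
#' @param log,lower.tail logical, as for [stats::plnorm()].
#' @return `dlgumbel` the density, `plgumbel` the CDF, `qlgumbel` the
#'   quantile function and `rlgumbel` random draws.
#' @examples
#' plgumbel(qlgumbel(0.05, 1, 0.5), 1, 0.5)
#' @export
dlgumbel <- function(x, location = 0, scale = 1, log = FALSE) {
  stopifnot(scale > 0)
  z <- (base::log(x) - location) / scale
  ld <- -z - exp(-z) - base::log(scale) - base::log(x)
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname dlgumbel
#' @export
plgumbel <- function(q, location = 0, scale = 1, lower.tail = TRUE) {
  stopifnot(scale > 0)
  p <- ifelse(q <= 0, 0, exp(-exp(-(base::log(pmax(q, .Machine$double.xmin)) - location) / scale)))
  if (lower.tail) p else 1 - p
}

#' @rdname dlgumbel
#' @export
qlgumbel <- function(p, location = 0, scale = 1) {
  stopifnot(scale > 0, all(p >= 0 & p <= 1))
  exp(location - scale * base::log(-base::log(p)))
}

#' @rdname dlgumbel
#' @export
rlgumbel <- function(n, location = 0, scale = 1) {
  qlgumbel(runif(n), location, scale)
}

#' Log-logistic distribution (location/scale on the log scale)
#'
#' Density, distribution function, quantile function and random
#' generation for the log-logistic distribution, parameterized as a
#' logistic distribution on the natural log of the variate.  `location`
#' is the log of the median; `scale` controls spread.
#'
#' @inheritParams dlgumbel
#' @return `dllogis` the density, `pllogis` the CDF, `qllogis` the
#'   quantile function and `rllogis` random draws.
#' @examples
#' qllogis(0.5, log(100), 1) # median 100
#' @export
dllogis <- function(x, location = 0, scale = 1, log = FALSE) {
  stopifnot(scale > 0)
  ld <- dlogis(base::log(x), location, scale, log = TRUE) - base::log(x)
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname dllogis
#' @export
pllogis <- function(q, location = 0, scale = 1, lower.tail = TRUE) {
  stopifnot(scale > 0)
  ifelse(q <= 0,
         if (lower.tail) 0 else 1,
         plogis(base::log(pmax(q, .Machine$double.xmin)), location, scale,
                lower.tail = lower.tail))
}

#' @rdname dllogis
#' @export
qllogis <- function(p, location = 0, scale = 1) {
  stopifnot(scale > 0, all(p >= 0 & p <= 1))
  exp(qlogis(p, location, scale))
}

#' @rdname dllogis
#' @export
rllogis <- function(n, location = 0, scale = 1) {
  qllogis(runif(n), location, scale)
}

# ---------------------------------------------------------------------------
# family registry ------------------------------------------------------------

#' Names of the candidate SSD families
#'
#' The five unimodal distributions conventionally fitted to species
#' sensitivity data: gamma, log-Gumbel (inverse Weibull), log-logistic,
#' log-normal and Weibull.  The order given here is also the fixed
#' tie-break order used by [select_ssd()].
#'
#' @return character vector of family names.
#' @export
ssd_families <- function() {
  c("log_normal", "log_logistic", "log_gumbel", "gamma", "weibull")
}

# dispatch table: each entry supplies d/p/q/r taking a named params vector
.family_funs <- function(family) {
  switch(family,
    log_normal = list(
      d = function(x, pr, log = FALSE) dlnorm(x, pr[["meanlog"]], pr[["sdlog"]], log = log),
      p = function(q, pr) plnorm(q, pr[["meanlog"]], pr[["sdlog"]]),
      q = function(p, pr) qlnorm(p, pr[["meanlog"]], pr[["sdlog"]]),
      r = function(n, pr) rlnorm(n, pr[["meanlog"]], pr[["sdlog"]])),
    log_logistic = list(
      d = function(x, pr, log = FALSE) dllogis(x, pr[["location"]], pr[["scale"]], log = log),
      p = function(q, pr) pllogis(q, pr[["location"]], pr[["scale"]]),
      q = function(p, pr) qllogis(p, pr[["location"]], pr[["scale"]]),
      r = function(n, pr) rllogis(n, pr[["location"]], pr[["scale"]])),
    log_gumbel = list(
      d = function(x, pr, log = FALSE) dlgumbel(x, pr[["location"]], pr[["scale"]], log = log),
      p = function(q, pr) plgumbel(q, pr[["location"]], pr[["scale"]]),
      q = function(p, pr) qlgumbel(p, pr[["location"]], pr[["scale"]]),
      r = function(n, pr) rlgumbel(n, pr[["location"]], pr[["scale"]])),
    gamma = list(
      d = function(x, pr, log = FALSE) dgamma(x, pr[["shape"]], pr[["rate"]], log = log),
      p = function(q, pr) pgamma(q, pr[["shape"]], pr[["rate"]]),
      q = function(p, pr) qgamma(p, pr[["shape"]], pr[["rate"]]),
      r = function(n, pr) rgamma(n, pr[["shape"]], pr[["rate"]])),
    weibull = list(
      d = function(x, pr, log = FALSE) dweibull(x, pr[["shape"]], pr[["scale"]], log = log),
      p = function(q, pr) pweibull(q, pr[["shape"]], pr[["scale"]]),
      q = function(p, pr) qweibull(p, pr[["shape"]], pr[["scale"]]),
      r = function(n, pr) rweibull(n, pr[["shape"]], pr[["scale"]])),
    stop("unknown SSD family: ", family, call. = FALSE)
  )
}
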