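#' Fit one candidate species sensitivity distribution
#'
#' Maximum-likelihood fit of a single candidate family to a vector of
#' per-species sensitivity values (concentrations in ug/L).
#'
#' Parameterizations: `log_normal` is `meanlog`/`sdlog` (MLE in closed
#' form: mean of the logs and their root-mean-square deviation);
#' `log_logistic` and `log_gumbel` are location-scale families on the
#' natural log of concentration; `gamma` (`shape`/`rate`) and `weibull`
#' (`shape`/`scale`) act on the raw scale and are fitted with
#' [fitdistrplus::fitdist()].  Fits are deterministic: optimizer starts
#' are derived from moment estimates of the (log) data, and the data are
#' internally centred on the log scale (equivalently rescaled by their
#' geometric mean) so that rescaling all concentrations by a constant
#' shifts the fit exactly equivariantly.
#'
#' @param values positive concentrations, one per species (ug/L).
#' @param family one of [ssd_families()].
#' @param min_n minimum sample size accepted for fitting (default 8,
#'   the conventional SSD floor).
#' @return an object of class `ssd_fit`: a list with elements `family`,
#'   `params` (named numeric), `n`, `loglik`, `aic`, `aicc`, `gof`
#'   (Anderson-Darling and Kolmogorov-Smirnov statistics) and `values`
#'   (the data, kept for bootstrapping).
#' @examples
#' fit <- fit_ssd(rlnorm(32, log(5), 1.2), "log_normal")
#' protective_concentration(fit, 95)
#' @seealso [select_ssd()], [bootstrap_ci()]
#' @export
fit_ssd <- function(values, family = ssd_families(), min_n = 8) {
  family <- match.arg(family)
  values <- as.numeric(values)
  if (anyNA(values) || any(values <= 0)) {
    stop("all sensitivity values must be positive and non-missing", call. = FALSE)
  }
  n <- length(values)
  if (n < min_n) {
    stop("need at least ", min_n, " species values to fit an SSD; got ", n,
         call. = FALSE)
  }
  lx <- log(values)
  if (max(lx) - min(lx) < 1e-12) {
    stop("degenerate sample: all sensitivity values are identical", call. = FALSE)
  }

  # centre on the log scale; refits are then identical under rescaling
  m0 <- mean(lx)
  params <- switch(family,
    log_normal = {
      cs <- sqrt(mean((lx - m0)^2))        # closed-form MLE
      c(meanlog = m0, sdlog = cs)
    },
    log_logistic = {
      pr <- .fit_logls(lx - m0, dfun = function(z, loc, sc) dlogis(z, loc, sc, log = TRUE),
                       start = c(median(lx - m0), sd(lx) * sqrt(3) / pi))
      c(location = pr[1] + m0, scale = pr[2])
    },
    log_gumbel = {
      sc0 <- sd(lx) * sqrt(6) / pi
      pr <- .fit_logls(lx - m0,
                       dfun = function(z, loc, sc) {
                         u <- (z - loc) / sc
                         -u - exp(-u) - log(sc)
                       },
                       start = c(-0.5772157 * sc0, sc0))
      c(location = pr[1] + m0, scale = pr[2])
    },
    gamma = {
      s0 <- exp(m0)
      y <- values / s0
      # Minka's closed-form approximation as the deterministic start
      tt <- log(mean(y)) - mean(log(y))
      sh0 <- (3 - tt + sqrt((tt - 3)^2 + 24 * tt)) / (12 * tt)
      fd <- .fitdist_quiet(y, "gamma",
                           start = list(shape = sh0, rate = sh0 / mean(y)))
      c(shape = unname(fd["shape"]), rate = unname(fd["rate"]) / s0)
    },
    weibull = {
      s0 <- exp(m0)
      y <- values / s0
      ly <- log(y)
      # start from the extreme-value moments of log(y)
      k0 <- pi / (sd(ly) * sqrt(6))
      fd <- .fitdist_quiet(y, "weibull",
                           start = list(shape = k0,
                                        scale = exp(mean(ly) + 0.5772157 / k0)))
      c(shape = unname(fd["shape"]), scale = unname(fd["scale"]) * s0)
    })

  funs <- .family_funs(family)
  ll <- sum(funs$d(values, params, log = TRUE))
  if (!is.finite(ll)) {
    stop("fit for family '", family, "' produced a non-finite log-likelihood",
         call. = FALSE)
  }
  k <- 2L
  aic <- -2 * ll + 2 * k
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  structure(
    list(family = family, params = params, n = n, loglik = ll,
         aic = aic, aicc = aicc,
         gof = .gof_stats(values, funs$p, params),
         values = values),
    class = "ssd_fit")
}

# 2-parameter location-scale MLE on the log scale; Nelder-Mead with
# log-parameterized scale, then a BFGS polish for tight convergence
.fit_logls <- function(z, dfun, start) {
  nll <- function(par) {
    sc <- exp(par[2])
    -sum(dfun(z, par[1], sc))
  }
  p0 <- c(start[1], log(max(start[2], 1e-8)))
  o1 <- optim(p0, nll, method = "Nelder-Mead",
              control = list(reltol = 1e-12, maxit = 2000))
  o2 <- optim(o1$par, nll, method = "BFGS",
              control = list(reltol = 1e-14, maxit = 500))
  if (o2$convergence != 0 && o1$convergence != 0) {
    stop("maximum-likelihood fit did not converge", call. = FALSE)
  }
  best <- if (o2$value <= o1$value) o2$par else o1$par
  c(best[1], exp(best[2]))
}

.fitdist_quiet <- function(x, distr, start = NULL) {
  fd <- NULL
  err <- NULL
  # fitdist prints optimizer failures before signalling; swallow both
  utils::capture.output(
    fd <- tryCatch(
      suppressWarnings(fitdistrplus::fitdist(x, distr, method = "mle",
                                             start = start)),
      error = function(e) {
        err <<- conditionMessage(e)
        NULL
      }))
  if (!is.null(fd)) return(coef(fd))
  # heavy-tailed samples can defeat fitdist's finite-difference step;
  # retry with a log-parameterized direct optimization from the same start
  dfun <- if (distr == "gamma") dgamma else dweibull
  nll <- function(p) -sum(dfun(x, exp(p[1]), exp(p[2]), log = TRUE))
  p0 <- log(unlist(start))
  o <- tryCatch({
    o1 <- optim(p0, nll, method = "Nelder-Mead",
                control = list(reltol = 1e-12, maxit = 2000))
    optim(o1$par, nll, method = "BFGS",
          control = list(reltol = 1e-14, maxit = 500))
  }, error = function(e) NULL)
  if (is.null(o) || !is.finite(o$value)) {
    stop("fit for family '", distr, "' failed to converge: ", err,
         call. = FALSE)
  }
  setNames(exp(o$par), names(start))
}

# Anderson-Darling and Kolmogorov-Smirnov statistics against the fitted CDF
.gof_stats <- function(x, pfun, params) {
  n <- length(x)
  u <- sort(pmin(pmax(pfun(sort(x), params), 1e-15), 1 - 1e-15))
  i <- seq_len(n)
  ad <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  ks <- max(i / n - u, u - (i - 1) / n)
  list(anderson_darling = ad, kolmogorov_smirnov = ks)
}

#' @export
print.ssd_fit <- function(x, ...) {
  cat("SSD fit:", x$family, " (n =", x$n, ")\n")
  cat("  params:", paste(names(x$params), signif(x$params, 5), sep = " = ",
                         collapse = ", "), "\n")
  cat("  logLik:", signif(x$loglik, 6), " AICc:", signif(x$aicc, 6),
      " AD:", signif(x$gof$anderson_darling, 4),
      " KS:", signif(x$gof$kolmogorov_smirnov, 4), "\n")
  invisible(x)
}

#' Fit all candidate SSD families
#'
#' Convenience wrapper fitting each requested family; non-converging
#' families are dropped with a warning rather than failing the set.
#'
#' @inheritParams fit_ssd
#' @param families families to try (default all five).
#' @param quiet drop non-converging families silently (they are still
#'   recorded in the `"dropped"` attribute) instead of warning.
#' @return named list of `ssd_fit` objects (converged families only),
#'   with attribute `"dropped"` naming any family that failed.
#' @export
fit_ssd_all <- function(values, families = ssd_families(), min_n = 8,
                        quiet = FALSE) {
  fits <- list()
  dropped <- character(0)
  for (fam in families) {
    f <- tryCatch(fit_ssd(values, fam, min_n = min_n),
                  error = function(e) {
                    dropped <<- c(dropped, setNames(conditionMessage(e), fam))
                    if (!quiet) {
                      warning("family ", fam, " dropped: ",
                              conditionMessage(e), call. = FALSE)
                    }
                    NULL
                  })
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (!length(fits)) stop("no candidate SSD family converged", call. = FALSE)
  attr(fits, "dropped") <- dropped
  fits
}

#' Select the best-fitting SSD
#'
#' Chooses the fit with minimum AICc among the converged candidates.
#' Ties (within `tie_tol`) are broken by a fixed family order
#' (log_normal, log_logistic, log_gumbel, gamma, weibull) so selection
#' is deterministic.
#'
#' @param fits list of `ssd_fit` objects (e.g. from [fit_ssd_all()]).
#' @param tie_tol absolute AICc difference treated as a tie.
#' @return the selected `ssd_fit`, with attribute `"rationale"` naming
#'   each candidate's AICc.
#' @export
select_ssd <- function(fits, tie_tol = 1e-9) {
  if (inherits(fits, "ssd_fit")) fits <- list(fits)
  if (!length(fits)) stop("no fits supplied to select from", call. = FALSE)
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  fams <- vapply(fits, function(f) f$family, character(1))
  ord <- order(aiccs, match(fams, ssd_families()))
  best <- ord[1]
  # prefer earlier family order among ties with the minimum
  ties <- which(aiccs <= aiccs[best] + tie_tol)
  if (length(ties) > 1) best <- ties[which.min(match(fams[ties], ssd_families()))]
  out <- fits[[best]]
  attr(out, "rationale") <- setNames(aiccs, fams)
  out
}

#' Protective concentration (PC) from a fitted SSD
#'
#' The concentration protecting `protection_pct` percent of species:
#' the (100 - protection_pct)-th percentile of the fitted distribution.
#' PC99 is the 1st percentile, PC95 the 5th, and so on (also known as
#' hazardous concentrations HC1, HC5, ...).
#'
#' @param fit an `ssd_fit`.
#' @param protection_pct protection level(s) in percent, strictly
#'   between 0 and 100.
#' @return concentration(s) in ug/L, strictly decreasing in
#'   `protection_pct`.
#' @examples
#' fit <- fit_ssd(rlnorm(32, 0, 1), "log_normal")
#' protective_concentration(fit, c(99, 95, 90, 80))
#' @export
protective_concentration <- function(fit, protection_pct) {
  stopifnot(inherits(fit, "ssd_fit"))
  if (any(protection_pct <= 0 | protection_pct >= 100)) {
    stop("protection_pct must lie strictly between 0 and 100", call. = FALSE)
  }
  funs <- .family_funs(fit$family)
  funs$q((100 - protection_pct) / 100, fit$params)
}

#' Potentially affected fraction (PAF) at a concentration
#'
#' The fitted SSD's CDF at `concentration`, in percent: the fraction of
#' species expected to be affected at that exposure concentration.
#' Inverse of [protective_concentration()].
#'
#' @inheritParams protective_concentration
#' @param concentration positive concentration(s) in ug/L.
#' @return percent affected, in \[0, 100\].
#' @export
fraction_affected <- function(fit, concentration) {
  stopifnot(inherits(fit, "ssd_fit"))
  if (any(concentration <= 0)) {
    stop("concentration must be positive", call. = FALSE)
  }
  funs <- .family_funs(fit$family)
  100 * funs$p(concentration, fit$params)
}
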