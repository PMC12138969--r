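#' Parametric-bootstrap confidence intervals for protective concentrations
#'
#' Fits `family` to `values`, then repeatedly (i) draws a synthetic
#' sample of the same size from the fitted distribution, (ii) refits,
#' and (iii) recomputes each protective concentration.  Confidence
#' intervals are the 2.5/97.5 percentiles of the bootstrap replicates;
#' the point estimate comes from the original-data fit (set
#' `pc_point = "bootstrap_median"` for the replicate median instead).
#'
#' Reproducibility: a single `seed` initializes a draw of one
#' sub-seed per replicate (counter-style splitting), so each
#' replicate's random stream is fixed regardless of execution order.
#'
#' @inheritParams fit_ssd
#' @param protection_pcts protection levels in percent (default the
#'   canonical 99, 95, 90, 80).
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed integer seed governing all bootstrap randomness.
#' @param pc_point `"fit"` (default) or `"bootstrap_median"`.
#' @param max_failure_rate abort if more than this fraction of
#'   replicates fails to refit (default 0.2).
#' @return a data frame of class `pc_estimate` with columns
#'   `protection_pct`, `point`, `ci_lower`, `ci_upper`, `n_boot`.
#' @examples
#' bootstrap_ci(rlnorm(32, 0, 1), "log_normal", n_boot = 50, seed = 1)
#' @export
bootstrap_ci <- function(values, family = ssd_families(),
                         protection_pcts = c(99, 95, 90, 80),
                         n_boot = 10000, seed = 1,
                         pc_point = c("fit", "bootstrap_median"),
                         max_failure_rate = 0.2, min_n = 8) {
  family <- match.arg(family)
  pc_point <- match.arg(pc_point)
  if (!is.numeric(n_boot) || n_boot < 1) {
    stop("n_boot must be a positive integer", call. = FALSE)
  }
  n_boot <- as.integer(n_boot)
  fit <- fit_ssd(values, family, min_n = min_n)
  funs <- .family_funs(family)
  n <- fit$n

  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_boot)

  reps <- matrix(NA_real_, n_boot, length(protection_pcts))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(sub_seeds[b])
    x_star <- funs$r(n, fit$params)
    f_star <- tryCatch(fit_ssd(x_star, family, min_n = min_n),
                       error = function(e) NULL)
    if (is.null(f_star)) {
      failed <- failed + 1L
      next
    }
    reps[b, ] <- protective_concentration(f_star, protection_pcts)
  }
  if (failed / n_boot > max_failure_rate) {
    stop("bootstrap unstable: ", failed, " of ", n_boot,
         " replicates failed to refit family '", family, "'", call. = FALSE)
  }

  point <- protective_concentration(fit, protection_pcts)
  if (pc_point == "bootstrap_median") {
    point <- apply(reps, 2, median, na.rm = TRUE)
  }
  ci <- apply(reps, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE,
              names = FALSE)
  out <- data.frame(
    protection_pct = protection_pcts,
    point = point,
    ci_lower = pmin(ci[1, ], point),
    ci_upper = pmax(ci[2, ], point),
    n_boot = n_boot)
  class(out) <- c("pc_estimate", "data.frame")
  attr(out, "family") <- family
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_failed") <- failed
  out
}

#' Serialize an SSD fit report as JSON
#'
#' One JSON record per fit with a stable key order
#' (`family, params, n, loglik, aicc, gof, seed, n_boot`), suitable for
#' diffable run logs.
#'
#' @param fit an `ssd_fit`.
#' @param seed,n_boot optional provenance fields recorded verbatim.
#' @return a one-element character vector of JSON.
#' @export
ssd_fit_report <- function(fit, seed = NULL, n_boot = NULL) {
  stopifnot(inherits(fit, "ssd_fit"))
  rec <- list(
    family = fit$family,
    params = as.list(fit$params),
    n = fit$n,
    loglik = fit$loglik,
    aicc = fit$aicc,
    gof = fit$gof,
    seed = seed,
    n_boot = n_boot)
  rec <- rec[!vapply(rec, is.null, logical(1))]
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
}
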