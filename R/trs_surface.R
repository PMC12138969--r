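#' Configuration for building a temporal response surface
#'
#' Collects the knobs of a TRS run in one validated object.
#'
#' @param class_map named character vector mapping each data class to a
#'   reference class or `"exclude"`.
#' @param calibration named list, one entry per reference class, each a
#'   list with `ec_measured` (ug/L) and `measured_day` (days): the
#'   reference species' observed acute effect concentration and its
#'   test duration.
#' @param protection_levels protection percentages (default
#'   `c(99, 95, 90, 80)`).
#' @param days exposure days of the surface (default `1:100`; the
#'   100-day cap reflects the inflection-window argument and is
#'   configurable).
#' @param families candidate SSD families fitted per day.
#' @param forced_family optional override of AICc selection: a single
#'   family name applied to every day, or a named character vector
#'   keyed by day (days not named fall back to AICc).
#' @param n_boot bootstrap replicates for per-day PC confidence
#'   intervals (0 disables intervals; the conventional full run uses
#'   10000).
#' @param seed integer seed for all bootstrap randomness.
#' @param min_fit_size minimum species count per day-slice fit.
#' @param pc_point `"fit"` or `"bootstrap_median"` (see
#'   [bootstrap_ci()]).
#' @return a list of class `trs_config`.
#' @export
trs_config <- function(class_map, calibration,
                       protection_levels = c(99, 95, 90, 80),
                       days = 1:100, families = ssd_families(),
                       forced_family = NULL, n_boot = 0, seed = 1,
                       min_fit_size = 8, pc_point = "fit") {
  stopifnot(is.character(class_map), !is.null(names(class_map)))
  if (!length(days)) stop("empty day range", call. = FALSE)
  refs <- setdiff(unique(class_map), "exclude")
  miss <- setdiff(refs, names(calibration))
  if (length(miss)) {
    stop("calibration missing for reference class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (cl in refs) {
    cal <- calibration[[cl]]
    if (is.null(cal$ec_measured) || cal$ec_measured <= 0 ||
        is.null(cal$measured_day) || cal$measured_day <= 0) {
      stop("calibration for class ", cl,
           " needs positive ec_measured and measured_day", call. = FALSE)
    }
  }
  bad <- protection_levels <= 0 | protection_levels >= 100
  if (any(bad)) stop("protection levels must lie in (0, 100)", call. = FALSE)
  families <- match.arg(families, ssd_families(), several.ok = TRUE)
  if (!is.null(forced_family)) {
    stopifnot(all(forced_family %in% ssd_families()))
  }
  structure(
    list(class_map = class_map, calibration = calibration,
         protection_levels = protection_levels, days = as.integer(days),
         families = families, forced_family = forced_family,
         n_boot = as.integer(n_boot), seed = as.integer(seed),
         min_fit_size = min_fit_size, pc_point = pc_point),
    class = "trs_config")
}

.forced_family_for_day <- function(config, day) {
  ff <- config$forced_family
  if (is.null(ff)) return(NULL)
  if (is.null(names(ff))) {
    if (length(ff) == 1) return(ff)
    stop("forced_family must be a single family or named by day", call. = FALSE)
  }
  key <- as.character(day)
  if (key %in% names(ff)) ff[[key]] else NULL
}

#' Build the temporal response surface
#'
#' For every exposure day the acute sensitivity set is rescaled with the
#' class-wise temporal adjustment factors, the candidate SSD families
#' are fitted to the adjusted values, the best fit is selected by AICc
#' (unless `forced_family` overrides it), and protective concentrations
#' are computed — with parametric-bootstrap confidence intervals when
#' `n_boot > 0`.  Stacking the daily SSDs over days 1-100 gives a
#' surface over concentration x affected fraction x exposure duration.
#'
#' All randomness is derived from `config$seed` (one sub-seed per day),
#' so a rebuilt surface with the same inputs and configuration is
#' identical.
#'
#' @param sens_set acute `sensitivity_set` (one value per species,
#'   already converted to the chronic-estimate basis).
#' @param models named list of [time_response_model()] objects keyed by
#'   reference class.
#' @param config a [trs_config()].
#' @return an object of class `trs_surface`: list with `days`,
#'   `pc_table` (long data frame: day, family, protection_pct, point,
#'   ci_lower, ci_upper, n_species), `fits` (selected `ssd_fit` per
#'   day), `family_by_day`, `adjusted` (per-day datasets), `tafs`,
#'   `config` and `provenance`.
#' @examples
#' spec <- community_spec(seed = 7)
#' com <- generate_community(spec)
#' # see vignette("temporal-response-surface") for the full pipeline
#' @export
build_trs <- function(sens_set, models, config) {
  stopifnot(inherits(config, "trs_config"))
  refs <- setdiff(unique(config$class_map), "exclude")
  miss <- setdiff(refs, names(models))
  if (length(miss)) {
    stop("no time-response model for reference class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tafs <- lapply(setNames(refs, refs), function(cl) {
    cal <- config$calibration[[cl]]
    compute_taf_table(models[[cl]], cal$ec_measured, cal$measured_day,
                      days = config$days)
  })

  set.seed(config$seed)
  day_seeds <- sample.int(.Machine$integer.max - 1L, length(config$days))

  fits <- vector("list", length(config$days))
  adjusted <- vector("list", length(config$days))
  pc_rows <- vector("list", length(config$days))
  for (i in seq_along(config$days)) {
    day <- config$days[i]
    adj <- adjust_toxicity(sens_set, tafs, config$class_map, day)
    adjusted[[i]] <- adj
    forced <- .forced_family_for_day(config, day)
    sel <- tryCatch({
      if (is.null(forced)) {
        select_ssd(fit_ssd_all(adj$value, config$families,
                               min_n = config$min_fit_size, quiet = TRUE))
      } else {
        fit_ssd(adj$value, forced, min_n = config$min_fit_size)
      }
    }, error = function(e) {
      stop("SSD fitting failed on day ", day, ": ", conditionMessage(e),
           call. = FALSE)
    })
    fits[[i]] <- sel
    if (config$n_boot > 0) {
      pcs <- bootstrap_ci(adj$value, sel$family,
                          protection_pcts = config$protection_levels,
                          n_boot = config$n_boot, seed = day_seeds[i],
                          pc_point = config$pc_point,
                          min_n = config$min_fit_size)
      pc_rows[[i]] <- data.frame(
        day = day, family = sel$family,
        protection_pct = pcs$protection_pct, point = pcs$point,
        ci_lower = pcs$ci_lower, ci_upper = pcs$ci_upper,
        n_species = nrow(adj))
    } else {
      pt <- protective_concentration(sel, config$protection_levels)
      pc_rows[[i]] <- data.frame(
        day = day, family = sel$family,
        protection_pct = config$protection_levels, point = pt,
        ci_lower = NA_real_, ci_upper = NA_real_, n_species = nrow(adj))
    }
  }
  names(fits) <- names(adjusted) <- as.character(config$days)
  pc_table <- do.call(rbind, pc_rows)
  rownames(pc_table) <- NULL
  structure(
    list(days = config$days,
         pc_table = pc_table,
         fits = fits,
         family_by_day = setNames(
           vapply(fits, function(f) f$family, character(1)),
           config$days),
         adjusted = adjusted,
         tafs = tafs,
         config = config,
         provenance = list(seed = config$seed,
                           config_hash = .config_hash(config),
                           class_map = config$class_map)),
    class = "trs_surface")
}

.config_hash <- function(config) {
  # order-stable digest of the serialized configuration
  raw <- serialize(config, NULL, version = 2)
  sprintf("%08x-%08x", sum(as.integer(raw) * seq_along(raw)) %% 4294967291,
          length(raw))
}

#' @export
print.trs_surface <- function(x, ...) {
  cat("Temporal response surface:", length(x$days), "day slices, ",
      x$pc_table$n_species[1], "species\n")
  fams <- rle(unname(x$family_by_day))
  cat("  selected families:",
      paste(sprintf("%s (%d days)", fams$values, fams$lengths), collapse = ", "),
      "\n")
  cat("  protection levels:",
      paste(unique(x$pc_table$protection_pct), collapse = ", "), "\n")
  invisible(x)
}

#' Query the surface for a PAF or a protective concentration
#'
#' @param surface a [build_trs()] result.
#' @param day exposure day inside the surface.
#' @param mode `"paf"` (fraction of species affected, percent, at
#'   concentration `arg` ug/L) or `"pc"` (protective concentration at
#'   protection level `arg` percent).
#' @param arg concentration (ug/L) for `"paf"`, protection level for
#'   `"pc"`.
#' @return a single number: percent affected or ug/L.
#' @export
query_surface <- function(surface, day, mode = c("paf", "pc"), arg) {
  stopifnot(inherits(surface, "trs_surface"))
  mode <- match.arg(mode)
  key <- as.character(as.integer(day))
  if (!key %in% names(surface$fits)) {
    stop("day ", day, " is outside the surface (days ",
         min(surface$days), "-", max(surface$days), ")", call. = FALSE)
  }
  fit <- surface$fits[[key]]
  if (mode == "paf") fraction_affected(fit, arg)
  else protective_concentration(fit, arg)
}

#' First day a protective concentration falls below a threshold
#'
#' Scans the surface's PC point estimates in day order and returns the
#' smallest day at which PC(`protection_pct`) drops below `threshold`
#' (e.g. an analytical limit of reporting), or `NA` if it never does.
#'
#' @inheritParams query_surface
#' @param protection_pct protection level present in the surface.
#' @param threshold concentration threshold in ug/L.
#' @return integer day, or `NA_integer_`.
#' @export
first_day_below <- function(surface, protection_pct, threshold) {
  stopifnot(inherits(surface, "trs_surface"), threshold > 0)
  tab <- surface$pc_table
  tab <- tab[tab$protection_pct == protection_pct, , drop = FALSE]
  if (!nrow(tab)) {
    stop("protection level ", protection_pct, " is not in the surface",
         call. = FALSE)
  }
  tab <- tab[order(tab$day), , drop = FALSE]
  hit <- which(tab$point < threshold)
  if (!length(hit)) NA_integer_ else as.integer(tab$day[hit[1]])
}

#' Export the surface's protective concentrations as CSV
#'
#' Writes one row per day with the selected family, the species count,
#' and for each protection level the PC point (full precision) with CI
#' bounds, plus a two-significant-figure display column following the
#' usual guideline-table rounding convention.  Numeric columns are
#' serialized with 17 significant digits so a read-back reproduces the
#' values exactly.
#'
#' @param surface a `trs_surface`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_trs_table <- function(surface, path) {
  stopifnot(inherits(surface, "trs_surface"))
  tab <- surface$pc_table
  levels <- sort(unique(tab$protection_pct), decreasing = TRUE)
  wide <- data.frame(day = sort(unique(tab$day)))
  wide$family <- unname(surface$family_by_day[as.character(wide$day)])
  wide$n_species <- tab$n_species[match(wide$day, tab$day)]
  for (lv in levels) {
    sub <- tab[tab$protection_pct == lv, ]
    ix <- match(wide$day, sub$day)
    stub <- paste0("pc", format(lv, trim = TRUE))
    wide[[stub]] <- .full_precision(sub$point[ix])
    wide[[paste0(stub, "_lower")]] <- .full_precision(sub$ci_lower[ix])
    wide[[paste0(stub, "_upper")]] <- .full_precision(sub$ci_upper[ix])
    wide[[paste0(stub, "_2sf")]] <- signif(sub$point[ix], 2)
  }
  write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Basic perspective plot of the surface
#'
#' Renders the surface as affected fraction over log10 concentration x
#' exposure day using [graphics::persp()].  This is a diagnostic view,
#' not a publication figure.
#'
#' @param x a `trs_surface`.
#' @param n_conc grid resolution on the concentration axis.
#' @param ... passed to [graphics::persp()].
#' @return the persp transformation matrix, invisibly.
#' @export
plot.trs_surface <- function(x, n_conc = 60, ...) {
  lo <- log10(min(x$pc_table$point))
  hi <- log10(max(vapply(x$fits, function(f)
    protective_concentration(f, 1), numeric(1))))
  conc <- 10^seq(lo, hi, length.out = n_conc)
  z <- vapply(x$fits, function(f) fraction_affected(f, conc),
              numeric(n_conc))
  graphics::persp(log10(conc), x$days, z,
                  xlab = "log10 concentration (ug/L)", ylab = "exposure day",
                  zlab = "affected fraction (%)", theta = 35, phi = 25,
                  ticktype = "detailed", ...)
}
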