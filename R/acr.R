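#' Build an ACR-adjusted SSD scenario
#'
#' Converts acute sensitivity values to chronic estimates by dividing
#' by an acute-to-chronic ratio (ACR) — either one default value (e.g.
#' the guideline default 10, or 50, or 100) or a per-class table of
#' literature-derived ratios — combines them with observed chronic
#' values (chronic data take precedence and pass through unmodified),
#' fits the candidate SSD families to the combined set, selects by
#' AICc and computes protective concentrations.
#'
#' @param chronic `sensitivity_set` of observed chronic values (may be
#'   empty: pass `NULL`).
#' @param acute `sensitivity_set` of acute values.
#' @param acr single positive number, or named numeric vector keyed by
#'   taxonomic class; a class present in the acute data but absent
#'   from a per-class table is a configuration error.
#' @param name scenario label (e.g. `"ACR10"`, `"ACR_lit"`).
#' @param protection_levels protection percentages.
#' @param families candidate families.
#' @param n_boot bootstrap replicates for PC confidence intervals
#'   (0 disables).
#' @param seed bootstrap seed.
#' @param min_fit_size minimum combined sample size.
#' @return an object of class `acr_scenario`: list with `name`,
#'   `acr_values`, `combined_set`, `fit` (selected `ssd_fit`) and
#'   `pcs` (data frame of PC estimates).
#' @examples
#' acute <- aggregate_species(generate_community(community_spec(seed = 3))$records)
#' apply_acr_scenario(NULL, acute, acr = 10, n_boot = 0)
#' @export
apply_acr_scenario <- function(chronic, acute, acr, name = NULL,
                               protection_levels = c(99, 95, 90, 80),
                               families = ssd_families(), n_boot = 0,
                               seed = 1, min_fit_size = 8) {
  if (any(acr <= 0)) stop("ACR values must be positive", call. = FALSE)
  if (is.null(name)) {
    name <- if (length(acr) == 1 && is.null(names(acr))) {
      paste0("ACR", format(acr, trim = TRUE))
    } else "ACR_per_class"
  }
  adj <- acute
  if (length(acr) == 1 && is.null(names(acr))) {
    adj$value <- adj$value / acr
  } else {
    miss <- setdiff(unique(adj$taxon_class), names(acr))
    if (length(miss)) {
      stop("per-class ACR table lacks class(es): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    adj$value <- adj$value / unname(acr[adj$taxon_class])
  }
  adj$value_kind <- "acute_estimated"

  if (!is.null(chronic) && nrow(chronic)) {
    chronic$value_kind <- "chronic_observed"
    # chronic precedence: drop acute rows for species with chronic data
    dup <- tolower(trimws(adj$species_name)) %in%
      tolower(trimws(chronic$species_name))
    combined <- rbind(chronic, adj[!dup, , drop = FALSE])
  } else {
    combined <- adj
  }
  rownames(combined) <- NULL
  class(combined) <- c("sensitivity_set", "data.frame")

  fit <- select_ssd(fit_ssd_all(combined$value, families,
                                min_n = min_fit_size))
  pcs <- if (n_boot > 0) {
    bootstrap_ci(combined$value, fit$family, protection_levels,
                 n_boot = n_boot, seed = seed, min_n = min_fit_size)
  } else {
    data.frame(protection_pct = protection_levels,
               point = protective_concentration(fit, protection_levels),
               ci_lower = NA_real_, ci_upper = NA_real_, n_boot = 0L)
  }
  structure(
    list(name = name, acr_values = acr, combined_set = combined,
         fit = fit, pcs = pcs),
    class = "acr_scenario")
}

#' @export
print.acr_scenario <- function(x, ...) {
  cat("ACR scenario:", x$name, " (n =", nrow(x$combined_set),
      "species, family", x$fit$family, ")\n")
  print(x$pcs)
  invisible(x)
}

#' Compare ACR scenarios with the temporal response surface
#'
#' Tabulates protective concentrations for each scenario against the
#' surface's values at the requested exposure days, with the ratio
#' scenario PC / TRS PC.  This mirrors the usual grouped-bar comparison
#' of duration-aware versus ACR-converted guideline values.
#'
#' @param scenarios list of [apply_acr_scenario()] results.
#' @param surface a [build_trs()] result.
#' @param days exposure days to compare at (must lie in the surface).
#' @return long data frame: `scenario`, `day`, `protection_pct`,
#'   `scenario_pc`, `trs_pc`, `ratio`.
#' @export
compare_with_trs <- function(scenarios, surface, days = c(7, 14, 21, 28)) {
  stopifnot(inherits(surface, "trs_surface"))
  if (inherits(scenarios, "acr_scenario")) scenarios <- list(scenarios)
  outside <- setdiff(as.integer(days), surface$days)
  if (length(outside)) {
    stop("day(s) outside the surface: ", paste(outside, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (sc in scenarios) {
    for (d in as.integer(days)) {
      trs_pc <- vapply(sc$pcs$protection_pct, function(p)
        query_surface(surface, d, "pc", p), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        scenario = sc$name, day = d,
        protection_pct = sc$pcs$protection_pct,
        scenario_pc = sc$pcs$point,
        trs_pc = trs_pc,
        ratio = sc$pcs$point / trs_pc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a literature ACR table and geomean it by class
#'
#' Expected columns: `taxon_class`, `acr`, optional `acr_min`,
#' `acr_max`, `source_id`.  When several per-species ratios share a
#' class they are combined by geometric mean; the min and max across
#' the class are carried for sensitivity bands.
#'
#' @param path CSV path.
#' @return data frame: `taxon_class`, `acr` (geomean), `acr_min`,
#'   `acr_max`, `n`.
#' @export
read_acr_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon_class", "acr")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("ACR table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(raw$acr <= 0)) stop("ACR values must be positive", call. = FALSE)
  sp <- split(raw, raw$taxon_class)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(
      taxon_class = g$taxon_class[1],
      acr = exp(mean(log(g$acr))),
      acr_min = min(if ("acr_min" %in% names(g)) g$acr_min else g$acr),
      acr_max = max(if ("acr_max" %in% names(g)) g$acr_max else g$acr),
      n = nrow(g))
  }))
  rownames(out) <- NULL
  out
}
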