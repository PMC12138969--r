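#' Read a declarative run configuration
#'
#' A run configuration is a single YAML file with the keys:
#'
#' * `toxicity_csv` — acute record table (see [read_toxicity_table()]);
#' * `reference_series` — mapping reference class -> time-series CSV
#'   (see [read_reference_series()]);
#' * `class_map` — mapping data class -> reference class or `exclude`;
#' * `calibration` — mapping reference class ->
#'   `{ec_measured, measured_day}`;
#' * optional `acr_table_csv`, `acr_defaults` (e.g. `[10, 50, 100]`),
#'   `protection_levels`, `days` (`[first, last]`), `families`,
#'   `forced_family`, `n_boot_pc`, `n_boot_regression`, `seed`,
#'   `min_purity`, `min_quality`, `acute_divisor`, `medium`,
#'   `out_dir`.
#'
#' Paths are resolved relative to the YAML file's directory.
#'
#' @param path YAML file path.
#' @return a list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  }
  cfg$toxicity_csv <- resolve(cfg$toxicity_csv)
  cfg$acr_table_csv <- resolve(cfg$acr_table_csv)
  if (!is.null(cfg$reference_series)) {
    cfg$reference_series <- lapply(cfg$reference_series, resolve)
  }
  defaults <- list(protection_levels = c(99, 95, 90, 80),
                   days = c(1, 100), families = ssd_families(),
                   n_boot_pc = 0, n_boot_regression = 1000, seed = 1,
                   min_purity = 80, min_quality = 50, acute_divisor = 5,
                   out_dir = ".")
  cfg <- modifyList(defaults, cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration against its inputs
#'
#' Checks every cross-reference — files exist and parse, every class in
#' the data resolves through `class_map`, every mapped reference class
#' has a series and calibration, the day range is non-empty, a seed is
#' present whenever bootstrapping is requested — and returns all
#' failures, not just the first.
#'
#' @param config a [read_run_config()] result (or an equivalent list).
#' @return data frame with columns `check` and `message`; zero rows
#'   means the configuration is valid.
#' @export
validate_config <- function(config) {
  fails <- list()
  add <- function(check, msg) {
    fails[[length(fails) + 1]] <<- data.frame(check = check, message = msg)
  }
  records <- NULL
  if (is.null(config$toxicity_csv)) {
    add("toxicity_csv", "no toxicity table configured")
  } else if (!file.exists(config$toxicity_csv)) {
    add("toxicity_csv", paste("file not found:", config$toxicity_csv))
  } else {
    records <- tryCatch(read_toxicity_table(config$toxicity_csv),
                        error = function(e) {
                          add("toxicity_csv", conditionMessage(e))
                          NULL
                        })
  }
  series <- list()
  for (cl in names(config$reference_series)) {
    p <- config$reference_series[[cl]]
    if (!file.exists(p)) {
      add("reference_series", paste0(cl, ": file not found: ", p))
    } else {
      series[[cl]] <- tryCatch(read_reference_series(p),
                               error = function(e) {
                                 add("reference_series",
                                     paste0(cl, ": ", conditionMessage(e)))
                                 NULL
                               })
    }
  }
  cmap <- unlist(config$class_map)
  if (!is.null(records)) {
    unmapped <- setdiff(unique(records$taxon_class), names(cmap))
    for (cl in unmapped) add("class_map", paste("class in data but not in class_map:", cl))
  }
  refs <- setdiff(unique(cmap), "exclude")
  for (cl in refs) {
    if (!cl %in% names(config$reference_series)) {
      add("reference_series", paste("no reference series for class:", cl))
    }
    cal <- config$calibration[[cl]]
    if (is.null(cal$ec_measured) || is.null(cal$measured_day)) {
      add("calibration", paste("incomplete calibration for class:", cl))
    }
  }
  days <- config$days
  if (length(days) == 2 && days[2] < days[1]) add("days", "empty day range")
  if ((config$n_boot_pc > 0 || config$n_boot_regression > 0) &&
      is.null(config$seed)) {
    add("seed", "a seed is required when any bootstrap size is positive")
  }
  if (!length(fails)) {
    data.frame(check = character(0), message = character(0))
  } else {
    do.call(rbind, fails)
  }
}

#' Run the full pipeline from a configuration
#'
#' Executes read -> screen -> acute conversion -> species aggregation ->
#' time-response fits -> TAFs -> surface build -> exports, plus the ACR
#' comparison when `acr_defaults` or `acr_table_csv` is configured.
#' Every artifact is stamped with the configuration hash and seed;
#' identical configuration and seed produce identical outputs.
#'
#' Files written to `config$out_dir`: `records_normalized.csv`,
#' `screening_report.csv`, `model_<class>.json`, `trs_table.csv`,
#' `surface.json`, `acr_comparison.csv` (if configured) and `run_log.txt`.
#'
#' @param config a validated [read_run_config()] result.
#' @return (invisibly) a list with `records`, `screen`, `sens_set`,
#'   `models`, `surface`, `scenarios`, `comparison`, `paths`.
#' @export
run_pipeline <- function(config) {
  v <- validate_config(config)
  if (nrow(v)) {
    stop("configuration invalid:\n",
         paste(" -", v$check, ":", v$message, collapse = "\n"), call. = FALSE)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  records <- read_toxicity_table(config$toxicity_csv)
  if (!is.null(config$medium)) {
    records <- records[records$medium %in% config$medium, , drop = FALSE]
    note("medium filter '", paste(config$medium, collapse = ","),
         "': ", nrow(records), " records retained")
  }
  scr <- screen_records(records, config$min_purity, config$min_quality)
  for (i in which(!scr$report$kept)) {
    note("excluded record ", i, " (", scr$report$species[i], "): rule ",
         scr$report$rule[i])
  }
  kept <- scr$kept
  kept_raw <- kept          # original basis, for ACR scenarios
  is_acute <- kept$effect_type == "acute"
  kept$concentration[is_acute] <-
    acute_to_chronic_estimate(kept$concentration[is_acute],
                              config$acute_divisor)
  note("acute records divided by ", config$acute_divisor,
       " to estimate 10%-effect values: ", sum(is_acute), " records")
  sens_set <- aggregate_species(kept[is_acute, , drop = FALSE],
                                value_kind = "acute_estimated")

  models <- list()
  for (cl in names(config$reference_series)) {
    ser <- read_reference_series(config$reference_series[[cl]])
    models[[cl]] <- fit_time_response(
      ser, species_name = ser$species[1], taxon_class = cl)
    if (length(models[[cl]]$removed_points)) {
      note("class ", cl, ": removed influential point(s) ",
           paste(models[[cl]]$removed_points, collapse = ", "))
    }
    note("class ", cl, ": slope ", signif(models[[cl]]$slope, 4),
         ", D^2 ", signif(models[[cl]]$dsquared, 3),
         ", inflection day ", models[[cl]]$inflection_day)
    writeLines(time_response_report(models[[cl]]),
               file.path(out_dir, paste0("model_", cl, ".json")))
  }

  days <- if (length(config$days) == 2) {
    seq.int(config$days[1], config$days[2])
  } else as.integer(config$days)
  tcfg <- trs_config(
    class_map = unlist(config$class_map),
    calibration = config$calibration,
    protection_levels = config$protection_levels,
    days = days, families = config$families,
    forced_family = if (!is.null(config$forced_family))
      unlist(config$forced_family) else NULL,
    n_boot = config$n_boot_pc, seed = config$seed)
  surface <- build_trs(sens_set, models, tcfg)
  for (d in surface$days) {
    note("day ", d, ": selected family ", surface$family_by_day[[as.character(d)]])
  }

  paths <- list(
    records = file.path(out_dir, "records_normalized.csv"),
    screening = file.path(out_dir, "screening_report.csv"),
    trs_table = file.path(out_dir, "trs_table.csv"),
    surface = file.path(out_dir, "surface.json"),
    log = file.path(out_dir, "run_log.txt"))
  write_toxicity_table(records, paths$records)
  write.csv(scr$report, paths$screening, row.names = FALSE)
  export_trs_table(surface, paths$trs_table)
  writeLines(jsonlite::toJSON(list(
    seed = config$seed,
    config_hash = surface$provenance$config_hash,
    family_by_day = as.list(surface$family_by_day),
    protection_levels = config$protection_levels),
    auto_unbox = TRUE, digits = NA), paths$surface)

  scenarios <- list()
  comparison <- NULL
  if (!is.null(config$acr_defaults) || !is.null(config$acr_table_csv)) {
    for (a in config$acr_defaults) {
      scenarios[[length(scenarios) + 1]] <-
        apply_acr_scenario(NULL, sens_set_unconverted(kept_raw), a,
                           n_boot = 0, min_fit_size = tcfg$min_fit_size)
    }
    if (!is.null(config$acr_table_csv)) {
      tab <- read_acr_table(config$acr_table_csv)
      acr_map <- setNames(tab$acr, tab$taxon_class)
      have <- unique(kept$taxon_class[kept$effect_type == "acute"])
      if (all(have %in% names(acr_map))) {
        scenarios[[length(scenarios) + 1]] <-
          apply_acr_scenario(NULL, sens_set_unconverted(kept_raw), acr_map,
                             name = "ACR_lit", n_boot = 0,
                             min_fit_size = tcfg$min_fit_size)
      } else {
        note("literature ACR table lacks class(es): ",
             paste(setdiff(have, names(acr_map)), collapse = ", "),
             "; scenario skipped")
      }
    }
    comparison <- compare_with_trs(scenarios, surface,
                                   days = intersect(c(7, 14, 21, 28), days))
    paths$comparison <- file.path(out_dir, "acr_comparison.csv")
    write.csv(comparison, paths$comparison, row.names = FALSE)
  }

  note("seed ", config$seed, "; config hash ",
       surface$provenance$config_hash)
  writeLines(log_lines, paths$log)
  invisible(list(records = records, screen = scr, sens_set = sens_set,
                 models = models, surface = surface, scenarios = scenarios,
                 comparison = comparison, paths = paths))
}

# acute values on their original (undivided) basis for ACR scenarios
sens_set_unconverted <- function(kept_records) {
  acute <- kept_records[kept_records$effect_type == "acute", , drop = FALSE]
  aggregate_species(acute, value_kind = "acute_estimated")
}
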