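#' Write the bundled synthetic fixture suite
#'
#' Generates, with a pinned seed, the complete set of CSV inputs a
#' pipeline run needs — a 32-species acute toxicity table, one
#' reference time series per class, a per-class ACR table — plus a
#' matching `run.yaml` configuration.  All files are synthetic and
#' labelled as such; the same files ship under
#' `system.file("extdata", package = "trsurface")`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed pinning the generated values.
#' @param spec optional [community_spec()]; defaults to
#'   `community_spec(seed = seed)`.
#' @return (invisibly) named character vector of written paths.
#' @export
write_fixture_suite <- function(dir, seed = 20260101L, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(spec)) spec <- community_spec(seed = seed)
  bundle <- generate_synthetic_bundle(spec)

  paths <- c(toxicity = file.path(dir, "synthetic_toxicity.csv"))
  write_toxicity_table(bundle$community$records, paths[["toxicity"]])

  for (cl in names(bundle$reference_series)) {
    ser <- bundle$reference_series[[cl]]
    p <- file.path(dir, paste0("synthetic_reference_", tolower(cl), ".csv"))
    write.csv(data.frame(
      species = ser$species, class = ser$class,
      duration_days = .full_precision(ser$duration),
      endpoint = ser$endpoint,
      effect_concentration_ugL = .full_precision(ser$effect_concentration),
      source_id = ser$source_id), p, row.names = FALSE, quote = TRUE)
    paths[paste0("reference_", cl)] <- p
  }

  # synthetic per-class ACR table (ratios in the range reported for
  # arthropods: default 10 up to >100 for sensitive insects)
  acr <- data.frame(
    taxon_class = names(spec$class_mix),
    acr = c(22.6, 12, 10)[seq_along(spec$class_mix)],
    acr_min = c(5, 6, 8)[seq_along(spec$class_mix)],
    acr_max = c(150, 30, 15)[seq_along(spec$class_mix)],
    source_id = "synthetic")
  paths["acr_table"] <- file.path(dir, "synthetic_acr_table.csv")
  write.csv(acr, paths[["acr_table"]], row.names = FALSE, quote = TRUE)

  cfg <- list(
    toxicity_csv = basename(paths[["toxicity"]]),
    reference_series = setNames(
      as.list(basename(paths[paste0("reference_", names(bundle$reference_series))])),
      names(bundle$reference_series)),
    class_map = as.list(bundle$class_map),
    calibration = bundle$calibration,
    acr_table_csv = basename(paths[["acr_table"]]),
    acr_defaults = c(10, 50, 100),
    protection_levels = c(99, 95, 90, 80),
    days = c(1, 100),
    n_boot_pc = 0,
    n_boot_regression = 1000,
    seed = seed,
    out_dir = "trs_output")
  paths["config"] <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}
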