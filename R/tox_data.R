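#' Read a toxicity-record table
#'
#' Reads delimited bioassay records and normalizes them to the package's
#' canonical units (concentrations in ug/L, durations in days).  The
#' expected columns (renameable through `schema`) are: `species`,
#' `class`, `phylum`, `medium`, `endpoint`, `effect_type`,
#' `concentration`, `conc_unit`, `duration`, `duration_unit`,
#' `purity_pct`, `quality_pct`, `source_id`.  A template ships at
#' `system.file("extdata", "toxicity_template.csv", package = "trsurface")`.
#'
#' Units: `conc_unit` may be `ug/L` or `mg/L` (converted x1000);
#' `duration_unit` may be `days`/`d` or `hours`/`h` (converted /24).
#'
#' @param source path to a CSV file, or a connection.
#' @param schema optional named character vector mapping canonical
#'   column names to the names used in the file, e.g.
#'   `c(species = "taxon", concentration = "conc_ugL")`.
#' @return a data frame of class `toxicity_records`, one row per input
#'   row (order preserved), in canonical units.
#' @examples
#' tpl <- system.file("extdata", "toxicity_template.csv", package = "trsurface")
#' read_toxicity_table(tpl)
#' @export
read_toxicity_table <- function(source, schema = NULL) {
  raw <- read.csv(source, stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("species", "class", "phylum", "medium", "endpoint",
                 "effect_type", "concentration", "conc_unit", "duration",
                 "duration_unit", "purity_pct", "quality_pct", "source_id")
  colmap <- setNames(canonical, canonical)
  if (!is.null(schema)) colmap[names(schema)] <- schema
  missing_cols <- canonical[!colmap[canonical] %in% names(raw)]
  # conc_unit / duration_unit may be omitted; defaults assumed canonical
  optional <- c("conc_unit", "duration_unit", "phylum", "source_id")
  hard_missing <- setdiff(missing_cols, optional)
  if (length(hard_missing)) {
    stop("input table is missing mandatory column(s): ",
         paste(colmap[hard_missing], collapse = ", "), call. = FALSE)
  }

  get_col <- function(nm, default = NA) {
    if (colmap[[nm]] %in% names(raw)) raw[[colmap[[nm]]]] else rep(default, nrow(raw))
  }
  rec <- data.frame(
    species_name = trimws(as.character(get_col("species"))),
    taxon_class = trimws(as.character(get_col("class"))),
    phylum = trimws(as.character(get_col("phylum", ""))),
    medium = tolower(trimws(as.character(get_col("medium")))),
    endpoint = toupper(trimws(as.character(get_col("endpoint")))),
    effect_type = tolower(trimws(as.character(get_col("effect_type")))),
    concentration = as.numeric(get_col("concentration")),
    duration = as.numeric(get_col("duration")),
    purity_pct = as.numeric(get_col("purity_pct")),
    quality_pct = as.numeric(get_col("quality_pct")),
    source_id = as.character(get_col("source_id", "")),
    stringsAsFactors = FALSE)

  cu <- tolower(trimws(as.character(get_col("conc_unit", "ug/l"))))
  cu[cu %in% c("", NA)] <- "ug/l"
  du <- tolower(trimws(as.character(get_col("duration_unit", "days"))))
  du[du %in% c("", NA)] <- "days"
  bad_cu <- !cu %in% c("ug/l", "µg/l", "mg/l")
  if (any(bad_cu)) {
    stop("unknown concentration unit '", cu[which(bad_cu)[1]], "' in row ",
         which(bad_cu)[1], call. = FALSE)
  }
  bad_du <- !du %in% c("days", "day", "d", "hours", "hour", "h")
  if (any(bad_du)) {
    stop("unknown duration unit '", du[which(bad_du)[1]], "' in row ",
         which(bad_du)[1], call. = FALSE)
  }
  rec$concentration <- rec$concentration * ifelse(cu == "mg/l", 1000, 1)
  rec$duration <- rec$duration / ifelse(du %in% c("hours", "hour", "h"), 24, 1)

  validate_toxicity_records(rec)
  class(rec) <- c("toxicity_records", "data.frame")
  rec
}

#' Validate toxicity records
#'
#' Checks the row-level invariants of a record table: positive
#' concentrations and durations, known endpoint and medium labels, and
#' purity/quality percentages in range.  Errors cite the offending row.
#'
#' @param records a data frame of toxicity records (canonical units).
#' @return the records, invisibly, if valid.
#' @export
validate_toxicity_records <- function(records) {
  endpoints <- c("LC50", "EC50", "NOEC", "EC10", "LC10")
  check <- function(bad, what) {
    if (any(bad, na.rm = TRUE) || anyNA(bad)) {
      row <- which(bad | is.na(bad))[1]
      stop("invalid record in row ", row, ": ", what, call. = FALSE)
    }
  }
  check(!(records$concentration > 0), "concentration must be positive")
  check(!(records$duration > 0), "duration must be positive")
  check(!records$endpoint %in% endpoints,
        paste("endpoint must be one of", paste(endpoints, collapse = ", ")))
  check(!records$medium %in% c("freshwater", "marine"), "unknown medium")
  check(!(records$purity_pct > 0 & records$purity_pct <= 100),
        "purity_pct must lie in (0, 100]")
  check(!(records$quality_pct >= 0 & records$quality_pct <= 100),
        "quality_pct must lie in [0, 100]")
  invisible(records)
}

#' Write toxicity records back to CSV
#'
#' Inverse of [read_toxicity_table()]: values are written at full
#' precision in canonical units so that a read/write/read round trip
#' reproduces the records exactly.
#'
#' @param records a `toxicity_records` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_toxicity_table <- function(records, path) {
  out <- data.frame(
    species = records$species_name,
    class = records$taxon_class,
    phylum = records$phylum,
    medium = records$medium,
    endpoint = records$endpoint,
    effect_type = records$effect_type,
    concentration = .full_precision(records$concentration),
    conc_unit = "ug/L",
    duration = .full_precision(records$duration),
    duration_unit = "days",
    purity_pct = .full_precision(records$purity_pct),
    quality_pct = .full_precision(records$quality_pct),
    source_id = records$source_id,
    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

.full_precision <- function(x) formatC(x, digits = 17, format = "g")

#' Screen records on purity and quality
#'
#' Applies the guideline screening rules: the active-ingredient purity
#' must exceed `min_purity` percent (strict `>`, matching the ">80%
#' active ingredient" convention) and the study quality score must be
#' at least `min_quality` percent (`>=`, "acceptable" quality or
#' better).
#'
#' @param records a `toxicity_records` data frame.
#' @param min_purity purity threshold in percent (default 80; strict).
#' @param min_quality quality threshold in percent (default 50;
#'   inclusive).
#' @return a list with `kept` (the surviving records, class preserved)
#'   and `report` (a per-record disposition table: row, species, kept,
#'   rule fired or `"pass"`).
#' @export
screen_records <- function(records, min_purity = 80, min_quality = 50) {
  fail_purity <- !(records$purity_pct > min_purity)
  fail_quality <- !(records$quality_pct >= min_quality)
  rule <- ifelse(fail_purity & fail_quality, "purity+quality",
          ifelse(fail_purity, "purity",
          ifelse(fail_quality, "quality", "pass")))
  keep <- rule == "pass"
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- class(records)
  report <- data.frame(
    row = seq_len(nrow(records)),
    species = records$species_name,
    kept = keep,
    rule = rule,
    stringsAsFactors = FALSE)
  list(kept = kept, report = report)
}

#' Convert an acute median-effect value to a chronic 10%-effect estimate
#'
#' Acute LC50/EC50 values are converted to estimated LC10/EC10 values by
#' dividing by a fixed assessment factor (guideline default 5).
#'
#' @param value positive effect concentration(s) in ug/L.
#' @param divisor positive conversion factor (default 5).
#' @return `value / divisor`.
#' @examples
#' acute_to_chronic_estimate(705) # 141
#' @export
acute_to_chronic_estimate <- function(value, divisor = 5) {
  if (!is.numeric(divisor) || length(divisor) != 1 || divisor <= 0) {
    stop("divisor must be a single positive number", call. = FALSE)
  }
  if (any(value <= 0)) stop("value must be positive", call. = FALSE)
  value / divisor
}

#' Aggregate records into one sensitivity value per species
#'
#' Where multiple records exist for a species their concentrations are
#' combined by geometric mean (equivalently, the arithmetic mean of the
#' natural logs).  Species identity is the record's name after
#' whitespace trimming and case-folding; no synonym resolution is
#' attempted.  A species whose records disagree on taxonomic class
#' raises a data-integrity error.
#'
#' @param records a `toxicity_records` data frame.
#' @param value_kind provenance label attached to every entry
#'   (`"acute_estimated"` or `"chronic_observed"`).
#' @return a data frame of class `sensitivity_set` with columns
#'   `species_name`, `value` (ug/L), `taxon_class`, `medium`,
#'   `n_source_records`, `value_kind`.
#' @examples
#' # two records for one species with values 10 and 1000 -> geomean 100
#' @export
aggregate_species <- function(records,
                              value_kind = c("acute_estimated", "chronic_observed")) {
  value_kind <- match.arg(value_kind)
  if (!nrow(records)) stop("no records to aggregate", call. = FALSE)
  key <- tolower(trimws(records$species_name))
  split_idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(split_idx, function(ix) {
    cls <- unique(records$taxon_class[ix])
    if (length(cls) > 1) {
      stop("inconsistent taxon_class for species '",
           records$species_name[ix[1]], "': ",
           paste(cls, collapse = " vs "), call. = FALSE)
    }
    data.frame(
      species_name = records$species_name[ix[1]],
      value = exp(mean(log(records$concentration[ix]))),
      taxon_class = cls,
      medium = records$medium[ix[1]],
      n_source_records = length(ix),
      value_kind = value_kind,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_set", "data.frame")
  out
}
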