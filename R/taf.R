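#' Compute a temporal adjustment factor table for one taxonomic class
#'
#' Temporal adjustment factors (TAFs) are the day-indexed analogue of
#' acute-to-chronic ratios.  For each day `x`, the reference model's
#' predicted effect concentration is divided by the measured
#' (observed) effect concentration of the reference species:
#' `TAF_x = EC_modelled(x) / ec_measured`.  Multiplying a species'
#' acute value by `TAF_x` rescales it to an exposure of `x` days;
#' for a negative slope the factors decline with day, so adjusted
#' toxicity values decline with exposure duration.
#'
#' When `ec_measured` equals the model's own prediction at
#' `measured_day`, the factor at that day is exactly 1 and
#' `TAF_x = (x / measured_day) ^ slope`.
#'
#' @param model a fitted [time_response_model()] for the class's
#'   reference species.
#' @param ec_measured the reference species' measured acute effect
#'   concentration (ug/L), supplied explicitly in configuration.
#' @param measured_day the exposure duration (days) of that
#'   measurement.
#' @param days days to tabulate (default 1:100).
#' @return an object of class `taf_table`: list with
#'   `reference_species`, `taxon_class`, `slope`, `ec_measured`,
#'   `measured_day` and `factors` (named numeric vector, one per day).
#' @examples
#' m <- time_response_model(log(100), -1)
#' taf <- compute_taf_table(m, ec_measured = 100, measured_day = 1)
#' taf$factors[["10"]] # 0.1
#' @export
compute_taf_table <- function(model, ec_measured, measured_day, days = 1:100) {
  if (is.null(model) || !inherits(model, "time_response_model")) {
    stop("a fitted time_response_model is required", call. = FALSE)
  }
  if (!is.numeric(ec_measured) || ec_measured <= 0) {
    stop("ec_measured must be a positive concentration", call. = FALSE)
  }
  if (!is.numeric(measured_day) || measured_day <= 0) {
    stop("measured_day must be positive", call. = FALSE)
  }
  days <- as.integer(days)
  pred <- exp(model$intercept + model$slope * log(days))
  structure(
    list(reference_species = model$species_name,
         taxon_class = model$taxon_class,
         slope = model$slope,
         ec_measured = ec_measured,
         measured_day = measured_day,
         factors = setNames(pred / ec_measured, days)),
    class = "taf_table")
}

#' Apply class-wise temporal adjustment to a sensitivity set
#'
#' Rescales each species' acute sensitivity value to exposure day
#' `day`: `adjusted = value * TAF_day(class)`, with the TAF table
#' chosen by mapping the species' taxonomic class through `class_map`.
#' Every class present in the data must be mapped either to the name of
#' a reference class with a TAF table or to the literal `"exclude"`;
#' unmapped classes raise an error listing the affected species rather
#' than being dropped silently.
#'
#' @param sens_set a `sensitivity_set` (see [aggregate_species()]).
#' @param tafs named list of [compute_taf_table()] results, keyed by
#'   reference class name.
#' @param class_map named character vector mapping each data class to a
#'   reference class or `"exclude"`.  A class mapped to itself uses its
#'   own table.
#' @param day integer exposure day to adjust to.
#' @return a data frame of class `adjusted_dataset` with columns
#'   `species_name`, `taxon_class`, `value` (ug/L) and attribute
#'   `day`; excluded species are absent.
#' @export
adjust_toxicity <- function(sens_set, tafs, class_map, day) {
  day <- as.integer(day)
  classes <- unique(sens_set$taxon_class)
  unmapped <- setdiff(classes, names(class_map))
  if (length(unmapped)) {
    sp <- sens_set$species_name[sens_set$taxon_class %in% unmapped]
    stop("no class mapping for class(es) ", paste(unmapped, collapse = ", "),
         "; affected species: ", paste(sp, collapse = ", "),
         ". Map each class to a reference class or to 'exclude'.",
         call. = FALSE)
  }
  target <- class_map[sens_set$taxon_class]
  keep <- target != "exclude"
  out <- sens_set[keep, c("species_name", "taxon_class", "value")]
  target <- target[keep]
  missing_taf <- setdiff(unique(target), names(tafs))
  if (length(missing_taf)) {
    stop("no TAF table for reference class(es): ",
         paste(missing_taf, collapse = ", "), call. = FALSE)
  }
  fac <- vapply(target, function(cl) {
    f <- tafs[[cl]]$factors
    key <- as.character(day)
    if (!key %in% names(f)) {
      stop("day ", day, " is outside the TAF table for class ", cl,
           call. = FALSE)
    }
    f[[key]]
  }, numeric(1))
  out$value <- out$value * unname(fac)
  rownames(out) <- NULL
  class(out) <- c("adjusted_dataset", "data.frame")
  attr(out, "day") <- day
  out
}
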