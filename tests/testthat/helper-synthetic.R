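# shared helpers: independent oracles and small generated fixtures

# normal-equations least squares on (ln duration, ln EC) -- independent
# of the glm path used by fit_time_response()
ls_oracle <- function(duration, ec) {
  x <- log(duration)
  y <- log(ec)
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  c(intercept = beta[1], slope = beta[2])
}

# brute-force scan oracle for the inflection rule
inflection_oracle <- function(slope, threshold = 0.05, horizon = 365) {
  for (d in seq_len(horizon)) {
    if (1 - ((d + 1) / d)^slope < threshold) return(d)
  }
  horizon
}

# a small screening-compliant record table built in code
make_records <- function(species, class, conc, duration = 2,
                         purity = 99, quality = 90, medium = "freshwater",
                         endpoint = "LC50", effect_type = "acute") {
  n <- length(species)
  rec <- data.frame(
    species_name = species, taxon_class = class, phylum = "Arthropoda",
    medium = rep_len(medium, n), endpoint = rep_len(endpoint, n),
    effect_type = rep_len(effect_type, n),
    concentration = conc, duration = rep_len(duration, n),
    purity_pct = rep_len(purity, n), quality_pct = rep_len(quality, n),
    source_id = "test", stringsAsFactors = FALSE)
  class(rec) <- c("toxicity_records", "data.frame")
  rec
}

# zero-noise single-class bundle for closed-form end-to-end checks
single_class_bundle <- function(n_species = 32, mu = log(50), sigma = 1.1,
                                beta = -1.5, d0 = 2, seed = 11) {
  spec <- community_spec(
    n_species = n_species, class_mix = c(Insecta = 1),
    ssd_location = mu, ssd_scale = sigma,
    class_slopes = c(Insecta = beta), noise_sd_log = 0,
    acute_duration = c(Insecta = d0), seed = seed)
  generate_synthetic_bundle(spec)
}
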