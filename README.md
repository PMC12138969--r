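# trsurface

Exposure-duration-aware species sensitivity distributions for toxicants
with time-cumulative toxicity.

## The problem

Water-quality guidelines derived from species sensitivity distributions
(SSDs) protect a chosen fraction of species — a PC95 is the
concentration at the 5th percentile of the fitted distribution of
per-species sensitivities. The standard derivation converts acute
bioassay endpoints (48–96 h LC50/EC50) to chronic estimates with a
fixed acute-to-chronic ratio (ACR) and then ignores exposure duration
entirely. For chemicals whose toxicity accumulates with time —
neonicotinoid insecticides are the canonical case, binding nicotinic
acetylcholine receptors essentially irreversibly — the effect
concentration keeps falling the longer organisms are exposed, and a
single ACR under-protects long exposures.

`trsurface` implements the temporal response surface (TRS) method:

1. fit a log–log time-response regression
   `ln EC = α + β ln(duration) + ε` to time-series bioassay data for a
   reference species of each taxonomic class;
2. convert each fitted curve into daily **temporal adjustment factors**
   `TAF(d) = EC_modelled(d) / EC_measured` (equal to `(d/d₀)^β` when
   calibrated on the fitted curve at the acute test duration `d₀`);
3. rescale every species' acute sensitivity value class-wise,
   `EC_adj(d) = EC × TAF(d)`, for each day d = 1…100;
4. fit the five standard SSD candidate families (log-normal,
   log-logistic, log-Gumbel/inverse-Weibull, gamma, Weibull) to each
   daily data set by maximum likelihood, select by AICc, and read off
   protective concentrations (PC99/PC95/PC90/PC80) with
   parametric-bootstrap confidence intervals.

The stacked daily SSDs form a surface over concentration × affected
fraction × exposure day, so the same object answers guideline questions
("what PC95 applies to a 28-day exposure?") and probabilistic ones
("what fraction of species is potentially affected by 0.2 µg/L
sustained for 100 days?").

It also ships the conventional ACR-scenario machinery (defaults 10, 50,
100 and literature-derived per-class tables) for side-by-side
comparison, guideline-style data screening (purity > 80%, quality ≥
50%, acute-to-EC10 conversion by /5, per-species geometric means), and
synthetic data generators with known ground truth.

## Worked example

Everything below runs from a synthetic 32-species arthropod community
with known ground truth (class mix Insecta/Malacostraca/Branchiopoda =
16/10/6, sensitivities spanning ~4 orders of magnitude, class slopes
−1.827 / −0.737 / −3.892):

```r
library(trsurface)

spec   <- community_spec(seed = 1)
bundle <- generate_synthetic_bundle(spec)

# per-species acute values, converted to chronic (EC10) estimates
sens <- aggregate_species(bundle$community$records)
sens$value <- acute_to_chronic_estimate(sens$value)   # /5

# one time-response regression per class
models <- lapply(names(bundle$reference_series), function(cl)
  fit_time_response(bundle$reference_series[[cl]], taxon_class = cl))
names(models) <- names(bundle$reference_series)
models$Insecta
#> Time-response model: reference (Insecta)
#>   ln(EC) = 5.95 -1.799 * ln(day)
#>   D^2 = 0.9964  LOOCV-MSE = 0.02617  n = 7  inflection day = 35

# calibration on the same /5 basis, then the surface
calib <- lapply(bundle$calibration, function(cal) {
  cal$ec_measured <- cal$ec_measured / 5; cal
})
surface <- build_trs(sens, models,
                     trs_config(bundle$class_map, calib, days = 1:100, seed = 1))
surface
#> Temporal response surface: 100 day slices,  32 species
#>   selected families: log_logistic (1 days), weibull (4 days), gamma (95 days)
#>   protection levels: 99, 95, 90, 80

query_surface(surface, 28, "pc", 95)    # 0.00212 ug/L
query_surface(surface, 100, "paf", 0.2) # 29 (% of species affected)
first_day_below(surface, 95, 1)         # day 6: PC95 crosses 1 ug/L
export_trs_table(surface, "trs_table.csv")
```

The regression recovered the generating Insecta slope (−1.799 vs the
true −1.8 under noise), the PC95 for a 28-day exposure is three orders
of magnitude below the day-1 value — the signature of time-cumulative
toxicity — and a sustained 0.2 µg/L exposure, harmless by a
duration-blind SSD, is predicted to affect ~29% of this community after
100 days.

File-based runs are driven by a single YAML configuration (see
`system.file("extdata", "run.yaml", package = "trsurface")`) through
`read_run_config()` / `validate_config()` / `run_pipeline()`, or from a
shell via the thin CLI in `exec/trs`
(`trs build-trs --config run.yaml`, `trs query --config run.yaml
--day 28 --pc 95`, `trs make-fixtures --out dir`).

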