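---
title: "Temporal response surfaces: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal response surfaces: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(trsurface)
```

## The problem

Species sensitivity distributions (SSDs) summarise how the species of an
ecological community vary in their sensitivity to a toxicant: a
distribution is fitted to one effect concentration per species, and the
concentration at its lower tail — the protective concentration PCx, the
(100 − x)th percentile — becomes a guideline value protecting x% of
species. The standard derivation is duration-blind: an acute 2- or
4-day endpoint is converted to a chronic estimate with a fixed
acute-to-chronic ratio (ACR), regardless of how long organisms are
actually exposed.

For toxicants with *time-cumulative* toxicity this is a poor
approximation. Neonicotinoid insecticides bind nicotinic acetylcholine
receptors effectively irreversibly, so the aqueous concentration needed
to produce a given effect keeps falling as exposure continues; a single
ACR cannot represent a continuum of exposure durations. `trsurface`
implements a duration-aware alternative: the temporal response surface
(TRS).

## The model

**Time-response regression.** For a reference species with time-series
bioassay data (an effect concentration EC, e.g. an LC50, observed at
several exposure durations ED in days), toxicity is modelled as a power
law, fitted as a Gaussian identity-link GLM on natural logs:

$$\ln EC = \alpha + \beta \,\ln ED + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2).$$

`fit_time_response()` estimates $(\alpha, \beta)$ — this is ordinary
least squares on the log pairs — and reports the explained deviance
$D^2$ (identical to $R^2$ here), the leave-one-out cross-validated MSE
on the log scale (computed from the hat matrix), and coefficient
standard errors. $\beta < 0$ for a time-cumulative toxicant; a
non-negative slope warns rather than errors, since the data decide.

The regression includes an intercept. A pure proportional-hazards
reading of the power law would force the line through the origin of the
log-log plane, but the intercept is exactly the log effect
concentration at day 1 and is always reported by time-response studies;
omitting it would make the model useless for calibration.

**Temporal adjustment factors.** The fitted curve is turned into a
day-indexed ratio, the temporal adjustment factor,

$$TAF_x \;=\; \frac{\widehat{EC}(x)}{EC_{\text{measured}}},$$

where $EC_{\text{measured}}$ is the reference species' observed acute
effect concentration at its standard test duration $d_0$, supplied
explicitly in configuration (never inferred from the data). When the
calibration datum sits on the fitted curve, $TAF_x = (x/d_0)^\beta$,
equal to 1 at $d_0$ and declining with day for $\beta < 0$. The two
possible orientations of the ratio are algebraically equivalent up to
inversion; we adopt the multiplicative form

$$EC_x^{\text{adj}} \;=\; EC_y \times TAF_x$$

because adjusted toxicity values must *decline* with exposure duration
— the defining phenomenon. Dividing by the inverse ratio
$EC_{\text{measured}}/\widehat{EC}(x)$, an ACR-like quantity, gives the
same numbers.

**The surface.** Each species in the acute data set is adjusted with
the TAF of its taxonomic class (the assumption: species within a class
share the reference species' slope, justified by phylogenetic
similarity of toxic response). Doing this once per day for days 1–100
yields 100 adjusted data sets; each gets an SSD, and the stack of daily
SSDs is the TRS. `query_surface()` then answers both guideline
questions (PCx at a given day) and probabilistic ones (the potentially
affected fraction, PAF — the fitted CDF — at a given concentration and
day).

## SSD fitting and selection

Five candidate families are fitted by maximum likelihood
(`fit_ssd()`): log-normal, log-logistic, log-Gumbel and the raw-scale
gamma and Weibull. Parameterizations:

* `log_normal`: `meanlog`/`sdlog`; the MLE is closed form (mean of the
  logs, and their root-mean-square deviation — the 1/n variant).
* `log_logistic`, `log_gumbel`: location/scale of a logistic resp.
  Gumbel (type-I extreme value, maximum convention) distribution on
  ln(concentration). Log-Gumbel on the raw scale is the inverse
  Weibull (Fréchet) distribution.
* `gamma` (`shape`/`rate`) and `weibull` (`shape`/`scale`) act on raw
  concentrations and are fitted with `fitdistrplus::fitdist()`, with
  deterministic moment-based starts supplied by the package (Minka's
  closed-form approximation for gamma; extreme-value moments of the
  log data for Weibull), because default starts can diverge on data
  spanning four orders of magnitude. If the finite-difference step
  inside `fitdist` still fails, a log-parameterized direct optimization
  from the same start takes over.

Numerical choices worth knowing:

* **Scale equivariance by construction.** Data are internally centred
  on the log scale (equivalently rescaled by their geometric mean)
  before optimization, so multiplying every concentration by k scales
  every fitted quantile by exactly k — units cannot leak into the fit.
* **Selection.** The reported goodness-of-fit assessment behind most
  SSD tools mixes visual checks with statistics; we adopt the minimum
  AICc as the selection rule (two-parameter families, so AICc ordering
  equals AIC ordering, but AICc is the SSD-tooling convention), with
  Anderson–Darling and Kolmogorov–Smirnov statistics reported for
  transparency and a `forced_family` configuration override for when a
  particular family must be imposed on some or all days.
  Ties break by a fixed family order (log_normal, log_logistic,
  log_gumbel, gamma, weibull) so selection is deterministic.
* **Degenerate input.** All-equal samples are rejected with a
  degenerate-sample error before any optimizer runs; fewer than
  `min_n = 8` species (the conventional SSD floor) is an error too.

## Bootstrap intervals

`bootstrap_ci()` implements the parametric percentile bootstrap:
replicate samples of size n are drawn from the fitted distribution,
refitted, and the 2.5/97.5 percentiles of each replicate PC form the
interval. The point estimate comes from the original-data fit — the
deterministic convention of standard SSD practice — with
`pc_point = "bootstrap_median"` available where the replicate median is
wanted instead. One seed governs a run; per-replicate sub-seeds are
drawn up front (counter-style splitting), so results do not depend on
execution order. More than 20% replicate refit failure aborts with a
bootstrap-instability error rather than returning quietly biased
intervals.

A caveat the validation suite quantifies: for a lower tail quantile
(PC95) at n = 32 the percentile interval is known to undercover
slightly — our simulations put its true coverage near 91–92% at
nominal 95%. That is a property of the percentile method at this
sample size, shared by the standard tooling, not an implementation
artefact; treat the intervals as approximate.

Regression prediction intervals (`predict_ec()`) instead draw
coefficient pairs from the estimated bivariate normal sampling
distribution of $(\alpha, \beta)$ (1000 draws by default); residual
resampling is available as an option, useful when the Gaussian
approximation at n ≈ 5–8 points is in doubt.

## The exposure window and the inflection day

Extrapolating a regression fitted on ≤ 28-day bioassays to a year is
not defensible; the surface is therefore capped where the modelled
daily change becomes negligible. `inflection_day()` implements a
relative-change rule: the first whole day $d$ at which the decline
from day $d$ to $d+1$,

$$1 - \left(\tfrac{d+1}{d}\right)^{\beta} \;\approx\; \tfrac{|\beta|}{d},$$

falls below a threshold (default 0.05, i.e. less than 5% change per
day). The rule is deliberately pluggable — published inflection-day
tables for reference species are not always reproducible from any
single rule, and analysts may prefer a criterion tied to the bootstrap
bands — but `relative_change` is the documented default, and the
100-day default surface span reflects where the slowest-declining
reference models flatten out. Predictions beyond the inflection day or
beyond 100 days carry an explicit warning flag.

## Data screening conventions

Following the Australian/New Zealand guideline conventions the package
screens on active-ingredient purity (strictly > 80%) and study quality
score (≥ 50%, the "acceptable" floor), both exposed as parameters;
acute LC50/EC50 values are converted to estimated LC10/EC10 by
dividing by 5 before temporal adjustment, so the adjusted values are
chronic 10%-effect estimates; multiple records per species are
combined by geometric mean. Because the geometric mean commutes with a
constant divisor, it is immaterial whether the /5 conversion happens
before or after geomeaning — the pipeline applies it before
aggregation. Species identity is the trimmed, case-folded name string;
synonym resolution is out of scope.

## ACR comparison scenarios

`apply_acr_scenario()` reproduces the conventional alternative for
benchmarking: acute values divided by a default ACR (10, 50, 100) or a
per-class table of literature-derived ratios (geomeaned within class
by `read_acr_table()`, with class min/max kept for sensitivity bands),
combined with observed chronic values (chronic data pass through
untouched and take precedence), then fitted like any other SSD.
`compare_with_trs()` tabulates scenario PCs against surface PCs at
chosen days with their ratios. Because a scalar ACR is a pure rescaling,
every PC of an acute-only scenario scales by exactly 1/ACR — a property
the test suite checks through the whole fitting path.

## What the synthetic generator emulates — and what it does not

`generate_community()` draws a 32-species arthropod community
(Insecta : Malacostraca : Branchiopoda = 0.5 : 0.3 : 0.2 by default,
allocated by largest-remainder rounding) from a log-normal SSD with
location log(400 µg/L) and log-scale 2.3 — a geometric centre of
hundreds of µg/L with roughly four orders of magnitude between
sensitive mayfly-like and tolerant daphnid-like species, the regime
typical of neonicotinoid acute data. Class slopes default to −1.827,
−0.737 and −3.892, spanning the published range for mayfly, amphipod
and daphnid time-response regressions. Reference series use 4–8
durations between 1 and 28 days with multiplicative log-normal noise
(sd 0.15). Records are emitted at the standard acute windows (48 h for
daphnids, 96 h otherwise) with screening-compliant purity and quality.

These choices were fixed once, from the descriptive regime above, and
are the study conditions of the validation suite. What passing tests on
this generator demonstrate: correct arithmetic and statistics under a
known ground truth (a log-normal community rescaled by a power law
stays log-normal with a shifted location, so the whole pipeline has a
closed-form oracle). What they do not demonstrate: robustness to real
data's censoring, mixed endpoints, taxonomic misassignment, or
deviations from the shared-slope-within-class assumption — real
communities are under no obligation to be log-normal.

## Validation problem sizes

The shipped suite fits 1000 fuzzed regressions against a
normal-equations oracle (tolerance 1e-10); checks the PC/PAF round
trip at 1e-9 across all five families under fuzzed parameters; runs
200 replicate simulations at $\alpha = 5, \beta = -1.8$, noise 0.15,
8 durations for slope bias (< 0.02) and 95% CI coverage (93–97%);
measures bootstrap PC95 coverage over 300 repetitions at n = 32 with
500 replicates each; verifies the zero-noise single-class surface
against its closed form at 1e-6 over all 100 days; and asserts
monotonicity, equivariance and byte-identical reproducibility of
exports. `scripts/acceptance.R` re-runs the pipeline end to end on the
default synthetic conditions and writes every headline quantity it
computes as JSON.

## Known limitations

* One TAF per class per day, applied regardless of each species' own
  test duration (the literal class-wise reading). Rescaling by each
  species' own acute duration, `(d / d_species)^β`, would be a natural
  extension under the shared-slope assumption but is not implemented.
* No censored data, no model averaging, no Bayesian SSDs.
* The percentile bootstrap undercovers tail-quantile CIs at small n
  (above).
* Mixture toxicity and multi-stressor TAFs (multiple regression on
  e.g. temperature or pH) are out of scope.
* Classes without a reference model must be mapped or excluded
  explicitly in configuration; the package never guesses.
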