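Package: trsurface
Title: Temporal Response Surfaces for Time-Cumulative Aquatic Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds exposure-duration-aware species sensitivity
    distributions (SSDs) for toxicants with time-cumulative toxicity such
    as neonicotinoid insecticides.  Taxa-specific log-log regressions of
    effect concentration on exposure duration are converted into daily
    temporal adjustment factors (TAFs) that rescale acute toxicity data to
    any exposure duration from 1 to 100 days.  Fitting the five standard
    SSD candidate distributions to each daily adjusted data set yields a
    temporal response surface (TRS): protective concentrations (PC99,
    PC95, PC90, PC80) and potentially affected fractions as functions of
    both concentration and exposure duration, with parametric-bootstrap
    confidence intervals.  Includes acute-to-chronic-ratio (ACR) scenario
    comparisons, data screening utilities following the Australian and
    New Zealand water quality guideline conventions, and synthetic data
    generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    fitdistrplus,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
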