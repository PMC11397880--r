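# tirsurvey

Design and analysis of thermal-infrared (TIR) drone surveys of arboreal
primates.

Drone-mounted thermal cameras are an increasingly standard way to count
canopy-dwelling mammals such as spider monkeys, whose warm bodies stand out
against cooler forest at dawn and dusk. Before such surveys can be
standardised, two questions must be answered: do the flight parameters
(speed, height above ground, camera angle) change how many animals a coder
detects in the footage, and do independent human coders agree on the
counts? `tirsurvey` implements the computational machinery for both
questions, for survey designers and analysts working with transect flights
over known sleeping sites:

* **Ground-projection geometry** — oblique-camera footprints, ground
  sample distance (GSD), area-equalisation masking between camera angles
  and flight heights, and pixel-size detection limits
  (`ground_footprint()`, `mask_spec_for_angle()`,
  `max_detection_distance()`, ...).
* **Design expansion and footage handling** — factorial flight designs
  expanded into blinded video records, with faster flight speeds simulated
  by frame subsampling (`expand_design()`, `simulate_speed()`).
* **Count inference** — the Poisson random-intercept model
  `y_ij | b_i ~ Poisson(exp(x_ij' beta + b_i))`, `b_i ~ N(0, sigma^2)`,
  fitted by maximising the exact marginal likelihood with adaptive
  Gauss-Hermite quadrature, with likelihood-ratio tests against the
  random-intercept-only null, a Cramér's V collinearity screen, a
  whole-flight zero filter, and a Pearson dispersion check
  (`fit_poisson_glmm()`, `likelihood_ratio_test()`, ...).
* **Inter-coder agreement** — Fleiss' kappa over count categories,
  Landis-Koch verbal bands, and agreement summaries stratified by
  flight-parameter combination and thermal-contrast zone
  (`fleiss_kappa()`, `agreement_summary()`).
* **A synthetic survey generator** realising exactly the structure the
  analysis assumes (`sim_config()`, `generate_counts()`,
  `generate_coder_ratings()`), so the whole pipeline is testable without
  field data.

The methods vignette (`vignettes/tir-survey-methods.Rmd`) documents the
models, parameter defaults, numerical choices and limitations.

## Worked example

```r
library(tirsurvey)

# a survey: 5 sleeping sites x 8 flights, each flight cut into 12 videos
# (2 heights x 2 camera angles x 3 speeds), counts with a flight random
# intercept, three coders whose reliability depends on thermal contrast
cfg <- sim_config(seed = 1)
sim <- generate_counts(cfg)
nrow(sim$counts)                     # 480 videos, 12 per flight
reduced <- reduced_dataset_filter(sim$counts)

full <- fit_poisson_glmm(reduced)
null <- fit_poisson_glmm(reduced, predictors = character(0))
print(full)
#> Poisson random-intercept model (adaptive Gauss-Hermite, 25 nodes)
#>   480 observations in 40 groups; logLik = -918.1867; sigma = 0.4304
#>              Estimate Std. Error
#> (Intercept)    0.9485     0.0918
#> speed_m_s4    -0.0857     0.0663
#> speed_m_s6    -0.0170     0.0652
#> height_m50     0.0900     0.0539
#> angle_deg-90   0.0116     0.0539
likelihood_ratio_test(full, null)
#> Likelihood ratio test: chi-squared = 4.698, df = 4, p = 0.3197
```

The intercept is the log expected count at the reference setting (2 m/s,
40 m, -45 degrees); `sigma` is the between-flight SD on the log scale, and
the likelihood-ratio test compares the full model with the
random-intercept-only null — here, as in the generating model, there is no
evidence that speed, height or angle affect the counts (effects were
simulated as zero).

```r
ratings <- generate_coder_ratings(sim$counts, cfg)
agr <- agreement_summary(ratings, sim$counts)
head(agr$cells, 2)
#>   speed_m_s height_m angle_deg zone n_subjects     kappa        band
#> 1         2       40       -90 high         27 0.6434336 substantial
#> 2         2       40       -90  low         13 0.3589965        fair
```

Agreement among the three simulated coders is substantial in
high-thermal-contrast (forest-only) zones and drops to fair/slight in
low-contrast zones near heat-retaining structures, reflecting the
generator's contrast-dependent miss and false-positive rates.

The survey-planning side in one line: a 0.5 m animal must span 10 pixels,
so with the study camera the maximum camera-to-animal distance is
`max_detection_distance(0.5, 10, camera_model(640, 512, 9))` = 37.5 m;
an externally derived 57 m limit corresponds to
`max_flight_height_agl(57, canopy_height_m = 25)` = 82 m a.g.l.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full study
pipeline over the package functions and write tables under `results/`:

1. `01_geometry.R` — camera footprints, masks, detection limits
2. `02_design.R` — design expansion, blind codes, frame subsampling
3. `03_simulate.R` — synthetic counts and coder ratings
4. `04_fit.R` — collinearity screen, filter, mixed models and LRTs
5. `05_agreement.R` — kappa by combination and contrast zone

`run_pipeline()` executes the same stages programmatically from a YAML
config and writes a run manifest; `read_count_table()` /
`read_coder_table()` ingest external CSVs (with a column-mapping option)
in place of the simulation stage.

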