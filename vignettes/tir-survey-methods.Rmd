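---
title: "Models and methods for thermal-infrared drone survey analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for thermal-infrared drone survey analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirsurvey)
```

`tirsurvey` analyses standardised thermal-infrared (TIR) drone surveys of
arboreal primates: transect flights over known sleeping sites, flown at a
small set of heights, camera angles and speeds, with animal counts coded
from the footage by one or more human coders. The package covers four
stages — ground-projection geometry, design expansion and footage handling,
count modelling, and inter-coder agreement — plus a synthetic-data
generator that realises the statistical structure the analysis assumes, so
every stage is testable without field data.

## Ground-projection geometry

All geometry derives from a pinhole camera with sensor size (pixels times
pixel pitch) and focal length. The angular fields of view are
$2\arctan(n_{px}\, p / 2f)$; for the study camera (640 x 512 px, 9 mm
focal length, 12 µm pitch) this gives roughly 46 x 38 degrees. The camera
tilt is stored as degrees *from nadir* (0 is the gimbal's -90 setting, 45
is the gimbal's -45 setting), which removes sign ambiguity from the
trigonometry; `tilt_from_gimbal()` converts the signed notation.

For a line of sight at angle $\chi$ from the vertical, the ground distance
subtended scales as $1/\cos\chi$ relative to nadir
(`projected_distance_ratio()`). With height $H$ above the detection
surface (the canopy top, not the ground — animals sit on the canopy), the
near, middle and far edges of the footprint lie at
$H\tan(\phi - \theta_v/2)$, $H\tan\phi$ and $H\tan(\phi + \theta_v/2)$
from the sub-drone point, with widths $2\,(H/\cos\cdot)\tan(\theta_h/2)$
(`ground_footprint()`). The ground sample distance is linear in range,
$\mathrm{GSD} = d\,p/f$, and inverting the rule "an animal must span at
least $k$ pixels" gives the maximum detection distance
$d_{max} = \ell f / (k p)$ (`max_detection_distance()`), which
`max_flight_height_agl()` converts to a flight ceiling for a canopy-top
subject.

### Area-equalisation masks

Oblique and high-altitude footage cover more ground than nadir and
low-altitude footage. To compare counts across settings, the larger
footage is masked back to the common area. Two rules are implemented and
flagged in the output:

* the **survey dialect** used in field practice: a width excess of $e$% at
  a frame edge is masked at $e/2$% per side, and an area excess of $e$% at
  $e/4$% on each of the four sides. For the study's printed excesses
  (10% at the bottom and 56% at the top of the oblique frame; 55.2%
  between 50 m and 40 m images) this yields 5%/28% horizontal masks and a
  13.8% four-sided mask;
* an **exact-area** variant, $(1 - 1/(1+e))/2$ per side for widths and
  $(1 - 1/\sqrt{1+e})/2$ for areas, which restores parity exactly (the
  dialect rule over-masks slightly; its simplicity is why it is the field
  default, and it is the package default when reproducing the survey).

The printed excesses themselves are *inputs*, not quantities the package
derives: they are not exactly recoverable from the printed camera specs
(pure height scaling gives $(50/40)^2 - 1 = 56.25$%, not 55.2%), so the
masking functions accept whatever excesses the user measured.
Pixel-bound conversion rounds each side's masked pixels half away from
zero before differencing, so viewports are bit-identical across platforms.

## Design expansion and speed simulation

`expand_design()` expands sites x flights x heights x angles x speeds into
one video record per combination (the study's 5 x 8 x 2 x 2 x 3 design
gives 480 videos, 12 per flight). Each record gets a blind code drawn as a
seeded permutation *within speed groups*: coders are blind to height and
angle but, because footage is grouped by speed for transfer, not to speed.
Faster flights are simulated by frame subsampling
(`simulate_speed()`): keeping every $k$-th frame of footage flown at the
base speed and playing it at the original rate reproduces a flight $k$
times faster. Frame 0 is always retained and non-integer speed ratios are
rejected rather than interpolated, mirroring the frame-extraction
procedure used on real footage. Real video decoding is out of scope; the
package handles footage at the metadata level (frame manifests,
durations, viewports).

## The count model

The analysis assumes per-video counts $y_{ij}$ (video $j$ of flight $i$)
follow a Poisson generalized linear mixed model:

$$y_{ij} \mid b_i \sim \mathrm{Poisson}\!\left(\exp(x_{ij}'\beta + b_i)\right),
\qquad b_i \sim N(0, \sigma^2),$$

with speed, height and angle as categorical fixed effects and a flight
random intercept absorbing the correlation among the 12 videos cut from
one flight. `fit_poisson_glmm()` maximises the *exact marginal
likelihood*: each flight's intercept is integrated out by Gauss-Hermite
quadrature adaptively centred and scaled at the flight's conditional mode
(found by a damped Newton iteration; the integrand is strictly
log-concave so the mode is unique). With a log link the integral depends
on a flight's data only through its total count and the sum of
$\exp(x'\beta)$ over its videos, which makes likelihood evaluations cheap
enough for the simulation studies below. Default 25 nodes; the fitted
log-likelihood changes by less than $10^{-6}$ between 15 and 25 nodes at
the study's size, and setting $\sigma = 0$ reproduces the independent
Poisson likelihood exactly (both are tested).

Numerical choices: $\sigma$ is optimised as $\log\sigma$ (unconstrained)
and reported on the natural scale; estimates within $10^{-6}$ of zero, or
whose $\sigma = 0$ likelihood is no worse than the interior optimum, are
reported as boundary fits with $\sigma = 0$. Optimisation starts from a
Poisson GLM solution plus two deterministic perturbed restarts, keeping
the best optimum. Fixed effects are reference-coded with levels in sorted
character order — reference = lowest speed, lowest height, -45 angle —
a convention the summaries document because the original analysis does
not state its coding. An all-zero response returns the boundary fit
rather than an error. Standard errors come from the numerical Hessian.

Model comparison uses likelihood-ratio tests against the null model
containing only the random intercept
(`likelihood_ratio_test()`): $2(\ell_{full} - \ell_{null})$, clipped at
zero, against $\chi^2_{df}$ with $df$ the difference in fixed-effect
count (4 for the full model: 2 for speed, 1 each for height and angle).
No boundary-mixture correction is needed since no variance component is
tested. Two screens accompany the fit: Cramér's V between design factors
(exactly 0 in a balanced factorial; the model is only fitted when
factors are near-independent) and a Pearson dispersion statistic
conditional on the empirical-Bayes modes, with residual df reduced by the
per-flight shrinkage weights $\lambda_i/(\lambda_i + 1/\sigma^2)$ so the
statistic is calibrated near 1 under a correct model.

The *reduced-dataset filter* (`reduced_dataset_filter()`) drops entire
flights in which no video recorded a detection — such flights indicate no
animals present rather than non-detection, and carry no information about
flight-parameter effects — while keeping all 12 videos of any flight with
at least one detection. Per-angle analyses reuse the same fitting code on
an angle-filtered subset with the angle term dropped ($df = 3$).

## Inter-coder agreement

`fleiss_kappa()` implements the multi-rater chance-corrected agreement
coefficient with counts as unordered nominal categories: agreement means
the identical count. This is deliberately strict — a coder reporting 5
versus 6 scores zero agreement on that video — matching standard kappa
usage; no partial credit is given. Unanimity with at least two categories
present gives $\kappa = 1$; unanimity within a single category makes the
chance-agreement term 1 and $\kappa$ undefined, which is returned as a
flagged "degenerate-perfect" result and counted as the strongest
agreement band in summaries.

Verbal bands follow the Landis-Koch convention with upper-closed
intervals: poor $(-\infty,0)$, slight $[0,0.20]$, fair $(0.20,0.40]$,
moderate $(0.40,0.60]$, substantial $(0.60,0.80]$, almost perfect
$(0.80,1]$. The conventional printed band list leaves a gap between 0.80
and 0.81; resolving it with a $>0.80$ cut is a documented package choice
recorded in the summary metadata. `agreement_summary()` computes kappa
per flight-parameter combination and thermal-contrast zone (12 x 2 cells
for the full design), per-band shares of combinations within each zone,
and marginal shares by factor under *two denominators* — share of
combinations and share of rated videos — because "substantial in X% of
cases" is ambiguous between the two; cells with fewer than two rated
videos are flagged and excluded from shares.

## The synthetic survey generator

`generate_counts()` realises the assumed count model so parameter
recovery, test calibration and the full pipeline can be validated
end-to-end. Defaults are the study conditions: the 5 x 8 x (2 x 2 x 3)
design; baseline $\beta_0 = \log 2.7$ (the observed mean count per
video); all flight-parameter effects zero, matching the null finding;
and $\sigma = 0.5$, a moderate between-flight heterogeneity chosen as
realistic for counts at sleeping sites with variable subgroup sizes
(fission-fusion grouping makes flight-to-flight totals vary well beyond
Poisson noise). A *mechanistic* mode replaces the log-normal mixing with
an explicit latent subgroup: $S_i \sim \mathrm{Poisson}$(mean 2.7) animals
present, each detected with a logistic probability in the same linear
predictor — the Poisson subgroup-size law is a placeholder (the true
distribution at sleeping sites is unknown) and is isolated behind that
mode.

`generate_coder_ratings()` assigns each video one thermal-contrast zone
(high with probability 0.7 — forest-only scenes dominate the study area)
and gives each coder a count
$\mathrm{Binomial}(y, p_z) + \mathrm{Poisson}(f_z)$ with defaults
$p_{high} = 0.95$, $p_{low} = 0.75$, $f_{high} = 0.02$, $f_{low} = 0.10$:
high-contrast zones are coded almost perfectly while heat-retaining
structures in low-contrast zones cause misses and false positives. These
four rates are calibration choices producing the qualitative pattern
observed in practice (higher and more consistent agreement in
high-contrast zones), not field-measured quantities. Assigning a single
zone per video is a simplification — real coders split videos into zone
sections — that keeps the data model flat while still exercising the
stratified kappa.

The random stream is split per flight and then per video from the master
seed, so enlarging a design leaves earlier flights' draws untouched, and
every output is byte-reproducible from (config, seed).

What the generator does *not* emulate: animal movement between the four
transect passes of a flight, coder drift over a session, zone sections
within a video, and any image-level phenomenon (blur at speed, thermal
crossover). Passing tests therefore validate the statistical machinery
under the assumed model, not the field accuracy of TIR counts.

## Validation problem sizes

The test suite validates the fitter against brute-force numerical
integration of the marginal likelihood on small groups (agreement to
$10^{-9}$), against an independent Newton solver for the $\sigma = 0$
limit, and against an independently implemented mixed-model fit on a
simulated survey. Calibration studies use: 500 null replicates at the
study's size (40 flights x 12 videos) for the LRT type-I error, whose
rejection rate at $\alpha = 0.05$ must fall in $[0.03, 0.07]$; 200
replicates of 200 flights x 12 videos for recovery of $\sigma = 0.5$
within $\pm 0.05$; and a 20/60/200-flight ladder for the shrinking-bias
trend. These sizes give Monte-Carlo error comfortably below the asserted
margins while keeping the default suite fast; kappa properties are
checked against a brute-force oracle to $10^{-12}$ and on 5,000
random-rating subjects for the near-zero null.

## Known limitations

* The geometry is flat-terrain pinhole optics: no lens distortion,
  terrain relief or earth curvature, and no gimbal dynamics.
* Counts are modelled as Poisson; overdispersed alternatives are not
  fitted (the dispersion statistic flags when they would be needed).
* Only a single scalar random intercept is supported — no crossed or
  nested effects, no REML.
* Agreement is exact-match nominal kappa; ordinal-aware coefficients
  (weighted kappa, ICC, Krippendorff's alpha) are out of scope.
* The pixel-size detection rule is the naive pinhole formula; tools that
  model atmospheric and sensor effects can give materially different
  (larger) maximum distances, so both the formula's result and any
  externally derived distance can be carried through
  `max_flight_height_agl()`.
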