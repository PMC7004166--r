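---
title: "Detecting musth from movement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting musth from movement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mature male African savanna elephants cycle through musth, a
physiologically distinct reproductive state marked by temporal gland
swelling and secretion and urine dribbling, during which bulls roam
faster and further in search of receptive females. Bulls over roughly 35
years express one long annual bout (on the order of two months); younger
bulls express several short bouts of up to two weeks. Because the state
is so strongly reflected in movement, it should be recoverable from GPS
collar data alone — which matters for remote study and for management,
since musth bulls are both reproductively important and potentially
dangerous near people.

`musthmove` implements that chain of inference end to end: raw fixes are
regularised and gap-filled, daily movement statistics are computed,
a mixed-effects model quantifies how the musth effect scales with age and
environment, and an ordered three-state hidden Markov model (HMM) detects
musth bouts in windows of daily speeds. A synthetic study system with
known ground truth exercises every stage.

## Track regularisation and the CTCRW

Collars report roughly hourly fixes (some deployments at 15- or 30-min
cadence). Fixes are snapped to the top of the hour when they fall within
±5 minutes of it (the nearest fix wins; the tolerance is a package
choice — fixes further off become gaps rather than being shifted by more
than a few minutes). Days are bounded at local midnight (UTC+3, the
study-region timezone).

Short gaps are filled with a continuous-time correlated random walk: per
projected coordinate, velocity follows an Ornstein–Uhlenbeck process
$dv = -\beta v\,dt + \sigma\,dW$ with mean-reversion rate $\beta$ (1/h)
and stationary SD $\sigma_v = \sigma/\sqrt{2\beta}$ (km/h), and position
is its integral. The two axes of a local azimuthal-equidistant
projection (centred on the track centroid) share parameters and are
treated independently. The exact discrete-time transition over a gap
$\Delta$ is Gaussian with

$$\operatorname{Var}(x_\Delta) = \sigma_v^2\left[\tfrac{2\Delta}{\beta}
  - \tfrac{3 - 4e^{-\beta\Delta} + e^{-2\beta\Delta}}{\beta^2}\right],\quad
  \operatorname{Var}(v_\Delta) = \sigma_v^2(1 - e^{-2\beta\Delta}),$$

so the likelihood is computed by a Kalman filter and interpolated
positions by the RTS smoother. GPS measurement error is fixed at zero —
collar error (tens of metres) is far below hourly displacements — so the
smoother reproduces observed fixes exactly and prediction reduces to
conditioning the Gaussian bridge. Parameters are fitted per individual by
maximum likelihood (L-BFGS-B on log scale); a fit on the parameter
boundary (e.g. a stationary track) falls back to linear interpolation, as
does any non-converged fit. Only gaps of at most 4 h are filled; a day is
analysable when its largest gap (including the lead-in from midnight and
tail-out to midnight) is at most 4 h and it has at least 20 hourly fixes,
interpolated fixes counting. Interpolated fixes participate in all
downstream statistics — gaps are filled precisely so that days remain
usable.

## Daily movement statistics

* **Mean speed (km/h)**: the mean over consecutive-fix steps of
  great-circle (haversine, sphere radius 6371.0088 km) distance divided
  by elapsed time. Steps crossing local midnight belong to the day in
  which they end.
* **Daily range (km²)**: the 95% minimum convex polygon. Fixes are
  projected to a local azimuthal-equidistant plane; the
  $\lceil 0.05\,n\rceil$ points farthest from the arithmetic centroid are
  peeled (distance ties resolved against the earlier fix), and the convex
  hull area of the remainder is reported. The peel rule is the classic
  MCP convention; computing on the projected plane makes the area
  rotation-invariant and metrically honest at daily scales.
* **Sinuosity (1/√km)**: the corrected index
  $2\,[p\,((1+c)/(1-c) + b^2)]^{-1/2}$ with $p$ the mean step length, $c$
  the mean cosine of turning angles and $b$ the CV of step length. It is
  computed for completeness but treated as optional downstream, being
  strongly collinear with speed and range.

## Environmental covariates

Slope (Horn's eight-neighbour estimator, degrees) and the vector
ruggedness measure (dispersion of surface unit normals over a 3×3
window, in [0,1]) are derived from the elevation grid; NDVI comes from
16-day composites, each valid from its start date; distance to water is
the great-circle distance to the nearest water feature; protected-area
membership is a point-in-polygon test. Raster values are sampled at the
nearest cell. Daily values are arithmetic means of the per-fix samples,
with the protected fraction rounded to binary (exactly 0.5 rounds in).
Continuous covariates are standardized once over the pooled analysis set
(never per individual); age stays in years, centred on 35 — the age from
which clear annual musth periods are expressed — so the musth main effect
reads as the effect for a 35-year-old. Grids are serialised as
plain-text ESRI ASCII rasters and vector features as GeoJSON, formats
chosen so that every artefact in the pipeline is human-readable text.

## The mixed-effects model

Log daily mean speed (or log MCP) is modelled with fixed effects
musth × {age, age², NDVI, NDVI², slope, slope², VRM, VRM², distance to
water and its square, protected} — 24 columns including intercept and
musth — a per-individual random intercept and NDVI slope (covariance
$G$), and residuals that are AR1 within individual with state-specific
variances: corr$(\varepsilon_s, \varepsilon_t) = \phi^{|s-t|}$ across
calendar-day gaps (the continuous-AR1 convention, chosen because included
days are frequently non-consecutive) and SD $\sigma$ on non-musth days
versus $\delta\sigma$ in musth.

The implementation profiles the fixed effects (GLS) and the residual
scale out of the marginal Gaussian likelihood and optimises the remaining
five parameters (log-Cholesky of $G/\sigma^2$, atanh $\phi$, log
$\delta$) numerically (Nelder–Mead polished by BFGS). Backward selection
drops one term per iteration — the largest-p LRT among droppable terms,
marginality respected (a quadratic protects its linear term, an
interaction its mains) — while p ≥ 0.05, refitting by ML; the selected
model is refitted by REML for reporting. The random structure is fixed,
not selected; its contribution is reported as a diagnostic LRT only. The
musth/non-musth ratio at age $a$ is
$\exp(\beta_\text{musth} + (a{-}35)\,\beta_{\text{musth:age}} +
(a{-}35)^2\beta_{\text{musth:age}^2})$ at average environmental
conditions, with a 95% CI from a nonparametric bootstrap that resamples
individuals (1,000 resamples at study scale; drivers default to fewer).

## The ordered three-state HMM

A detection window is eligible when the bull has at least six usable
observations including one musth sighting, and at least 120 days of daily
values with under 10% missing; the window spans up to 120 days either
side of the midpoint of the musth-observation dates. Within a window the
day series $y_t$ (log mean speed, or log MCP via a response switch)
follows

$$y_t \mid k \sim \mathcal{N}(\beta_k, \sigma_k), \qquad k \in \{1,2,3\},$$

where the latent state starts at 1 (pre-musth), may advance once to 2
(musth) with daily probability $q_1$ and once more to 3 (post-musth) with
probability $q_2$; no other moves exist. The left-to-right structure
encodes exactly one bout per window — multi-bout windows are outside the
model's contract, which is precisely why short-bout young bulls degrade
detection. Missing days contribute transition-only steps. The state
sequence is marginalised by the forward algorithm in log space
(implemented in C++; verified against brute-force path enumeration).

Priors are weakly informative and anchored on the window, mirroring an
analysis that anchored its priors on mixed-model estimates while leaving
the states free: $\beta_1, \beta_3 \sim \mathcal{N}(m_0, 0.5)$ with $m_0$
the window median; $\beta_2 \sim \mathcal{N}(m_0 + 0.7, 0.5)$ (an offset
of about a doubling of speed) constrained above
$\max(\beta_1,\beta_3)$ through an offset parameterisation;
$\sigma_k \sim$ half-normal(0.5); $q_1, q_2 \sim$ Beta(1, 30), since a
bout starts rarely on any given day and lasts weeks.

Sampling is Metropolis-within-Gibbs: an adaptive random-walk block plus
componentwise sweeps update the six emission parameters against the
marginal likelihood, and $q_1, q_2$ are redrawn exactly from their Beta
full conditionals given a path sampled by forward-filtering
backward-sampling. Adaptation stops at the end of warmup. The
study-scale configuration is 8 chains × 5,000 warmup + 5,000 sampling
iterations (40,000 retained draws); the package's desk-scale default for
tests and drivers is 4 × 1,000 + 1,000, which reaches the convergence
contract (split-chain $\hat R \le 1.1$ on every parameter) on
well-separated windows. Runs are seed-deterministic.

Decoding averages the smoothed state-2 marginal over posterior draws and
assigns musth where $P(\text{state}=2) > 0.5$ (the threshold is a package
choice). Bout change-days are read per draw from FFBS paths; the SD of
the bout duration over draws quantifies timing uncertainty. Posterior
predictive checks replicate the series per draw and report the quantile
of the observed mean, maximum and lag-1 autocorrelation; on real-style
data with day-to-day correlation the lag-1 check is expected to flag
misfit (the model deliberately keeps independent errors — an
autoregressive variant over-smooths and harms detection).

## Evaluation

Each usable observation labels the day before, of, and after the
sighting with its state; conflicting expansions resolve to the same-day
observation or drop the day. Sensitivity is the true-positive rate on
musth-labelled days, specificity the true-negative rate on non-musth
days. The primary aggregation is the mean of per-individual rates, with
pooled rates always reported alongside, because the two can differ
materially when individuals contribute very different numbers of
labelled days.

## The synthetic study system

The generator emulates exactly the statistical structure the models
assume. Daily log speed is baseline (0.3 km/h at age 35 — a plausible
daily-mean scale for savanna bulls) plus a mild decreasing age trend,
individual random intercept (SD 0.15) and NDVI slope (SD 0.05) on a
seasonal NDVI signal, a musth multiplier of 2.14 on musth days, and AR1
($\phi = 0.3$) lognormal noise with non-musth log-SD 0.19 (a ~20%
day-to-day CV) and mean-one correction so the multiplier is exact in
expectation. The musth-state log-SD is derived so the speed-scale SD
multiplier is 2.11. Bulls of 35+ get one ~60-day bout per year; younger
bulls several ~14-day bouts. The 24 hourly steps of a day form a
correlated random walk rescaled so the day's realised mean speed equals
its generated level, laid out on the projected plane and inverse-projected
to WGS84; fixes and whole days go missing at configurable rates (2%
defaults). Sightings are daily Bernoulli observations (rate 0.08) scoring
2–3 signals on musth days, 0 otherwise, with 5% downgraded to a single
ambiguous signal to exercise the exclusion rule.

What the generator does *not* emulate: habitat selection, social
dynamics, tortuosity structure beyond the statistics above, collar
measurement error, or multi-year seasonality. Passing tests therefore
demonstrate the pipeline's correctness and the detectability of
state-shifted movement under realistic noise — not performance on any
particular field dataset.

## Numerical choices and problem sizes

* Snap tolerance ±5 min; QC gap 4 h; minimum 20 fixes/day; decode
  threshold 0.5; MCP percent 95.
* The LME optimiser works on transformed scales with analytic profiling;
  degenerate evaluations ($G=0,\phi=0,\delta=1$) reproduce the closed-form
  OLS likelihood to 1e-8, and the likelihood is cross-checked against an
  independent mixed-model implementation on the nested
  random-intercept-and-slope submodel.
* Test and driver problem sizes are the package's own desk-scale choices:
  50 windows of 240 days for bout recovery, cohorts of 5 bulls per age
  class for end-to-end detection, 30 individuals × 120 days for LME
  parameter recovery, 150 replicates for selection behaviour. The
  study-scale MCMC configuration is retained as the default of
  `sample_posterior()`.

## Known limitations

* One bout per window by construction; recurrent short bouts are detected
  at best partially (this degradation is itself a finding the tests
  assert).
* The AR1 day-to-day correlation present in the generator (and in real
  data) is deliberately absent from the HMM emission model; the lag-1
  posterior predictive check is expected to flag it.
* The exact prior specification of the original field analysis is not
  public; the priors above are this package's documented stand-in.
* MCP and speed are correlated; MCP-based detection runs through the same
  machinery but is expected to perform slightly worse.
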