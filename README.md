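# musthmove

Movement-based detection of reproductive state in male African savanna
elephants.

Mature bulls periodically enter **musth** — a reproductively active,
hormonally distinct state signalled by temporal gland swelling/secretion
and urine dribbling — during which they travel markedly faster over
markedly larger daily ranges. Bulls over ~35 years hold one long annual
bout (~2 months); younger bulls express several short bouts. This
package implements the full chain of inference from raw GPS collar data
to automatic musth detection, for movement ecologists working with
long-term bio-logging data:

1. **Track regularisation** — fixes snapped to the hour; gaps ≤ 4 h
   interpolated with a continuous-time correlated random walk
   (integrated Ornstein–Uhlenbeck velocity model, Kalman
   filter/smoother, zero measurement error); days kept when the largest
   gap is ≤ 4 h and ≥ 20 hourly fixes remain.
2. **Daily movement statistics** — mean speed (haversine distance over
   elapsed time per step), 95% minimum convex polygon range on a local
   azimuthal-equidistant plane, corrected sinuosity.
3. **Environmental covariates** — Horn slope and vector ruggedness from
   an elevation grid, 16-day NDVI composites, great-circle distance to
   water, protected-area membership; pooled standardization, age centred
   on 35 years.
4. **Mixed-effects analysis** — log daily speed (or log MCP) with
   musth × {age, age², NDVI, NDVI², slope, slope², VRM, VRM²,
   dist-water, dist-water², protected} fixed effects, per-individual
   random intercept + NDVI slope, AR1(φ) residuals across day gaps with
   a musth variance ratio δ; profiled-GLS likelihood authored in the
   package, backward LRT selection, REML reporting, bootstrap CIs on the
   musth/non-musth ratio by age.
5. **Musth detection** — an ordered three-state Bayesian HMM on daily
   log speed: state 1 (before) → 2 (musth) → 3 (after), Gaussian
   emissions y_t|k ~ N(β_k, σ_k), daily transition probabilities q₁, q₂,
   single bout per window by construction. States are marginalised by a
   C++ forward algorithm; inference is adaptive
   Metropolis-within-Gibbs MCMC (conjugate Beta updates for q via
   forward-filtering backward-sampling), convergence gated at split-R̂
   ≤ 1.1, decoding by posterior mean smoothed state-2 probability > 0.5.
6. **Evaluation** — observations label the day before/of/after each
   sighting; sensitivity/specificity per individual and pooled.
7. **Synthetic study system** — covariate fields, hourly tracks with
   age-scheduled musth bouts (speed multiplier 2.14, SD multiplier 2.11,
   AR1 day noise, individual heterogeneity), and a sighting process —
   so every stage runs and is tested without any field download.

The methods vignette (`vignettes/musth-detection.Rmd`) documents the
models, priors, numerical choices and limitations.

## Worked example

The numbered scripts under `analysis/` run the pipeline on the synthetic
study system (a 6-bull cohort, ages 27–47, 240 days):

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_preprocess.R
Rscript analysis/03_daily_metrics.R
Rscript analysis/04_fit_lme.R --seed 1
Rscript analysis/05_detect_musth.R --seed 1
Rscript analysis/06_evaluate.R
```

which prints, stage by stage:

```
simulated 6 bulls x 240 days (303 musth days, 21.0%), 124 sightings
1409/1409 days pass QC; 708 fixes interpolated; CTCRW rates 1.03-1.15 /h
1409 analysable days, 286 with state labels; speed 0.13-1.17 km/h
musth speed ratio at age 35: 2.20 (phi = 0.20, delta = 1.08)
B004: interval 2022-03-27..2022-05-18, duration 53 +/- 0.1 d, max rhat 1.008
B005: interval 2022-05-31..2022-07-30, duration 61 +/- 0.2 d, max rhat 1.005
...
observation-day scoring: mean sens 0.81, mean spec 0.99 (pooled 0.81/0.98)
ground-truth scoring:    mean sens 0.81, mean spec 0.98
```

Read: the simulator plants musth bouts whose mean daily speed is 2.14×
the bull's non-musth speed; the mixed model recovers that multiplier as
`exp(β_musth)` ≈ 2.20 at the centring age under average conditions; the
HMM finds each older bull's bout to within days with sub-day duration
uncertainty; scoring against observation-days shows high specificity for
all bulls, with sensitivity pulled down by the young, short-bout bulls —
the same age contrast the detection method shows on real elephants. One
young bull's posterior fails the R̂ ≤ 1.1 gate (its several short bouts
make the single-bout model multimodal) and is flagged non-converged in
`hmm_posteriors.json` — the documented failure mode for the under-35
class. (The mean-of-individuals aggregation differs from the pooled
rates whenever bulls contribute unequal numbers of labelled days; both
are always reported.)

Each script writes its tables under `results/` (`daily_metrics.csv`,
`lme_fit.json`, `effect_ratio_by_age.csv`, `musth_decode.csv`,
`hmm_posteriors.json`, `evaluation.json`).

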