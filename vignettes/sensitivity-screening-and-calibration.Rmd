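---
title: "Screening, consistency testing and Bayesian calibration of a wheat crop emulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening, consistency testing and Bayesian calibration of a wheat crop emulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropsens)
```

## What this package is for

Process-based crop simulators expose dozens of cultivar and soil
parameters, and calibrating all of them against a handful of field
seasons is both expensive and statistically fragile. The standard remedy
is a two-stage workflow: a *global sensitivity analysis* first screens
the parameter space and identifies the subset that actually moves the
outputs of interest, and a *Bayesian calibration* then estimates only
that subset. `cropsens` implements this workflow end to end for a
winter-wheat setting with six irrigation treatments at an arid site,
with two outputs: aboveground total dry matter at maturity (WAGT) and
grain yield, both in kg ha^-1^.

Because the workflow has to be testable at desk scale, the package
ships a deterministic daily-step wheat *emulator* with exactly the
21-parameter interface of the screening study (thermal-time phenology
targets T1--T4, grain formation and filling G1/P1/P2/M2/X1, grain
nitrogen P3/M1, development modifiers P4/V1, canopy K/Y1/I1/S1/I2, and
resource capture R1/E1/N1), plus a seeded weather generator for the
site climate. Every stage — Morris screening, extended-FAST variance
decomposition, Savage-score concordance testing, Metropolis
calibration, and Moriasi-style model grading — runs against this
emulator in seconds to minutes, and can be re-pointed at an external
simulator through the adapter contract of `simulator_adapter()`.

## The parameter space

`load_bounds()` returns the bundled registry of the 21 parameters with
their uniform screening ranges (roughly ±50% around nominal cultivar
values, plus physically bounded ranges such as the extinction
coefficient K on [0, 1]). All sampling happens on the unit hypercube
and is mapped through `to_physical()`; `midpoint_defaults()` is the
baseline ("default cultivar") parameter set.

```{r}
specs <- load_bounds()
head(as.data.frame(specs), 4)
```

## The synthetic environment

`generate_weather()` produces a seeded daily series (day from sowing,
Tmax, Tmin, rain, radiation) for a temperate continental arid climate:
sinusoidal temperature cycle with a ~6.5 °C annual mean, clear-sky
radiation curve, and sparse precipitation events totalling ~190 mm
annualized. Sowing is anchored in mid September; days are indexed from
sowing rather than by calendar date because everything downstream is
thermal-time driven.

The default season length is 340 days. A nominal parameter set matures
around day 290 (early July), matching a mid-September-to-early-July
winter-wheat season; the margin beyond that exists because screening
designs visit the corners of the bounds, and the slowest corner
(all four thermal-time targets at their upper bounds with maximal
photoperiod/vernalization delay) needs about 2 600 °C d, which this
climate only accumulates by roughly day 320--330. A weather series too
short for a draw's phenology raises an error rather than silently
truncating the season, since truncation would corrupt elementary
effects exactly at the design corners.

The six soil-moisture treatments W1--W6 (`build_treatment()`) set a
lower irrigation limit, as a percentage of field capacity (FC =
26.15 vol-%), for each of seven growth phases; the bucket refills to FC
whenever storage crosses the active limit. W1 holds 65 %FC everywhere;
the other five move specific phases to 50 %FC (drier) or 80 %FC
(wetter) around greening--jointing or heading--grain-filling.

```{r}
build_treatment("W3")$lower_limit
```

## The emulator

`run_emulator()` advances a daily loop from sowing to maturity:

* **Phenology.** Daily thermal time `max(0, (Tmax+Tmin)/2)` with base
  0 °C accumulates toward the stage boundaries T1 (jointing), T1+T2
  (flowering), +T3 (grain-fill onset) and +T4 (maturity). Pre-jointing
  development is slowed by the photoperiod/vernalization factor
  `1/(1 + 0.02 P4 + 0.02 V1)` and gated by chill-day accumulation, so
  no parameter draw can reach jointing before winter — without the
  gate, low-T1 draws joint in autumn and the output surface has a
  cliff in the middle of the T1 range. Days are split into sub-day
  segments at every thermal-time boundary so stage transitions are
  continuous in the parameters; the integer-day staircase otherwise
  injects broadband noise into the Fourier spectra that EFAST
  decomposes.
* **Water.** A single 0--60 cm bucket: rain and refill-to-FC
  irrigation in, smooth saturating root uptake out, demand equal to E1
  times a Hargreaves-style reference. The stress factor (supply over
  demand) enters growth with stage-specific exponents — sensitivity
  peaks between jointing and heading and is mildest during late grain
  fill, which is what lets irrigation timing treatments differentiate
  while keeping late-season growth responsive to T4.
* **Canopy and biomass.** Leaf area expands thermally during tillering
  and through a leaf-mass term (Y1, I1), saturating against the I2
  ceiling; light interception is `1 - exp(-k_eff LAI)` with `k_eff`
  affine in K. Daily biomass is radiation × interception × stress ×
  nitrogen factor × stage vigor, scaled by establishment (T1) and
  spike-capacity (T2) factors that encode how autumn tillering and
  spring spike development set season-long sink capacity.
* **Grain.** Grain number is fixed at grain-fill onset from stem
  biomass and the thermal windows that set tillering, spikelet number
  and grain set (T1, T2, T3), reduced by drought around flowering
  (floret abortion). Filling proceeds at a smooth co-limitation of a
  thermal-time-driven potential rate (P1, tapering late in the window)
  and the assimilate supply per grain (current photosynthesis through
  the ear-layer light factor in K, plus stem reserves accumulated
  during the lag phase), capped softly by the maximum grain mass M2
  and a harvest-index ceiling of 0.55.

### Tuned constants and what the emulator does and does not claim

The emulator is explicitly an emulator. Its fixed constants
(`emulator_constants()`) were tuned once so that, over the bundled
bounds, its influential-parameter structure matches the reference
screening findings: WAGT driven by the thermal-time targets T1, T2, T4
and the water-demand multiplier E1 (with T1 ranked first by Morris
μ\*), yield by those four plus G1, T3, P1 and K, and everything else —
including the ±10% radiation-use-efficiency parameter R1, the grain
nitrogen rates M1/P3, and the canopy shape parameters — below the
screening thresholds. The constants ship frozen and a regression test
guards the emulator's reference outputs bit-for-bit.

Passing these tests demonstrates that the *workflow* recovers a known
sensitivity structure from ~4 000-run designs; it does not make the
emulator an agronomic model. Its harvest index (~0.1--0.2) is lower
than field wheat, nitrogen limitation is a single multiplier rather
than a cycle, the soil is one bucket, and no claim of fidelity beyond
the sensitivity structure is intended. Real data differ from the
synthetic observations in having structured (non-Gaussian,
year-correlated) errors and model discrepancy, so calibration results
on real records will be less clean than the recovery experiments here.

## Morris screening

`build_trajectories()` generates one-at-a-time trajectories on a
p-level grid with Δ = p/(2(p−1)) (p = 4 by default, so Δ = 2/3), each
perturbing every factor exactly once: t trajectories over n factors
cost t(n+1) runs — the classical screening budget (640 runs for t = 10
over 63 factors). Elementary effects are computed in unit-hypercube
coordinates so μ\* is comparable across parameters with different
units; μ\* (mean absolute effect) measures influence, σ (standard
deviation of effects) interaction/nonlinearity strength. A factor is
screened as influential when its μ\* exceeds the across-factor mean —
with the maximal factor always included, since an upper cut at the
maximum would absurdly exclude the strongest driver. σ is reported but
not thresholded.

```{r}
ctx <- study_context(years = 1, weather_seed_base = 100L)
m <- morris_emulator(ctx, "W1", t = 4, seed = 1)
head(m$wagt[order(m$wagt$rank), ], 5)
```

## EFAST

`build_fast_design()` drives each factor along the periodic search
curve `x(s) = 1/2 + arcsin(sin(ω s + φ))/π` with seeded phases. In the
block for factor *i*, that factor carries the highest frequency
`ω_max = floor((Ns − 1)/(2M))` (M = 4 harmonics) and the complementary
factors share low frequencies in `[1, max(1, ω_max/(2M))]`; at the
customary Ns = 70 per block this means ω_max = 8 with every
complementary factor at frequency 1.

The variance decomposition follows the classical estimator in
substance — `Si = V_i/V` from the harmonics of ω_max, `STi = 1 −
V_(−i)/V` — with three numerical choices that matter at small Ns and
are validated against closed forms:

* the complementary band is *all* frequencies below ω_max, because the
  harmonic tails of the frequency-1 complementary factors fill every
  low bin, not just those below ω_max/(2M);
* the total variance V is estimated from the pooled outputs of all
  blocks: along a single curve the complementary factors co-move on a
  one-dimensional manifold and their contributions interfere, making
  the single-curve spectrum a noisy estimate of V, while the pooled
  point cloud covers the hypercube with uniform marginals;
* interactions of the factor of interest appear as sidebands around
  its harmonics; the lower sidebands are inseparable from the
  complementary band, so the clean upper sidebands are counted twice
  (spectral symmetry) to form the interaction content of STi.

On the Sobol g-function at Ns = 1027 the first-order indices agree
with the closed form within ±0.05 and with an independent Monte-Carlo
pick-and-freeze estimator; on additive models Si is exact to the
estimator tolerance and STi ≈ Si. Degenerate (constant-output) blocks
report zero indices with a machine-readable flag instead of NaN so
batch pipelines never halt on dead corners.

A multi-year screening plan is read as *one design per season
replicate*: `efast_emulator()` builds an independent design per year
(seeded `seed + year − 1`), decomposes each year's outputs separately,
and averages the index tables — three year-replicates at Ns = 70 over
21 parameters cost 21 × 3 × 70 = 4 410 emulator runs. Influence uses
the joint rule Si > 0.05 and STi > 0.10.

## Rank consistency across treatments

Whether the same parameters matter under every irrigation regime is a
question about agreement of *rankings*, weighted toward the top ranks.
`savage_scores()` implements the rank transform `ss(r) = Σ_{i=r}^n 1/i`
(scores always sum to n; ties share the mean of their spanned scores),
and `tdcc()` the top-down concordance coefficient

C_T = (Σ_i (Σ_j ss_ij)² − m²n) / (m²(n − Σ_{i=1}^n 1/i)),

which equals 1 for identical rankings and has null expectation 1/m
under independent rankings — consistent with the significance test
T = m(n−1)C_T against χ² with n−1 degrees of freedom, whose null mean
is n−1. The χ² approximation was checked against a 10 000-permutation
null at n = 6, m = 3. Because a per-treatment consistency table can be
read two ways, `consistency_report()` offers both groupings: the m
treatments as the repetition columns of one coefficient per
year × variable (`mode = "columns"`), or each treatment scored against
the consensus ranking (`mode = "consensus"`).

## Calibration and evaluation

`run_mcmc()` samples the posterior of the eight yield-influential
parameters (the other thirteen pinned at midpoints) by single-chain
random-walk Metropolis in unit-hypercube coordinates: uniform priors
on the bounds (out-of-support proposals rejected), Gaussian likelihood
with per-observation residuals `O_j − P_j(θ)` and fixed observation SD
σ_o, Gaussian proposals at 5% of bound width. The package deliberately
omits multi-chain diagnostics and adaptation; chains are seeded and
reproducible, and the recovery experiment below is the calibration's
operating check. The observation σ_o is a configuration value; the
synthetic-observation generator's default noise (300 kg ha^-1^,
additive Gaussian to match the likelihood) is a design choice of the
synthetic study, not an estimate of real field error.

Three point estimates are available: posterior mean (default),
maximum-a-posteriori draw, and the best point visited anywhere in the
run including the start. The evaluation stage uses the best-visited
point as the "Optimized" set, which gives the clean guarantee that
optimization can never fit worse in-sample than the default set it
started from.

`fit_metrics()` computes R², Willmott's d, RMSE, MAE, NSE and RSR
under the population (divide-by-n) SD convention, which makes
RSR² = 1 − NSE an exact internal identity, and `performance_grade()`
assigns Excellent/Good/Satisfactory/Unacceptable from joint NSE/RSR
bands (band table is data, `grade_bands()`, with the Good band's RSR
ceiling at 0.60 so the published grade labels reproduce from their
printed NSE/RSR pairs; the worse statistic always wins).

The shipped recovery experiment draws true values for the free eight
uniformly from the middle half of their ranges (pinned parameters stay
at their pinned values, so the machinery is tested well-specified),
generates 18 noisy observations (6 treatments × 3 years), and checks
that the 95% credible intervals cover the truth in at least 90% of 20
seeded replicates and that the optimized set's in-sample RMSE beats
the midpoint default in every year.

## Study sizes and reproducibility

The default study (`run_study()`) uses the screening sizes of the
published plan — t = 10 trajectories (640 runs in the 63-factor
grouping), Ns = 70 per block (4 410 EFAST runs per treatment) — and
desk-scale calibration chains of a few thousand iterations; the test
suite and the acceptance script run the full set of checks in a few
minutes on one CPU. Every stage is seeded, every artifact is delimited
text, and `manifest.json` records the seeds and counts needed to
reproduce any number in the output tables. Designs can be exported
with `write_design()` for an external batch simulator and the outputs
re-imported with `read_design_outputs()`, which is exactly the
round trip a real crop-model study would drive through the
`simulator_adapter()` contract.
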