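# cropsens

Global sensitivity analysis and Bayesian calibration for daily-step
crop simulators, built around a 21-parameter winter-wheat emulator so
the whole workflow — screening, variance decomposition, rank-agreement
testing, calibration and model grading — runs reproducibly at desk
scale.

## The problem

Process-based crop models expose dozens of cultivar and soil
parameters; calibrating all of them against a few field seasons is
expensive and ill-posed. The standard workflow screens the parameter
space first and calibrates only the influential subset:

1. **Morris elementary-effects screening.** One-at-a-time trajectories
   on a p-level grid; for factor *i*,
   `EE_i = (y(x + Δ e_i) − y(x)) / Δ`, summarized by μ\* (mean |EE|,
   influence) and σ (SD of EE, interactions/nonlinearity), at a cost of
   `t (n + 1)` model runs for `t` trajectories over `n` factors.
   Influential: μ\* above the across-factor mean.
2. **Extended FAST (EFAST).** All factors driven along periodic search
   curves at incommensurate frequencies; the output spectrum partitions
   variance into first-order `S_i = V_i / V` and total-order
   `S_Ti = 1 − V_{−i} / V` indices. Influential: `S_i > 0.05` and
   `S_Ti > 0.10`.
3. **Top-down concordance (TDCC).** Rankings from different
   soil-moisture treatments are compared after a Savage-score transform
   `ss(r) = Σ_{i=r}^{n} 1/i`;
   `C_T = (Σ_i (Σ_j ss_ij)² − m²n) / (m² (n − Σ_i 1/i))` equals 1 for
   identical rankings and is tested via `T = m (n−1) C_T ~ χ²_{n−1}`.
4. **Bayesian calibration.** Random-walk Metropolis over the
   influential parameters with uniform priors on their bounds and a
   Gaussian likelihood `Σ_j [−½ log(2π σ_o²) − (O_j − P_j(θ))²/(2σ_o²)]`.
5. **Evaluation.** R², Willmott's d, RMSE, MAE, NSE and RSR
   (`RSR² = 1 − NSE` exactly under the population-SD convention), with
   Excellent/Good/Satisfactory/Unacceptable grades from joint NSE/RSR
   bands.

The bundled emulator maps 21 named parameters (thermal-time phenology
targets T1–T4, grain parameters G1/P1/P2/M2/X1, grain-nitrogen rates
P3/M1, development modifiers P4/V1, canopy K/Y1/I1/S1/I2, resource
capture R1/E1/N1) plus seeded arid-site weather and one of six
irrigation treatments (W1–W6) to aboveground dry matter (WAGT) and
grain yield in kg·ha⁻¹. Its tuning constants are frozen so that its
influential-parameter structure reproduces the reference screening
findings (WAGT driven by T1, T2, T4, E1; yield by those plus G1, T3,
P1, K); the methods vignette documents the model, the estimator
choices and the limits of what the emulator does and does not claim.

## Worked example

```r
library(cropsens)

specs <- load_bounds()                       # the 21 parameters, Table-style bounds
ctx   <- study_context(years = 3)            # weather x 3 seasons + plans W1..W6

# one run at the baseline (bound midpoints), control treatment
run_emulator(midpoint_defaults(specs), ctx$weather[[1]], ctx$plans$W1)
#> wheat emulator output: WAGT 21624 kg/ha, yield 2458 kg/ha (maturity day 295)

# EFAST screening of yield for W1: 21 x 3 x 70 = 4410 emulator runs
r <- efast_emulator(ctx, "W1", Ns = 70, seed = 1)
head(r$yield[order(r$yield$rank), ], 9)
#>    factor     Si   STi rank influential
#> 13      K 0.0510 0.130    1        TRUE
#> 7      G1 0.0942 0.126    2        TRUE
#> 9      T1 0.0861 0.121    3        TRUE
#> 11     T3 0.0953 0.116    4        TRUE
#> 1      P1 0.1001 0.115    5        TRUE
#> 10     T2 0.0962 0.114    6        TRUE
#> 12     T4 0.0855 0.109    7        TRUE
#> 18     E1 0.0808 0.104    8        TRUE
#> 14     R1 0.0098 0.016    9       FALSE
classify_influential_fast(r$yield)           # the eight yield drivers

# do the six irrigation treatments agree on the ranking?
mat <- sapply(paste0("W", 1:6), function(tr)
  efast_emulator(ctx, tr, years = 1, Ns = 70, seed = 2)$yield$STi)
tdcc(mat)
#> TDCC = 0.925 (T = 111.04 on 20 df, p = 1.27e-14) *
```

The first table reads: across the bounds, yield variance is spread
over eight parameters (total-order indices 0.10–0.13 each, first-order
0.05–0.10), while the remaining thirteen — including the ±10%
radiation-use-efficiency parameter R1 — fall below the joint
`Si > 0.05 & STi > 0.10` screening rule. The concordance of 0.93
(p ≪ 0.01) says all six irrigation regimes rank the parameters
essentially identically, which is what licenses calibrating one
parameter subset across treatments.

The full pipeline — both screening methods for every treatment and
season, consistency tables, calibration of the eight yield drivers
against synthetic observations, and the default-versus-optimized
evaluation table — is one call:

```r
run_study(study_config(seed = 1, out_dir = "study-out"))
```

A thin command-line front end with the same verbs lives at
`inst/scripts/cropsens-cli.R` (`sa`, `tdcc`, `calibrate`, `evaluate`,
`demo`).

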