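# dcenirs

Absolute tissue blood flow from dynamic contrast-enhanced time-resolved
near-infrared spectroscopy (DCE TR-NIRS).

Joint inflammation drives angiogenesis and increased perfusion, so
absolute joint blood flow (BF, mL/min/100 g) is a candidate marker for
monitoring inflammatory arthritis and its treatment. DCE TR-NIRS measures
it by tracking an indocyanine green (ICG) bolus: a pulsed laser and
time-correlated single-photon counting record photon time-of-flight
histograms (DTOFs) through the joint while a dye densitometer records the
arterial dye concentration. This package implements the full analysis for
that measurement — and, because raw instrument data are rarely shareable,
a physics-based synthetic generator for every input it consumes — aimed at
researchers developing or validating optical perfusion pipelines.

The processing chain:

1. **Pathlength** from the mean time of flight,
   `p = (c/n) (<t>_DTOF − <t>_IRF)`, with `n = 1.4`.
2. **Absorption changes** by the modified Beer–Lambert law,
   `Δμa(t) = ln[I0 / I(t)] / p`, intensities being per-frame photon
   totals and `p` fixed at its pre-injection baseline.
3. **Tissue ICG concentration** `Q(t) = Δμa(t) / (ln 10 · ε_ICG)` with
   the decadic ICG extinction coefficient at 805 nm (default 0.186
   µM⁻¹cm⁻¹).
4. **Blood flow** by regularized deconvolution of the indicator-dilution
   model `Q = f (Ca ⊛ R)`: a lower-triangular Toeplitz system solved by
   SVD Tikhonov regularization (λ from generalized cross-validation) with
   a nonnegative, nonincreasing-after-peak projection;
   `BF = 6000 · max(f·R) / ρ`.

Around that core: an India-ink titration phantom validation with
zero-intercept regression (`Δμa,expected = ln10 · 0.885 · ε_ink · Δc`),
repeat/side aggregation rules, a three-way repeated-measures ANOVA
(time × side within, group between) with Mauchly and Shapiro–Wilk checks
and partial η², Tukey HSD over timepoints, a heart-rate confound
correlation, Ward/k-means cohort clustering with elbow selection, and
noncentral-F power analysis for the time × group interaction under both
circulating effect-size conventions.

## Worked example

Simulate one bolus measurement at a known flow and recover it:

```r
library(dcenirs)

scene <- optical_scene()                 # 1 cm rat-ankle slab, 805 nm
irf   <- synthetic_irf(scene)
times <- seq(0, by = 0.3, length.out = 400)   # 400 DTOFs over 120 s

ca    <- generate_airf(times = times)          # arterial bolus, inj. at 10 s
truth <- perfusion_truth(bf_true = 15)         # 15 mL/min/100 g
qt    <- generate_tissue_curve(ca, truth)
stack <- generate_dtof_series(scene,
           scene$mu_a_baseline + icg_concentration_to_delta_mua(qt),
           irf, counts_per_frame = 3e5, seed = 1)

ac  <- delta_mua_timecourse(stack, irf, baseline_window = c(0, 10))
qm  <- to_icg_concentration(ac)
est <- deconvolve_bf(ca, qm)
est
#> Flow-scaled residue estimate
#>   BF: 15.16 mL/min/100 g (rho = 1.05 g/mL)
#>   regularization: gcv, lambda = 1.54, delay = 0.0 s
#>   refolding residual (RMS): 0.000765 uM

pathlength_sensitivity(stack, irf, ca, perturbation = 0.005)$percent_change
#> [1] 0.5025126
```

The recovered flow is within noise of the 15 mL/min/100 g ground truth;
the refolding residual sits at the counting-noise level of the tissue
curve; and perturbing the baseline pathlength by ±0.5% moves the flow
estimate by only ±0.5%, since BF scales as 1/p through the whole chain.

The phantom validation on a synthetic 10-step ink titration
(100 shot-noise frames per step, expected Δμa 0.005–0.048 cm⁻¹):

```r
series <- generate_phantom_series(seed = 1)
phantom_pipeline(series)$regression
#> Zero-intercept regression: slope = 0.9342, R2 = 0.99975, F(1,9) = 36603.2, Shapiro p = 0.0503
```

The slope just below one is the documented Beer–Lambert secant bias of a
baseline-fixed pathlength at the large end of the titration; linearity is
essentially perfect. See the methods vignette (`vignettes/methods.Rmd`)
for the models, parameter defaults, and their rationale.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data
and write their tables to `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | generates the phantom titration, one bolus measurement, and the 12-animal longitudinal study |
| `02_phantom_validation.R` | zero-intercept regression of measured vs expected Δμa |
| `03_quantify_bf.R` | DTOF → Δμa → Q → BF, pathlength sensitivity, noise sweep over flow levels |
| `04_longitudinal_stats.R` | aggregation, repeated-measures ANOVA, Tukey HSD, HR confound, cohort clustering |
| `05_power_analysis.R` | interaction power and required sample size under both effect-size conventions |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

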