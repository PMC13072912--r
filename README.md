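# xrfnet

Neural-network calibration for trace **arsenic quantification by ED-XRF under
lead spectral interference**, with a physics-grounded spectrum simulator and
the full method-validation battery.

## The problem

Energy-dispersive X-ray fluorescence is a rapid, low-cost, minimally
destructive way to screen heavy metals in food, and rice-based foods are the
canonical As screening target (regulatory limits sit near 200 µg kg⁻¹). But
the principal emission lines of As (Kα = 10.52 keV) and Pb (Lα = 10.50 keV)
are separated by 0.02 keV while a benchtop silicon-drift detector resolves
~0.135 keV FWHM (at Mn Kα) — the two peaks fuse into one. The weak secondary
lines (As Kβ 11.73 keV, Pb Lβ 12.62 keV) cannot carry a univariate
calibration near the detection limit.

`xrfnet` resolves the overlap statistically. Net counts in two narrow
spectral windows — the overlap region (10.35–10.70 keV) and the Pb Lβ region
(12.40–12.85 keV) — feed a feed-forward network (82 → 256 → 128 → 2, ReLU,
dropout p = 0.1) trained full-batch with Adam (lr = 10⁻⁵, 10 000 epochs)
under a joint RMSE loss, with best-checkpoint early stopping against an
independent test set and a one-pass residual z-score outlier screen
(|z| = |r/σᵣ| > 2.5) between a preliminary and the final fit. Method
performance follows the standard playbook:

- calibration R², standard error of calibration `SEC = √(Σ(x̂−x)²/(N−1))`;
- Eurachem replicate limits `LOD = 3·s₀/√n`, `LOQ = k_Q·s₀/√n` (k_Q = 10)
  under two scenarios (As alone; As with Pb interference), plus bias
  `b = x̄ − x_actual`;
- a ±20 % validation-agreement protocol with per-category mean/median error
  summaries.

Because the underlying raw spectra of such studies are rarely public, the
package includes a forward simulator (Gaussian detector response with
√E-scaled resolution, fluorescence yields ω_As = 0.549 / ω_Pb = 0.386,
Lα:Lβ branching 1.61, exponential matrix continuum, Poisson counting noise,
untracked pellet-to-pellet background variation) that regenerates the whole
study design — 28 calibration standards × 9 spectra, two 10-standard limit
scenarios, a 24-sample validation panel — from a single seed.

## Worked example

```r
library(xrfnet)

# simulate a compact calibration campaign: 8 standards, 3 pellets x 3 repeats
design <- default_calibration_design()[c(1:4, 8, 11, 20, 26), ]
cal <- simulate_standards(design, seed = 42)

# an independent test set for checkpointing (the simulated validation panel)
val <- simulate_validation(seed = 43)
test_ft <- assemble_dataset(val$spectra, val$standards)

# two-pass calibration: preliminary fit, residual z-screen, final fit
fit <- fit_calibration(
  cal$standards, cal$spectra, test_ft,
  spec = net_spec(hidden_sizes = c(64L, 32L)),
  config = train_config(learning_rate = 1e-4, n_epochs = 2000L,
                        eval_every = 200L, seed = 1L)
)
print(fit)
#> <xrf_calibration> 8 standards retained, 0 excluded (|z| > 2.5)
#>  element        r2      sec relative_sec     slope intercept n
#>       As 0.9996364 6.794552     1.132425 0.9702522  7.274858 8
#>       Pb 0.9983431 8.216999     2.054250 0.9643601  5.290182 8

# detection limits under Pb interference (scenario 2)
sc2 <- simulate_scenario(2, seed = 44)
ft2 <- assemble_dataset(sc2$spectra, sc2$standards)
agg <- aggregate_by_standard(predict(fit$model, ft2))
detection_limits(agg$as_mean, n = 3, actual = 128.97, element = "As")
#>   element actual mean_pred bias_abs bias_pct    s0 n kQ  lod   loq
#> 1      As    129     172.4    43.41    33.66 9.413 3 10 16.3 54.35
```

Reading the output: the simulated calibration is nearly ideal (synthetic
spectra are cleaner than real ones), the replicate spread of ten As
determinations at 128.97 µg kg⁻¹ is s₀ ≈ 9.4 µg kg⁻¹ giving
LOD ≈ 16 µg kg⁻¹ and LOQ ≈ 54 µg kg⁻¹ when results average three pellets —
well inside regulatory needs — while the short-trained model of this small
example over-reports As by ~34 % at that level (`bias_pct`), the kind of
concentration-dependent bias the validation protocol is there to catch.
`tidy()`, `glance()` and `autoplot()` work on fitted objects
(`xrf_ann`, `xrf_calibration`); `plot_spectra()` draws averaged net spectra
with the feature windows shaded.

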