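---
title: "Resolving the As/Pb spectral overlap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving the As/Pb spectral overlap: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrfnet)
```

## The analytical problem

Trace arsenic in rice and rice-based foods is regulated at levels around
200 ug/kg, and energy-dispersive X-ray fluorescence (ED-XRF) would be an
attractive screening tool -- rapid, low-cost and minimally destructive --
were it not for one awkward coincidence: the principal As emission
(K-alpha, 10.52 keV) sits 0.02 keV away from the principal Pb emission
(L-alpha, 10.50 keV), while a benchtop silicon-drift detector resolves about
0.135 keV FWHM at Mn K-alpha (about 0.18 keV at 10.5 keV). The two peaks are
one unresolvable blob. The secondary lines that could break the degeneracy
(As K-beta at 11.73 keV, Pb L-beta at 12.62 keV) are intrinsically weak, so
near the detection limit everything of interest happens at poor
signal-to-noise.

`xrfnet` implements a calibration strategy for this regime: feed narrow
spectral windows around the overlap region and the Pb L-beta region into a
small feed-forward neural network trained to output both concentrations at
once, let the network learn the deconvolution statistically, and wrap the
result in the standard method-performance battery (calibration metrics,
replicate-based detection limits, a +/-20 % validation-agreement protocol).
Because the raw spectra behind the original study are not publicly
available, the package also ships a physics-grounded forward simulator that
generates the entire study design from scratch; every claim the test suite
makes is made against simulated data whose ground truth is known.

## The forward simulator

An acquisition is simulated as

$$\mathbb{E}[\text{counts}_i] \;=\; C(E_i)\;+\;\sum_{\ell}
c_{z(\ell)}\, S\, \omega_\ell\, b_\ell \int_{E_i-\Delta/2}^{E_i+\Delta/2}
\mathcal{N}(E;\,E_\ell,\sigma_\ell)\,dE,$$

with observed counts drawn channelwise from a Poisson law. Here $C(E)$ is a
smooth matrix continuum, $c_z$ the element's total concentration (gravimetric
spike plus the rice unit's intrinsic contamination), $S$ the detector
sensitivity, $\omega_\ell$ the shell fluorescence yield, $b_\ell$ the
in-shell branching fraction and
$\sigma_\ell = \mathrm{FWHM}(E_\ell)/2.3548$ with
$\mathrm{FWHM}(E) = 0.135\sqrt{E/5.895}$ keV -- the square-root energy
scaling of Fano-limited silicon detectors anchored at the Mn K-alpha
resolution. The Gaussian is integrated over each channel, so line areas are
exact for any channel width.

The line table (`emission_lines()`) carries the physics the calibration
problem hinges on:

| line | energy (keV) | yield $\omega$ | branch $b$ |
|------|-------------:|---------------:|-----------:|
| As K-alpha | 10.52 | 0.549 | 1 |
| As K-beta  | 11.73 | 0.549 | 0.15 |
| Pb L-alpha | 10.50 | 0.386 | 1 |
| Pb L-beta  | 12.62 | 0.386 | 1/1.61 |

Two consequences follow and are enforced as invariants: at equal
concentration the As signal at 10.5 keV is $0.549/0.386 \approx 1.42$ times
the Pb signal, and the Pb L-alpha area is 1.61 times the L-beta area. Pb K
lines near 74 keV are excluded -- a 50 kV tube cannot excite them.

### Tunable parameters and their defaults

* **Sensitivity** (`detector_model(sensitivity = 8)`, counts per ug/kg per
  unit emission weight in a 120 s acquisition). Chosen so the lowest-As
  calibration standard (87.82 ug/kg, the intrinsic level of the cleaner
  Calrose rice unit) shows a peak signal-to-noise ratio of about 4 on the
  9-replicate averaged spectrum -- a weak but clearly identifiable peak,
  which is how such a standard presents on a real benchtop instrument.
  Absolute count rates per ug/kg are otherwise unconstrained by published
  information, so this parameter is exposed in the configuration.
* **Continuum**: amplitude 200 counts/channel at 10.5 keV decaying
  exponentially at 0.1 keV^-1. Only a smooth background under the two
  feature windows matters; coherent-scatter structure (Ag anode lines near
  22 keV) lies far outside both windows and is not modelled.
* **Background variability** (`background_cv = 0.05`): the true continuum
  amplitude of each acquisition varies lognormally (CV 5 %) around the
  nominal value while the *recorded* background estimate stays nominal.
  Real pellets do not scatter identically, and the instrument's background
  estimate does not track pellet-to-pellet matrix variation; a model
  calibrated on such data must absorb that mismatch.
* **Windows** (`region_spec()`): 10.35-10.70 keV (the overlap region) and
  12.40-12.85 keV (Pb L-beta), the published final windows. Window bounds
  are closed intervals on channel-centre energies, so the feature count is
  reproducible for any grid. At the default 0.01 keV channel width this
  gives 36 + 46 = 82 features. No uniform channel width reproduces the
  "101 channels" sometimes quoted for these windows, so the channel width
  is a configuration parameter rather than something to force.
* **Seeds**: a master seed plus deterministic per-(standard, pellet,
  repeat) sub-seeds, so any single acquisition is reproducible in
  isolation and whole simulated datasets are byte-identical across reruns.

What the simulator deliberately does **not** model: matrix
absorption/enhancement effects, secondary fluorescence, pile-up and escape
peaks, detector dead time, energy-calibration drift, and chemical
speciation. Passing tests on simulated data therefore demonstrate that the
calibration machinery recovers known parameters under Poisson counting
noise, spectral overlap and untracked background variation -- not that it
would survive every artefact of a physical instrument.

## The network and its training recipe

The calibration model is a fully connected network
(82 -> 256 -> 128 -> 2 by default) with ReLU activations and dropout
(p = 0.1) on the hidden layers. The nine replicate spectra of a standard
enter *unaveraged*, so the model trains on within-standard as well as
between-standard variability. Training is full-batch Adam at learning rate
1e-5 for 10,000 epochs with the joint RMSE over both outputs (in ug/kg) as
the loss; every 500 epochs the model is evaluated, dropout disabled, on an
independent test table -- the simulated validation set, never a random
split of the training standards -- and the state with the lowest test RMSE
is kept (best-model checkpointing as early stopping). Runs are
bit-reproducible from the training seed, which controls both the fan-in
uniform weight initialization and the dropout masks.

**Input and target scaling.** Features are standardized per channel using
training-set statistics. The package additionally standardizes the targets
per element (and inverse-transforms predictions back to ug/kg). This is a
deliberate design choice with a numerical argument behind it: Adam's
per-step displacement is bounded by roughly the learning rate, so 10,000
steps at 1e-5 move any single weight by at most ~0.1. A network asked to
emit raw outputs of order 600 ug/kg from standardized inputs cannot get
there within the epoch budget; with targets on unit scale the same recipe
converges comfortably. All logged and reported errors remain in ug/kg.

**Outlier screening.** After a preliminary fit, each standard's residual
(per-standard mean prediction minus known value, per element) is divided by
the standard deviation of all residuals for that element; standards with
|z| > 2.5 on either element are excluded and the model is retrained once on
the remainder. Two conventions are worth flagging. First, the numerator is
*not* mean-centred -- the screening rule divides the raw residual by the
residual spread, which is unusual (a systematic bias shared by all
standards inflates every |z|) but is implemented literally because it is
the published rule. Second, the screen runs exactly one cycle; it is not
iterated to convergence. The spread uses the sample (n-1) divisor
throughout, consistent with the replicate-summary convention.

## Method-performance statistics

* **Calibration metrics** (`calibration_metrics()`): the R-squared of the
  predicted-versus-actual regression (squared Pearson correlation, as read
  off a calibration plot), the standard error of calibration
  $\mathrm{SEC} = \sqrt{\sum (\hat x - x)^2 / (N - 1)}$ over per-standard
  mean predictions (the divisor is configurable via `ddof` since
  conventions differ), the SEC relative to an explicitly supplied working
  range, and the OLS slope/intercept.
* **Detection limits** (`detection_limits()`): the Eurachem replicate
  formulas $\mathrm{LOD} = 3 s_0/\sqrt{n}$ and
  $\mathrm{LOQ} = k_Q\, s_0/\sqrt{n}$ with $s_0$ the sample SD of ten
  per-standard mean predictions and $k_Q = 10$ (IUPAC default,
  corresponding to a 10 % RSD requirement). `n` defaults to 3: the
  published limit values are arithmetically consistent with averaging over
  three pellets, not the nine individual spectra, and the parameter is
  exposed precisely because that convention is a choice. LOQ/LOD equals
  $k_Q/3$ identically.
* **Bias**: mean prediction minus known value, absolute and percent.
* **Agreement** (`assess_agreement()`): a determination agrees when its
  percent error lies within +/-20 % (the regulatory verification band).
  When the reference value sits below the applicable LOQ, percent error is
  not quantitatively meaningful; the record then reports the absolute error
  in ug/kg and leaves the agreement flag undefined, and
  `category_summary()` switches that element-category cell to absolute
  errors -- the published convention for trace-Pb samples. Medians of
  even-sized sets are midpoint averages.
* **Recovery R-squared** (`recovery_r2()`): $1 - SS_{res}/SS_{tot}$, the
  predictive coefficient of determination. Unlike the correlation-based
  calibration R-squared, it penalizes bias and slope compression, which is
  exactly the Pb failure mode of interest; it is the metric used for
  held-out parameter-recovery comparisons.

## Study designs built into the generator

* **Calibration**: 28 standards on two rice units (intrinsic As
  137.37/87.82, Pb 4.26/3.19 ug/kg) -- an As-only ladder to 608.57 ug/kg,
  a Pb-only ladder to 586.27 ug/kg, and a crossed mixed block -- each as 3
  pellets x 3 repeats = 252 spectra.
* **Limit scenarios**: ten standards at 128.97 ug/kg total As with Pb
  either at the intrinsic trace level (scenario 1) or at 208.95 ug/kg
  (scenario 2), probing precision with and without overlap interference.
* **Validation**: one certified reference material (263.63 ug/kg As),
  eleven commercial rice products (56.84-296.72 ug/kg As, trace Pb), and
  twelve Pb-spiked points (four matrices x three Pb levels, ~75-400
  ug/kg), mirroring the published validation panel.
* **Probe** (`probe_design()`): a 4 x 4 crossed grid using the *same* four
  totals (100, 260, 420, 580 ug/kg) for both elements. Comparing recovery
  between elements requires matched levels; the validation panel cannot
  serve because its Pb spread (bimodal, 0-417) is much wider than its As
  spread (57-297), which mechanically flatters Pb. The common levels sit
  inside both elements' training support -- As cannot be probed below
  ~88 ug/kg because rice always carries intrinsic As, so levels start at
  100.

## Problem sizes and numerical choices

The test suite exercises the full recipe (82 features, 256/128 hidden
units, 10,000 epochs, 252 training spectra) in the acceptance checks and
scaled-down versions (16/8 hidden units, a few hundred epochs, a handful of
standards) everywhere a property does not depend on scale. A full training
pass takes on the order of two minutes in plain R matrix code on one core;
the two-pass calibration procedure roughly twice that.

Degenerate inputs are contracts, not surprises: empty windows, mixed energy
grids, negative counts, zero residual spread, all-excluded calibrations and
non-finite losses raise classed conditions. Net counts after background
subtraction are never clamped at zero -- clamping would bias exactly the
low-signal channels the network must learn from. Ties in checkpointing
resolve to the earliest evaluated epoch.

## Known limitations

* The simulator's clean physics makes calibration metrics on synthetic data
  (R-squared near 1, SEC of a few ug/kg) far better than anything a real
  instrument yields; published real-spectrum figures (As R-squared 0.92,
  SEC 41.2 ug/kg) are not reproducible without the raw spectra, and the
  package makes no attempt to imitate them. Detection limits, by contrast,
  land in the same range as the published ones because they are driven by
  replicate spread at fixed concentration, which the Poisson model captures
  well.
* The As-recovers-better-than-Pb ordering holds in expectation under the
  default conditions (per-spectrum Pb errors are systematically larger, as
  the weaker effective Pb emission weight predicts), but at a single
  training seed the two predictive R-squared values are close enough that
  an individual run can tie; the comparison is a property of the ensemble
  more than of any one fit.
* The spectral windows are taken as given. The iterative window search that
  produced them is not re-implemented, and no hyperparameter search,
  cross-validation or ensembling is attempted.
* Only total element content is modelled; chemical speciation (the
  regulatory quantity for As is the inorganic fraction) is out of scope.
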