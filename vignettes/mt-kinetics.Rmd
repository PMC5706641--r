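---
title: "Saturation-transfer kinetics of cerebral ATP metabolism: models, calibrations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturation-transfer kinetics: models, calibrations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsmt)
```

# The exchange model and its estimators

`mrsmt` models the creatine kinase (CK) and ATP synthase (ATPase) reactions
as a three-pool chemical-exchange network of longitudinal ³¹P magnetization,
PCr ⇌ ATP ⇌ Pi, with forward pseudo-first-order rate constants $k_1$
(PCr→ATP) and $k_2$ (Pi→ATP).  Reverse rates are never free parameters:
they follow from flux balance at equilibrium
($k_{-1} M^0_{PCr} = k_1 M^0_{ATP}$ and likewise for $k_{-2}$), so
`exchange_network()` derives them.  The full coupled system is linear,
$\dot M = A M + b$, and `evolve_network()` solves it exactly by
eigendecomposition — there is no step-size error to tune, and the solver
doubles as the independent oracle for the closed forms.

Under continuous saturation of γ-ATP ($M_{ATP} \equiv 0$) the partner pools
decouple and each decays mono-exponentially,

$$\frac{M(t_{sat})}{M^0} = \frac{k}{R_{app}} e^{-R_{app} t_{sat}}
  + \frac{1}{R_{app} T_1^{int}}, \qquad R_{app} = k + \frac{1}{T_1^{int}},$$

implemented in `progressive_signal()`.  Two estimators invert this model:

* **Progressive saturation** (`fit_progressive()`): areas measured on the
  seven-point grid $t_{sat}$ = 0, 565, 1058, 2045, 3032, 5005, 8295 ms are
  normalized to the $t_{sat}=0$ reference and fitted for $(k, T_1^{int})$ by
  bounded nonlinear least squares ($k \in [0,5]$ 1/s,
  $T_1^{int} \in [0.1, 20]$ s) with a deterministic three-point multi-start,
  lowest residual winning.  The bounds and multi-start matter because the
  model is weakly identifiable for Pi at realistic noise; a series with no
  detectable transfer is returned with `t1_identifiable = FALSE` rather than
  an arbitrary $T_1$.
* **Steady-state saturation** (`steady_state_rate()`):
  $k = (M^0 - M^\infty) / (M^\infty T_1^{int})$, with $T_1^{int}$ supplied
  from the resting progressive experiment and assumed unchanged during
  activation.  Negative estimates (noise pushing $M^\infty > M^0$) are
  *retained and flagged*, not clipped — clipping would bias group means
  upward at low SNR.

Derived physiology: concentrations from area ratios with an assumed
[ATP] = 3 mM; fluxes $F = k \cdot [\mathrm{substrate}]$ in mM/s and, with a
brain tissue density of 1.1 g/mL, in µmol/g/min (mM ≡ µmol/mL, so the
conversion is $\times 60 / 1.1$); intracellular pH from the Pi–PCr shift
difference (below); and an oxidative-phosphorylation cross-check
$F_{ATP} = \mathrm{CMRO_2} \times (P{:}O_2)$ with a default P:O₂ of 6.

A documented inconsistency: published baseline values give the forward
ATPase flux as $k_2 \times [Pi] = 0.15 \times 1.6 = 0.24$ mM/s, equivalent
to 13.1 µmol/g/min, which matches the mass-specific value usually quoted
(≈13.2) but not the mM/s value sometimes printed alongside it (2.4 — a
factor of 10 off its own unit conversion).  `mrsmt` follows the arithmetic.

## pH calibration

The pH-sensitive quantity is the chemical-shift difference $\delta$ between
Pi and PCr.  `ph_from_shift()` applies the Henderson–Hasselbalch form
$pH = pK_a + \log_{10}[(\delta - \delta_{acid})/(\delta_{base} - \delta)]$
with defaults $pK_a = 6.77$, $\delta_{acid} = 3.29$ ppm,
$\delta_{base} = 5.68$ ppm — the classical in vivo Pi titration against the
PCr reference.  The source protocol cites but does not print its
calibration, so these constants are a package choice: they are exposed as an
argument everywhere, echoed into every JSON report, and at $\delta$ = 4.79 ppm
they reproduce the expected resting pH of ≈7.0.  Shifts outside the open
interval $(\delta_{acid}, \delta_{base})$ are an error, not an
extrapolation.

# The synthetic world

The generator module states one concrete world and keeps it fixed; it is the
package's ground truth for validation, not a tuning surface.

**Spectrum.** Ten metabolites as twelve Lorentzian lines (`default_components()`),
at standard in vivo shifts relative to PCr = 0 ppm: PE +6.78, PC +6.24,
Pi +4.80 (placed on the pH titration curve, so generated spectra carry a
known pH), GPE +3.50, GPC +2.94, a broad membrane-phospholipid component at
+2.06, PCr 0.00, γ-ATP −2.50 and α-ATP −7.52 as 16-Hz J-coupled doublets
with equal line amplitudes and linewidths, NAD(H) −8.30.  Default areas put
γ-ATP at 1 with PCr/γ-ATP = 1.22, Pi/γ-ATP = 0.540, NAD(H)/γ-ATP = 0.157 —
the resting-state ratios.  The chemical-shift-anisotropy baseline is one
very broad Lorentzian (FWHM 800 Hz) suppressed to 15% of its area by *any*
off-resonance irradiation, mirroring the experimental strategy of
irradiating at +15 ppm in reference scans so saturated and unsaturated
spectra share a baseline.

**Acquisition.** 51.7 MHz (³¹P at 3 T, fixing the ppm↔Hz conversion),
3000 Hz bandwidth, 4096 complex points, TR 12 s, 24 averages, 15 Hz
apodization.  Circular Gaussian noise enters with sd
`noise_sd`/√n_averages per channel.  The saturation times of the published
schedule are taken from an explicit lookup, not computed as
n_pulses × (duration + gap): the printed grid implies a per-train overhead
the simple product does not reproduce, and the timing arithmetic is not
documented anywhere we could follow.

**Noise calibration.** The published Monte Carlo noise variance is described
only as "similar to in vivo"; the package default is **1.5% of the PCr
Boltzmann area per 24-average spectrum, with every area in a spectrum
carrying the same absolute sd** (PCr and Pi live in the same spectrum, so
the smaller Pi peak has proportionally larger relative noise).  This level
reproduces the reported CV of the steady-state $k_1$ (≈6.6–7%); it yields a
$k_2$ CV of ≈17–19% against a reported ≈23–24%, which would require a
Pi-to-PCr noise ratio larger than the area ratios imply — the exact
replicate-level variance is unknowable from the published numbers, so the
Monte Carlo acceptance checks are property-based (orderings and
invariances), not digit matching.

**Functional studies.** Four blocks OFF1, ON1, OFF2, ON2 per subject.
Between-subject baselines: $k_1 \sim N(0.35, 0.04)$,
$k_2 \sim N(0.15, 0.03)$ 1/s; stimulation multiplies $k_1$ by 1.24 (cycle 1)
and 1.11 (cycle 2) and $k_2$ by the observed trends 1.21/1.12.
Block-to-block physiological jitter is sd 0.01 1/s for $k_1$ and 0.07 1/s
for $k_2$; the $k_2$ value is calibrated so the simulated per-block spread
across subjects (≈0.08 1/s) sits mid-range of the in vivo block standard
deviations (0.05–0.10 1/s), which are far larger than thermal noise alone.
That physiological variance is what makes the ~20% $k_2$ trend statistically
undetectable in a 9-subject paired design, exactly as observed in vivo,
while the $k_1$ effect remains highly significant.  pH truth is 7.0 with
0.01 ppm shift noise (≈0.02 pH units).

**What a green test does and does not establish.** The generator shares the
saturation physics with the estimators (that closure is itself a tested
invariant), so recovery tests validate the inference machinery, fit
robustness and the statistics — not the biology.  Real data add baseline
imperfections, frequency drift, lineshape departures from Lorentzian,
incomplete γ-ATP saturation, and extracellular Pi contamination, none of
which are in the simulated world.

# Spectral fitting

`fit_components()` is a prior-knowledge constrained time-domain fit in the
spirit of AMARES, not a re-implementation of it: per-component shift and
linewidth plus one global zero-order phase are optimized by bounded
quasi-Newton iterations, while areas are solved exactly by linear least
squares at every step (variable projection).  Design choices:

* **Constraint windows** (unpublished in the source protocol, so package
  defaults, surfaced in `fit_model_definition()`): shifts within ±0.2 ppm
  of the prior with a weak quadratic pull toward it; linewidths bounded to
  2–20 Hz for narrow metabolites, 20–200 Hz for the broad phospholipid
  component, 300–1500 Hz for the baseline.
* **Doublets are hard links**: 16 Hz separation, shared amplitude and
  linewidth, one area coefficient — the linkage cannot drift, it is
  structural.
* **Apodization lives in the model.** The basis uses the physical linewidth
  plus whatever exponential broadening `apodize()` recorded, so fitted
  linewidths always refer to the pre-apodization spectrum and areas are
  invariant under 0–15 Hz apodization.  (Without this, 15 Hz broadening
  pushes a 7-Hz line past the 20-Hz prior bound and biases areas by ~7%.)
* **Determinism**: three fixed starts (priors; broadened/upfield;
  narrowed/downfield), best penalized residual wins, ties to the first; a
  numerically perfect first fit skips the restarts.
* **Numerics**: the FID is truncated to 512 points for fitting (an apodized
  ³¹P FID has decayed to noise well before that), and the frequency-domain
  path is exact — spectra are transformed back to the time domain
  analytically, so fitting a spectrum equals fitting its FID.
* The spectrum convention is `2·fft(FID with first point halved)/bandwidth`:
  the halving removes the DC offset a sampled decay otherwise spreads across
  the spectrum, and the factor 2 makes the full-spectrum real integral equal
  the generating amplitude exactly.

`quality_control()` applies the acquisition rules: residual γ-ATP under
saturation ≤7% of the unsaturated reference, pre-apodization PCr linewidth
in 2–20 Hz, noise floor from the fit residual.  It reports; it does not
throw.

# Error analysis

`mc_t1_recovery()` replicates the progressive experiment (default 1000
replicates) with noise added at the curve level — matching the published
simulation design, which perturbed the modelled signal curves, not raw FIDs
(spectral-level noise is available through the generator's `spectra` mode
for end-to-end runs).  Replicate fits reuse `fit_progressive()` with
identical bounds and starts, so no method variance contaminates the spread.
`mc_rate_sensitivity()` replicates the two-point ($t_{sat}$ = 0, 10 s)
steady-state design across assumed relative errors in $T_1^{int}$ (0, 20,
40%); since the estimator scales as $1/T_1^{int}$, a T₁ error biases the
mean by exactly $1/(1+\epsilon)$ while leaving the CV essentially unchanged
— the insensitivity that justifies using resting T₁ values during
activation.  Noise draws are independent per error level, so the CV
invariance is an empirical outcome, not an algebraic identity.  The truth
defaults follow the published simulation setup ($T_1$ = 5/3 s, $k$ =
0.3/0.2 1/s); note the same source elsewhere prints 5.1 s as the "true"
PCr value — the truth is a parameter here, so either is one argument away.

`partial_saturation_bias()` quantifies the finite-TR artefact: each
acquisition cycle is simulated to its cyclic steady state (saturate
$t_{sat}$ with ATP clamped → excite, zeroing longitudinal magnetization →
recover $TR - t_{sat}$ with free three-pool exchange), and the measured
$M(t_{sat})/M^0$ ratio is compared with the fully relaxed ideal.  With
TR = 12 s and $t_{sat}$ = 10 s this world gives scan attenuations of ≈1.2%
(PCr) and ≈0.7% (Pi) and a ratio deviation of ≈0.3–0.4% — the same sign
(rates underestimated) and order as the ≈3%/≈1% quoted from an external
partial-saturation model whose cycle details are unpublished; exchange with
the fast-relaxing ATP pool (T₁ assumed 1.0 s) accelerates PCr recovery and
shrinks the deficit relative to an isolated-pool picture.  The check is an
order-of-magnitude one by construction.

# The saturation pulse train

`simulate_saturation_profile()` integrates the Bloch equations (rotation
operators, 400 steps per pulse) for a single spin through the train of
sech-envelope pulses (B₁max 2.06 µT, 114.29 ms each) with ideal crushers
between pulses.  The envelope truncation β is the one unpublished shape
parameter; the default β = 6.95 was calibrated once so that a 3-s
(18-pulse) train yields a saturation band of 32 Hz FWHM and 65 Hz full
width at 5% of maximum — against the published 31/69 Hz — with 93%
on-resonance saturation after 3 s and bleed-over at ±2.5 ppm (±129 Hz) of
order 10⁻⁶, the negligible-bleed-over condition that justifies reading the
PCr signal loss as pure exchange.  β is an argument for anyone wanting a
different trade-off.

# Statistics

`block_statistics()` computes, per contrast, the subject-wise percent change
(per subject first, then mean ± sd — the convention behind "24% ± 14%"
style reporting, which differs from the ratio of group means) and a
two-sided paired t-test on the block values; multi-block sides (the pooled
ON vs OFF contrast) are averaged within subject before differencing.
Subjects with a zero reference value are excluded with a warning.  Five
contrasts are evaluated (ON1/OFF1, ON2/OFF2, OFF2/OFF1, ON2/ON1, pooled
ON/OFF) with no multiplicity correction by default, mirroring the original
analysis; `holm = TRUE` adds Holm-adjusted p-values for reuse.  Degenerate
inputs are defined, not special-cased away: identical paired columns give
0% change with p = 1.

The progressive study fits the group-averaged normalized series (the
published approach — whether averaging preceded fitting is ambiguous in the
source, so per-subject fits are returned alongside, and the two coincide at
n = 1).

# Numerical and degenerate-input policy

* All randomness in a top-level generator call flows through one seed;
  identical seeds give bit-identical outputs.
* The ODE solver refuses non-positive T₁ and non-finite initial states;
  closed-form/ODE agreement is tested to 10⁻⁶ relative over
  $t_{sat} \in [0, 20]$ s.
* Fits that fail from every start raise an error carrying the context;
  Monte Carlo replicates that fail are counted and excluded from moments.
* Text round trips (FID, spectrum, MT-series tables) are bit-exact: numbers
  are written with 17 significant digits.

# Known limitations

* No inversion-transfer or 2D exchange modelling; no transverse-magnetization
  dynamics inside the kinetic estimators (the saturation Bloch simulation is
  a separate, single-spin tool).
* The spectral model is strictly Lorentzian with a single global zero-order
  phase (near-FID acquisition, first-order phase fixed at zero); no
  lineshape distortions, no eddy-current artefacts.
* Intra/extracellular Pi are not resolved — at 3 T they are not resolvable —
  so simulated $k_2$ refers to the total Pi pool, with the same
  underestimation caveat as the in vivo measurement.
* The in-vivo headline numbers themselves (k₁ = 0.35 ± 0.04 1/s, T₁ =
  5.1/3.0 s, pH 6.99) are inputs to the generator, not quantities the
  package can re-derive without the unavailable raw data.
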