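---
title: "Monitoring heart-valve function with a one-class SVM baseline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring heart-valve function with a one-class SVM baseline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowmci)
```

## The problem and the model

A replacement heart valve — in particular a bioprosthetic aortic valve —
has limited durability, and its most common failure modes (above all
aortic regurgitation, an incomplete diastolic closure that lets blood
reflux into the ventricle) express themselves in the shape of the
volumetric flow-rate waveform just downstream of the valve. `flowmci`
monitors that waveform against a *patient-specific* baseline rather than
against population reference data: flow recorded while the valve is known
healthy defines a statistical model of normal behaviour, and later
recordings are scored by how much of their data that model still claims.

Because valve degradation is progressive and essentially unidirectional,
it is enough to detect *novelty* — departure from the baseline
distribution — without knowing the pathology in advance. The package
therefore uses a one-class SVM, an unsupervised novelty detector: training
data `x₁…x_l` is separated from the origin in a Gaussian-kernel feature
space by a hyperplane with weight vector ω and offset ρ, and the signed
decision value of a new sample is `f(x) = Σᵢ αᵢ k(xᵢ, x) − ρ` with
`k(x, y) = exp(−γ‖x−y‖²)`. The dual coefficients solve

    min_α ½ Σᵢⱼ αᵢαⱼ k(xᵢ, xⱼ)  s.t.  0 ≤ αᵢ ≤ 1/(νl),  Σᵢ αᵢ = 1.

The scalar reported for each recording is the **Model Compliance Index**,
`MCI = N_inliers/N_samples`, the fraction of the recording's samples on
the positive side of the decision boundary. Perfect agreement with the
baseline yields an MCI near the training score; degradation shows as a
declining MCI. The MCI deliberately carries no pathology label: it flags
*that* behaviour changed, not *what* changed.

## Feature construction

A recording is a uniformly sampled multi-beat series (defaults mirror an
in-vitro flow rig: 1000 samples at 60 Hz, about 16 beats at 60 BPM). The
preprocessing chain is per-recording and deterministic:

1. **Sinusoid fit.** `A sin(2πft + φ) + b` is fitted by a
   Levenberg–Marquardt iteration. The sinusoid is knowingly a bad model of
   the waveform; it is used only because its `f` and `φ` are robust
   estimates of the cardiac base frequency and phase.
2. **Phase condensation.** Samples are mapped onto one cycle by
   `τ = (t − t₀) mod T`, `T = 1/f`, with `t₀` the first *minimum* of the
   fitted sinusoid. All samples are retained.
3. **Standardization.** Each axis — `Z₁` phase, `Z₂` flow, optionally `Z₃`
   heart rate — is z-scored; the SVM is not scale-invariant.

### Choices made where the design was open

* **Slicing anchor.** Extrema of the sinusoid mark cycle boundaries; the
  package anchors at *minima* (the flow minimum, near end-diastole) as its
  single fixed convention. Anchoring at maxima would only shift the τ
  origin; since training and scoring share the convention, results are
  unchanged. The constant is recorded in every feature matrix and model
  (`anchor`).
* **Per-recording scalers.** Each recording — baseline and monitoring
  alike — is standardized by its own mean and σ. Preprocessing is thus
  fully self-contained per recording; the alternative (freezing the
  baseline scaler and applying it to later recordings) is available via
  the `scaler` argument of `standardize()` for sensitivity studies. With
  per-recording scaling a change in the waveform alters *where samples
  fall* after normalization, which is exactly what the detector consumes.
* **σ convention.** Population standard deviation (divide by *n*). It is
  the convention under which two equally frequent values standardize to
  exactly ±1, and the one used by mainstream ML scalers.
* **Phase as a linear axis.** `Z₁` enters as a plain bounded feature, not
  a circular variable; the wrap-around at τ = 0/T is accepted. The
  decision boundary simply closes around both ends of the cloud.
* **Heart rate (`Z₃`).** Constant within a recording, so it cannot be
  z-scored per recording; `pool_features()` standardizes it across the
  pooled training recordings instead. At constant pump/heart rate the axis
  is degenerate and the package refuses it — use the 2-feature layout,
  which is the default.
* **Frequency initialization.** `f₀` comes from the dominant peak of a
  *Hann-windowed* spectrum. With a rectangular window, spectral leakage on
  non-bin-aligned periods can let a bin-aligned harmonic of the
  pulse-train-like waveform overtake the fundamental; the Hann window's
  smaller scalloping loss removes that failure mode. The LM fit restarts
  at four initial phases (0, π/2, π, 3π/2) and keeps the lowest residual,
  escaping the phase local minima of sinusoid fitting.

## Training the baseline

`ocsvm_train()` solves the dual with a pairwise (SMO-style) working-set
method written for this package — the equality constraint makes pairs the
minimal working set. The pair with maximal first-order KKT violation is
updated analytically and clipped to the box; convergence is declared when
the maximal violation drops below `tol` (default 1e−6). The kernel matrix
is dense; at the intended scale (l ≈ 10⁴: ten pooled recordings) training
takes tens of seconds and ~800 MB.

* **Bias ρ.** At the optimum every margin support vector (0 < αᵢ < 1/(νl)
  strictly) satisfies `Σⱼ αⱼ k(xⱼ, xᵢ) = ρ`; ρ is the mean of that
  quantity over margin SVs identified inside a numerical guard band, with
  a KKT-interval midpoint fallback when no margin SV exists.
* **Hyperparameters.** ν budgets boundary violations (ν-property:
  training outlier fraction ≤ ν, support-vector fraction ≥ ν); γ sets the
  kernel radius — large γ resolves steep waveform gradients but risks an
  irregular, overfitted boundary, small γ over-regularizes. The working
  default ν = 0.05, γ = 7 gives a training score of ≈ 0.95 on the
  synthetic baseline, and `grid_search()` reproduces its optimality over
  ν ∈ {0.01, 0.05, 0.1, 0.2} × γ ∈ {0.1, 1, 7, 20, 100}, scored by the
  mean MCI separation between baseline and degraded recordings.
* **Boundary tie rule.** A decision value of exactly zero counts as
  inlier. In finite precision a margin SV's decision value is noise of
  magnitude ≈ `tol` around zero, so the rule is applied with that
  tolerance as a guard band (`inlier ⇔ f(x) ≥ −tol`). Without the band,
  roughly half the margin SVs would flip to outliers on numerical noise —
  catastrophically so in degenerate regimes (γ so large the kernel matrix
  is near-diagonal) where *every* point is a margin SV.

## The simulator: a stated world

`generate_recording()` stands in for an in-vitro pulsatile flow loop
driven by a computer-controlled piston pump. Per cycle it emits:

* a **half-sine systolic ejection** over a fraction `systolic_fraction`
  (default 0.35) of the cycle, its amplitude normalized so the leak-free
  cycle mean equals the configured cardiac output (default 5 l/min at
  60 BPM, i.e. mean 83.3 ml/s, peak ≈ 374 ml/s);
* a brief **closure-reflux dip** — a negative half-sine over 8% of the
  cycle carrying `closure_reflux_volume` (default 3 ml, a few percent of
  the ~83 ml stroke volume, at the physiological scale of aortic valve
  closure backflow);
* a constant **diastolic leak** `−C_d·A·√(2ΔP/ρ_blood)` (orifice
  equation, ρ_blood = 1060 kg/m³, ΔP = diastolic pressure, default
  80 mmHg). The three in-vitro insert areas 10.0/31.4/99.4 mm² give leak
  magnitudes 26.9/84.5/267.5 ml/s;
* additive Gaussian sensor noise (`noise_sd`, default 5 ml/s ≈ 1.3% of
  peak flow — a realistic magnitude for a clamp-on magnetic flow probe)
  and optional affine ADC quantization;
* optional cycle-period jitter, default **zero**: a piston-pump rig shows
  no appreciable cycle-to-cycle variability. The parameter exists for
  robustness experiments only.

What the simulator does *not* emulate: pressure dynamics, leaflet
mechanics, flow turbulence, beat-to-beat physiological variability,
sensor drift, or the specific (unpublished) waveform shape of any real
rig. A green synthetic test therefore establishes that the pipeline
*detects graded diastolic leaks against its own baseline under noise* —
it does not certify performance on clinical data, and the package's
decision thresholds have no claimed diagnostic meaning. The published
in-vitro severity ladder (median MCI 0.95 → 0.72 → 0.4 → 0.17) can only be
reproduced exactly from the original measurement datasets, which this
offline build does not ship; the synthetic ladder (≈ 0.95 → 0.83 → 0.42 →
0.24 at the default noise level) reproduces the qualitative structure —
monotone, sharply separated, significant at the 1% level.

## Statistics

* **Summaries.** Median and IQR over the per-recording MCIs of a
  scenario, with linear interpolation between order statistics (type-7
  quantiles). Reported MCIs are quoted to ≤ 2 decimals, so the percentile
  convention is below reporting precision.
* **Scenario comparison.** One-sided Wilcoxon rank-sum. Exact
  distribution for combined n ≤ 20 without ties (at the package's scale,
  8–10 recordings per scenario, full separation gives p = 1/12870);
  tie-corrected normal approximation otherwise. Note that two fully
  separated samples of size 4 give p = 1/70 ≈ 0.014 — the strongest
  evidence that sample size can produce, and *not* significant at 1%.
* **Monitoring.** `monitor_mci()` returns the MCI series in recording
  order plus an ordinary least-squares slope; a persistent negative slope
  is the degradation signal.

## Numerical notes and limitations

* SMO convergence tolerance 1e−6 (maximal KKT violation); duplicate
  training rows make the pair curvature vanish and are handled by a
  maximal clipped step.
* Model JSON is written with 17 significant digits so reloaded models
  reproduce predictions bit-identically.
* The LM fit declares non-convergence (classed error) rather than
  returning a silent bad fit; constant recordings (zero amplitude,
  undefined phase) are rejected.
* MCI resolution is 1/N_samples (0.001 at the default recording length);
  differences below that are not meaningful.
* With per-recording standardization, a pathology that changed the
  waveform *uniformly* (pure gain/offset) would be invisible — z-scores
  are affine-invariant per axis. Physiological degradations change the
  waveform *shape*, which is what the detector sees; monitoring with a
  frozen baseline scaler is the available alternative if absolute levels
  are trusted.
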