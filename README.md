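# flowmci

Automated monitoring of (bio)prosthetic heart-valve function from pulsatile
blood-flow recordings.

Bioprosthetic aortic valves degrade — often through aortic regurgitation
(AR), where the leaflets fail to close and blood refluxes during diastole —
and they usually do so faster than the patient's life expectancy. `flowmci`
implements an unsupervised monitoring pipeline for this setting: a
patient-specific statistical baseline of the *healthy* valve is learned from
flow recordings taken shortly after implantation, and every later recording
is scored against that baseline. No labeled reference data and no external
valve database are needed; any systematic deviation from the patient's own
baseline is treated as evidence of degradation.

## The method

1. **Preprocessing.** A multi-beat recording of volumetric flow rate
   `q(t)` (≈16 cardiac cycles at 60 Hz) is condensed onto a single cycle.
   A sinusoid `A sin(2πft + φ) + b` is fitted by Levenberg–Marquardt
   iteration — a poor model of the waveform, but a robust estimator of its
   base frequency and phase. Slicing at the fitted sinusoid's minima maps
   every sample to its cycle phase `τ = t mod T`, `T = 1/f`. Each feature
   axis — phase `Z₁`, instantaneous flow `Z₂`, optionally heart rate `Z₃` —
   is z-scored (`Z = (X − X̄)/σ`), because the SVM below is not
   scale-invariant.

2. **Baseline model.** A one-class SVM with Gaussian kernel
   `k(x, y) = exp(−γ‖x − y‖²)` learns the region of feature space the
   healthy valve occupies. The dual problem

       min_α ½ Σᵢⱼ αᵢαⱼ k(xᵢ, xⱼ)   s.t.  0 ≤ αᵢ ≤ 1/(νl),  Σᵢ αᵢ = 1

   is solved from scratch by an SMO-style pairwise working-set method
   (compiled, `src/smo.cpp`). `ν` budgets boundary violations: it
   upper-bounds the training outlier fraction and lower-bounds the
   support-vector fraction (the ν-property). The decision function is
   `f(x) = Σᵢ αᵢ k(xᵢ, x) − ρ`, positive inside the baseline region.

3. **Model Compliance Index.** A new recording's score is
   `MCI = N_inliers / N_samples` — the fraction of its samples inside the
   decision boundary. A healthy valve scores near the training score
   (≈ 1 − ν); progressive degradation shows as a declining MCI.

4. **Diagnostics.** Scenario summaries (median MCI + IQR), a `(ν, γ)`
   grid search scored by the mean baseline-vs-AR MCI separation, one-sided
   exact Wilcoxon rank-sum scenario comparison, and trend monitoring.

A pulsatile-flow simulator (`simulation_config()`, `generate_recording()`)
emulates the in-vitro flow loop used to validate this class of method:
5 l/min cardiac output, 60 beats/min, 120/80 mmHg, with regurgitant orifices
of 10.0 / 31.4 / 99.4 mm² (mild / moderate / severe AR) producing a
diastolic leak via the orifice equation `Q = C_d·A·√(2ΔP/ρ_blood)`. The
full pipeline is therefore testable with no external data.

## Worked example

```r
library(flowmci)

# 1. Synthesize a healthy-valve baseline: 10 recordings, 1000 samples @ 60 Hz
baseline <- generate_batch(simulation_config(leak_area = 0, seed = 1), 10)
features <- lapply(baseline, preprocess_recording)
pooled   <- pool_features(features)

# 2. Train the patient-specific one-class SVM baseline
model <- ocsvm_train(pooled, nu = 0.05, gamma = 7)
#> <ocsvm_model> nu=0.05, gamma=7, l=10000, 520 SVs, rho=0.07399, training score 0.953

# 3. Score recordings of graded aortic regurgitation
for (area in c(0, 10.0, 31.4, 99.4)) {
  cfg  <- simulation_config(leak_area = area, seed = 9000 + round(10 * area))
  mcis <- vapply(lapply(generate_batch(cfg, 8), preprocess_recording),
                 compute_mci, 0, model = model)
  print(summarize_scenario(mcis, scenario = sprintf("leak %.1f mm^2", area)))
}
#> <mci_report> leak 0.0 mm^2: median MCI 0.948 (iqr 0.005, n = 8)
#> <mci_report> leak 10.0 mm^2: median MCI 0.831 (iqr 0.011, n = 8)
#> <mci_report> leak 31.4 mm^2: median MCI 0.422 (iqr 0.013, n = 8)
#> <mci_report> leak 99.4 mm^2: median MCI 0.236 (iqr 0.002, n = 8)
```

The training score lands at `1 − ν` (0.953 for ν = 0.05): the model admits
5% boundary violations to absorb sensor noise. The no-leak scenario scores
at the training level; the median MCI then falls monotonically — 0.83, 0.42,
0.24 — as the regurgitant orifice grows, and adjacent severities separate
significantly (one-sided rank-sum, 1% level). That declining scalar is the
monitoring signal.

## Command line

```sh
Rscript inst/cli/flowmci simulate --leak-area 31.4 --seed 7 --out ar.tsv
Rscript inst/cli/flowmci preprocess --in ar.tsv --out ar.features
Rscript inst/cli/flowmci train --in b1.tsv,b2.tsv --nu 0.05 --gamma 7 \
        --model-out model.json
Rscript inst/cli/flowmci score --model model.json --in ar.tsv --out mci.json
Rscript inst/cli/flowmci gridsearch --baseline b1.tsv,b2.tsv --ar ar.tsv \
        --out grid.json
Rscript inst/cli/flowmci monitor --model model.json --in r1.tsv,r2.tsv \
        --out trend.csv
```

Exit codes distinguish input (2), configuration/validation (3) and
convergence (4) errors.

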