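# bafkit

Quantitative analysis of the biophysical assays used to study activation of
the apoptotic effector protein **BAX** by bioactive lipids (for example the
sphingosine-1-phosphate metabolite 2-*trans*-hexadecenal) in cooperation
with BH3-only proteins such as BIM. The package is written for protein
biochemists and biophysicists who run these assays on plate readers,
thermophoresis instruments, real-time PCR machines and NMR spectrometers,
and want a scripted, testable analysis instead of ad-hoc spreadsheet or
vendor-software steps.

## What it computes

* **LUV dye-release kinetics** — control-anchored normalization
  (`% = 100·(F − F₀)/(F₁₀₀ − F₀)` with F₀ the buffer-control minimum and
  F₁₀₀ the detergent-control mean), constrained fitting of the asymmetric
  five-parameter sigmoid
  `y = B + (T − B)/(1 + (E/x)^H)^S` (with T ≥ B, 0 < S ≤ 10), endpoint
  permeabilization, and the analytic **maximal rate**: the slope at the
  inflection point
  `x_IP = E·((HS − 1)/(H + 1))^(1/H)`, defined when `H·S > 1`.
* **Bliss synergy** — per-cell excess over the independence reference
  `f_A + f_B − f_A·f_B` on endpoint dose matrices, and a matrix score
  (mean combination-cell excess × 100, in percentage points).
* **FLAMBE** — milli-polarization from polarized intensities
  (`mP = 1000·(I∥ − I⊥)/(I∥ + I⊥)`), trace parameterization into
  (Tmax, EP) with a flagged no-binding rule, 0/1 control normalization,
  shift distance `Δs = √(ΔTmax² + ΔEP²)`, and normalized AUC.
* **MST** — one-phase decay fits
  `y = (Y₀ − Y_plateau)·e^(−Kx) + Y_plateau` in the 5–35 s window, the
  algebraic decay-constant inverse, temperature-jump responses, EC50 via a
  four-parameter log-logistic fit, and concentration-response slopes.
* **NMR CSP** — weighted perturbations
  `Δδ = √((Δ¹H² + 0.2·Δ¹⁵N²)/2)` from paired HSQC peak lists, proline and
  missing-assignment handling, mean + 1/2 SD significance thresholds, and
  concentration-series averaging.
* **Thermal shift** — Tm as the maximum first derivative of a melt curve,
  with smoothing, tie/boundary flags and ΔTm comparisons.
* **Synthetic data** — seeded generators for every input above with known
  ground truth, so the whole pipeline is verifiable without instrument
  data.

## Worked example

Simulate a noisy triplicate LUV plate on the raw fluorescence scale and
run the full kinetic analysis:

```r
library(bafkit)
spec <- sim_plate_spec(55, 55, 90, list(
  plate_condition("bax_bim_2t16", "sample",
                  list(b = 95, t = 455, e = 2000, h = 4, s = 1),
                  n_rep = 3, dose_a = 25, dose_b = 2.5),
  plate_condition("buffer", "buffer", list(level = 50), n_rep = 2),
  plate_condition("chaps", "detergent_max", list(level = 500), n_rep = 2)),
  noise_sd = 4, seed = 1)
fit_luv_plate(sim_luv_plate(spec))
#>      condition dose_a dose_b n_wells     b     t    e     h     s   rss x_ip
#> 1 bax_bim_2t16     25    2.5       3 12.35 90.64 2001 3.925 1.008 18.27 1758
#>   max_rate endpoint_pct converged degenerate
#> 1  0.04099        88.39      TRUE      FALSE
```

The generating trace spans raw 95–455 against controls at 50 (buffer) and
500 (detergent), i.e. 10–90% after normalization; the fit recovers the
normalized parameters (b ≈ 12, t ≈ 91, e ≈ 2000 s), places the inflection
at ≈ 1758 s and reports a maximal rate of ≈ 0.041 %/s and an endpoint of
≈ 88%. The maximal-rate statistic itself, on the textbook parameter set:

```r
maximal_rate(c(b = 0, t = 100, e = 30, h = 2, s = 1))
#> $rate  2.165064      # %/s, at
#> $x_ip  17.32051      # s  (= 30/sqrt(3))
```

Scoring an endpoint dose matrix carrying a known injected Bliss excess of
0.10 under 2% endpoint noise:

```r
dm <- sim_dose_matrix(c(0, 2^(0:6)), c(0, 2^(0:6)),
                      mono_a = seq(0.15, 0.5, length.out = 7),
                      mono_b = seq(0.15, 0.5, length.out = 7),
                      excess = 0.10, noise_sd = 0.02, seed = 42)
synergy_matrix(dm)$score
#> [1] 8.263623   # percentage points; 10 at zero noise
```

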