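---
title: "Models and methods for BAX activation assay analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for BAX activation assay analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bafkit)
```

bafkit analyzes the panel of in-vitro assays used to study how bioactive
lipid aldehydes (such as 2-trans-hexadecenal) cooperate with BH3-only
proteins to activate the apoptotic pore-former BAX. This vignette is the
package's account of the underlying models, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical and design decisions taken where the procedures
admitted more than one reasonable choice.

## LUV permeabilization kinetics

Liposome (LUV) dye-release assays report BAX pore formation as a rise in
fluorescence when encapsulated dye escapes quenching. Raw traces are
normalized to percent permeabilization by an affine map anchored on two
in-plate controls,

$$\%\;=\;100\,\frac{F - F_0}{F_{100} - F_0},$$

where $F_0$ is the **minimum** reading of the buffer control over the whole
assay and $F_{100}$ the **mean** reading of the detergent-solubilized
(1% CHAPS) control over the whole assay. Because the 100% anchor is a mean,
normalized values can exceed 100%; they are deliberately not clipped here.
Clipping to $[0,1]$ happens only when endpoint data enter synergy scoring
(`to_fraction()`, `dose_matrix()`), so the kinetic record stays faithful.

Normalized kinetics are fit with a modified five-parameter sigmoid,

$$y \;=\; B + \frac{T - B}{\bigl(1 + (E/x)^H\bigr)^S},$$

with bottom/top asymptotes $B \le T$, half-transition scale $E > 0$ (s),
steepness $H > 0$ and asymmetry $0 < S \le 10$. The fit
(`fit_5pl()`) is box-constrained Levenberg–Marquardt least squares; the
constraint $T \ge B$ is enforced structurally by fitting the non-negative
span $d = T - B$ rather than by rejecting solutions post hoc. Starting
values are $B_0 = \min y$, $T_0 = \max y$, $E_0$ the interpolated
half-rise time, $H_0 = S_0 = 1$. Two identities worth knowing: the curve
passes through $B + (T-B)/2^S$ at $x = E$ regardless of $H$, and the model
is singular at $x = 0$, so a plate-reader read at exactly $t = 0$ is
assigned the midpoint of the first read interval (configurable; the
alternative is to drop it).

When $HS > 1$ the curve has an inflection at positive time and the slope
there — the **maximal permeabilization rate** — has the closed form

$$x_{IP} = E\left(\frac{HS-1}{H+1}\right)^{1/H},\qquad
\left.\frac{dy}{dx}\right|_{x_{IP}}
 = \frac{H S (T-B)\left(\frac{H+1}{HS-1}\right)^{\frac{H+1}{H}}}
        {E\left(1+\frac{H+1}{HS-1}\right)^{S+1}}.$$

The test suite validates this closed form against an independent
finite-difference maximization of the curve's derivative over 1,000 random
parameter sets (relative agreement below $10^{-6}$). For $HS \le 1$ there
is no inflection at positive time and `maximal_rate()` refuses rather than
returning something misleading.

**Replicate handling.** Kinetic data in this field are reported as means
of technical replicates; `fit_luv_plate()` therefore averages replicate
wells per condition before fitting (per-well fitting is available via
`average_replicates = FALSE`). For homoscedastic Gaussian noise the two
orderings give the same least-squares estimate from the mean trace; the
averaged fit is simply less noisy.

### Design of the parameter-recovery study

The recovery tests simulate traces with $B=10$, $T=90$ (%), $E=3000$ s,
$H=10$, $S=0.3$ on the assay's native read schedule (90 reads at 55 s
intervals, i.e. a 90-minute kinetic run), with triplicate wells averaged
before fitting. Those defaults were chosen once, by a Cramér–Rao
identifiability analysis across realistic dye-release shapes: permeabilization
kinetics show a lag, a fast rise and a slow creep toward plateau, which in
this parameterization corresponds to large $H$ with $S < 1$, and that
regime is also where all five parameters are simultaneously identifiable.
The analysis also shows the limits of the design: at noise SD equal to 2%
of the span, the asymmetry exponent's sampling error sits essentially at
the information bound (median absolute relative error ≈ 5%), so recovery
of $S$ to much better than 5% is not achievable from a single 90-point
triplicate run regardless of fitting software. A flat-$B$ curve with
$B = 0$ would make *relative* error on $B$ undefined, which is why the
recovery truth uses a non-zero baseline.

## Bliss synergy scoring

Endpoint permeabilization over a two-compound titration forms a dose
matrix whose first row/column are the monotherapy margins. Each
combination cell is compared with the Bliss independence expectation of
its own margins, $e = f_A + f_B - f_A f_B$, and the matrix score is the
mean excess over all combination cells, in percentage points. The plain
Bliss reference model is implemented; web tools used for synergy heatmaps
apply additional smoothing/curve-fitting corrections they do not fully
document, so scores here are comparable in sign and ordering but not
guaranteed numerically identical to such tools. The score is invariant
under compound relabeling and under appending pure-vehicle rows/columns,
and an injected constant excess is recovered exactly at zero noise — the
property the acceptance tests exercise.

## FLAMBE polarization parameterization

FLAMBE monitors early BAX activation through the polarization of a
TAMRA-labeled BAK-BH3 peptide: association raises polarization,
activation-induced dissociation lowers it. Polarization is computed from
polarized intensities as $mP = 1000\,(I_\parallel - I_\perp)/(I_\parallel
+ I_\perp)$, bounded in $[-1000, 1000]$ and scale-invariant.

Traces are summarized non-parametrically by **Tmax** (time of maximum
polarization) and **EP** (endpoint polarization), computed on
replicate-averaged traces. A trace with no binding kinetics would
otherwise get a Tmax dictated by noise, so the field's convention sets
Tmax to 0 for such traces. "No binding kinetics" is not quantitatively
defined in the literature; the rule implemented is: rise amplitude less
than 10% (configurable) of the protein-control rise amplitude, or no rise
at all, triggers Tmax := 0, and the decision is always reported in a
`no_binding` flag so it can be audited.

Metrics are normalized per axis so the free-ligand control maps to 0 and
the vehicle-treated protein control to 1, and treatment effects are
summarized by the Euclidean shift distance
$\Delta s = \sqrt{(\Delta Tmax)^2 + (\Delta EP)^2}$ between conditions
without and with activator. Whether Tmax is measured in seconds or cycle
index is immaterial on a uniform grid (the normalization cancels the
units); seconds are used. AUC is trapezoidal and normalized with the same
0/1 control convention as the other metrics — the convention itself is a
package decision, chosen for internal consistency, since "normalized to
the controls" admits several affine variants.

The synthetic generator's rise–decay model
$P(t) = P_{free} + A(1-e^{-k_a t})e^{-k_d t}$ is *not* a mechanistic claim
about FLAMBE kinetics (the analysis never fits it); it exists to produce
traces with a controllable analytic peak time $\ln(1+k_a/k_d)/k_a$ and
endpoint, which is exactly what the parameterization tests need.

## MST decay and concentration response

Thermophoresis timetraces are fit with a one-phase decay
$y = (Y_0 - Y_{plateau})e^{-Kx} + Y_{plateau}$ restricted to the 5–35 s
window after IR-on (the standard window that skips the temperature-jump
transient), and the decay constant can be recovered from any single model
point by the algebraic inverse
$K = -\ln\bigl((y - Y_{plateau})/(Y_0 - Y_{plateau})\bigr)/x$. The inverse
is exact in real arithmetic; in double precision it degrades once
$e^{-Kx}$ falls near the rounding floor of the plateau offset, so the
property tests exercise the physically relevant range
($K \le 0.3\,\mathrm{s^{-1}}$ in the window).

Temperature-jump responses are window-mean differences (defaults −1–0 s
and 0.5–1.5 s around IR-on, configurable because instrument timing
varies). Concentration responses are summarized two ways: a
four-parameter log-logistic fit for the EC50 (vendor software performs
this fit in the original workflow; it is reimplemented here as the
standard model, with an `extrapolated` flag when the EC50 falls outside
the tested range), and an ordinary least-squares slope of response versus
concentration for ligand-series comparisons. Whether that slope should use
a linear or log concentration axis is not standardized; linear is the
default and `log_conc = TRUE` is exposed without any claim of fidelity to
any particular instrument software.

## NMR chemical-shift perturbations

Paired HSQC peak lists yield per-residue weighted perturbations

$$\Delta\delta = \sqrt{\frac{(\Delta^1H)^2 + 0.2\,(\Delta^{15}N)^2}{2}},$$

computed only where both spectra carry confident assignments. Prolines
(no backbone amide) and overlapped/missing resonances are carried through
with explicit status and are structurally excluded from all statistics.
Significance thresholds follow the standard convention: mean
$\Delta\delta$ across measurable residues plus one or two standard
deviations, with strict (">") exceedance and the higher class winning.
The SD convention (sample, $n-1$) is a documented choice with a
`sd_type = "population"` switch, since the convention is rarely stated in
practice. For a ligand concentration series, tables can be averaged per
residue across concentrations (residues measured in a subset of spectra
average over that subset) and thresholds recomputed on the averaged table;
both per-concentration and averaged-table thresholding are available
because the field uses both.

## Thermal-shift melting temperature

Melt curves are optionally smoothed with a centered moving average
(default window 5 points; window 1 = raw data) and differentiated by
central differences; Tm is the temperature of the maximal derivative.
This estimator is invariant under positive affine transforms of the
fluorescence axis. Degenerate shapes are flagged rather than silently
reported: derivative ties (e.g. a linear ramp) report the first maximum
with a `tie` flag, a maximum at the edge of the usable range sets
`boundary` (the transition may be truncated by the ramp), and a curve with
no positive derivative raises a no-transition error. The ramp rate itself
does not enter the estimator. `delta_tm()` compares replicate means and
retains per-replicate values so downstream significance testing (ANOVA,
paired t) can be done with standard tools; those tests are intentionally
not wrapped.

## The synthetic-data generator

Every pipeline input can be generated with known ground truth:
sigmoidal dye-release plates with buffer/detergent controls, rise–decay
polarization plates with flat ligand-only controls, pre-IR/heating MST
timetraces, two-state logistic melt curves, and paired peak lists with
designated perturbed residues, prolines and missing assignments. All
generators are pure functions of their specification and seed (they
restore the caller's RNG state), emit the same plate-map schema the
readers consume, and add i.i.d. Gaussian noise per reading — a plate-reader
shot-noise approximation. What they do **not** emulate: heteroscedastic or
drift noise, vesicle-to-vesicle heterogeneity, graded versus all-or-none
release, mechanistic FP kinetics, thermophoresis physics, or NMR spectra
(only peak lists). Passing recovery tests therefore demonstrate
correctness of the estimators under the stated noise model, not robustness
to every artifact of real plates.

## Problem sizes and tolerances

The test and acceptance studies use the sizes a desk-scale verification
calls for: 90-point kinetic traces in triplicate, 200-seed Monte-Carlo
repeats for every stochastic recovery claim, 1,000 random parameter sets
for the closed-form/oracle comparison, 10,000 random pairs for the metric
axioms, and 8×8 dose matrices for synergy roundtrips. Zero-noise
roundtrips are asserted at $10^{-6}$ relative (fit convergence tolerances
are set to $10^{-15}$ so the optimizer never limits them); stochastic
recovery bounds are asserted on medians, means or 95th percentiles as
appropriate to an unbounded noise model, with each aggregation stated in
the test.

## Worked example

```{r example}
spec <- sim_plate_spec(55, 55, 90, list(
  plate_condition("bax_bim_2t16", "sample",
                  list(b = 95, t = 455, e = 2000, h = 4, s = 1),
                  n_rep = 3, dose_a = 25, dose_b = 2.5),
  plate_condition("buffer", "buffer", list(level = 50), n_rep = 2),
  plate_condition("chaps", "detergent_max", list(level = 500), n_rep = 2)),
  noise_sd = 4, seed = 1)
plate <- sim_luv_plate(spec)
fit_luv_plate(plate)
```

The raw span (95, 455) sits at 10% and 90% of the control anchors
(50, 500), and the fitted normalized parameters recover that together with
the kinetic shape, inflection time and maximal rate.
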