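---
title: "Methods: model-based perfusion deconvolution and modality agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-based perfusion deconvolution and modality agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcmr)
```

# The quantification problem

First-pass perfusion CMR observes the transit of a gadolinium bolus through
the left-ventricular blood pool and the myocardium. Under linear
time-invariant tracer kinetics, the tissue concentration curve is the
arterial input function (AIF) convolved with a tissue impulse response
function (IRF), so absolute myocardial blood flow (MBF) can be estimated by
model-based deconvolution: pick a parametric IRF, convolve it with the
measured AIF, and adjust the parameters until the modelled curve matches the
measured tissue curve. `qpcmr` implements this pixel-wise for three IRFs —
Tofts, modified Tofts (adding an intravascular plasma term `Vp δ(t)`), and
the Fermi function — together with everything needed to score the result
against a reference modality.

Assumptions inherited from the framework: the system is linear and
time-invariant over the acquisition (no bolus-induced hemodynamic change);
the series is motion-corrected before it reaches the fitter; the AIF
measured in the blood pool is the input seen by every pixel up to a pure
delay; and concentration is proportional to relaxation-rate change
(fast-water-exchange limit).

# Signal model and AIF handling

The dual-sequence acquisition yields a short-saturation-delay
low-resolution stream (TD = 25 ms) whose blood-pool signal stays nearly
linear in concentration, and a TD = 110 ms high-resolution tissue stream.
Both are modelled as ideal saturation recovery,

$$S(C) = \frac{1 - e^{-TD\,(R_{10} + r_1 C)}}{1 - e^{-TD\,R_{10}}},$$

normalised so `S(0) = 1` after division by the pre-contrast baseline (3
frames by default), which also cancels coil gain and proton density. The
inversion is closed-form logarithmic; signals at or above the saturation
ceiling `1/(1 - e^{-TD R10})` are flagged non-invertible rather than
extrapolated, and small negative concentrations from noise are clipped to
zero and counted. Readout-train and flip-angle corrections are deliberately
out of scope: what matters for the pipeline's behaviour is the dual-TD
nonlinearity, and the forward/inverse pair is exact by construction
(property-tested to 1e-10 over random TD, T1, r1, C).

Defaults: relaxivity `r1 = 3.5` L·mmol⁻¹·s⁻¹ (literature-typical for
Gd-DOTA at 3 T), baseline T1 = 1.2 s (myocardium at 3 T). Both are plain
arguments, not constants.

The AIF is the per-frame mean over a circular blood-pool ROI (10-mm
diameter; a pixel counts if its centre lies inside). The blood curve is
divided by (1 − hematocrit) to give plasma concentration. The Tofts family
is plasma-referenced, so it consumes the plasma curve; the Fermi amplitude
is interpreted as blood flow and uses the blood curve. This pairing is a
package decision (overridable via `aif_reference`), keeping each model's
flow metric in its conventional reference frame.

# Kinetic models, units, and the flow read-out

Time runs in seconds internally; rate constants keep their conventional
units and the convolution step converts (dt in minutes), so `K_trans` and
`F` are per-minute quantities. Reported MBF:

* **Tofts / modified Tofts**: `MBF = K_trans / 1.05` — the transfer
  constant per mL of tissue converted to per gram with myocardial density
  1.05 g/mL.
* **Fermi**: `MBF = IRF(0) = F / (1 + exp(-k·MTT))` — the initial
  amplitude of the fitted impulse response.

The Fermi read-out deserves its paragraph. The scale parameter `F` is not
what the data determine: under noise the likelihood has a ridge along which
`F`, `k` and `MTT` trade off (a taller, narrower plateau fits as well as a
shorter, wider one), and on simulated SNR-20 phantoms the median error of
`F` is roughly twice the acceptance tolerance while the initial amplitude
`IRF(0)` — the conventional flow estimate in Fermi deconvolution, since the
residue function starts at the flow value — stays well determined. `qpcmr`
therefore reports `IRF(0)`, and the synthetic generator inverts the same
mapping (`F = MBF·(1 + exp(-k·MTT))`) so that noise-free round trips
recover the generating flow exactly.

The modified-Tofts Dirac term is never discretised: the forward model adds
`Vp·Ca(t - delay)` analytically, so `Vp = 0` reproduces the Tofts curve
bitwise and the term is grid-independent.

# Fitting: optimiser, delay, numerical choices

Per curve, bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) minimises the residual sum of squares. Defaults:
initialisation `K_trans`/`F` = 1 per min, `Ve` = 0.2, `Vp` = 0.05,
`k` = 0.3 s⁻¹, `MTT` = 5 s; bounds `K_trans, F ∈ [1e-4, 10]`,
`Ve ∈ (0, 1]`, `Vp ∈ [0, 0.5]`, `k ∈ [1e-4, 5]`, `MTT ∈ [0, 30]`; an
optional 3-point multistart scales the flow parameter by 0.5×/2×.

The bolus delay is handled by exhaustive grid search, 0–10 s in frame-time
steps by default, with a full continuous fit at each candidate; the lowest
residual wins and ties break to the smaller delay (the grid is scanned in
ascending order and a candidate must strictly improve). Delay is searched
rather than fitted continuously because it enters non-smoothly through the
interpolated shift and because delay–MTT trading is the known failure mode
of Fermi fitting.

The whole 60-s record is fitted by default; `fit_window` truncates to the
first-pass if desired, exposed as an option because window choice is known
to move Fermi estimates.

Degenerate inputs: an identically flat curve is not sent to the optimiser —
it returns MBF = 0, `converged = FALSE`, flag `"flat"`. In maps,
non-convergent pixels become `NA` and are counted; only flat curves map to
zero. MPR excludes pixels whose rest MBF is at or below a floor of
0.1 mL/min/g, so ratios are never driven by near-zero denominators.

# The synthetic generator

The generator exists so every downstream stage has a ground truth. It
emulates: a gamma-variate first-pass bolus
(`amplitude·((t−t0)/β)^α·exp(−(t−t0)/β)`, defaults α = 3, β = 2.5 s,
t0 = 5 s, peak ≈ 5.4 mM) with a 15 % recirculation copy delayed 20 s — the
field-standard smooth bolus shape, since no measured AIF numerics exist to
copy; an annular myocardium (endo 10 / epi 20 mm) around a circular blood
pool in up to three short-axis slices, 60 frames at 1-s spacing (one
R–R interval per frame over a 60-s acquisition); per-AHA-segment true MBF
with tissue curves generated by the same forward model the fitter inverts;
additive i.i.d. Gaussian noise in the concentration domain (the
signal-domain path through `sr_signal` exists for round-trip tests, and
keeping kinetics tests in the concentration domain decouples them from the
signal model). Phantom noise levels are specified relative to the peak
myocardial tissue concentration — e.g. "SNR 20" means noise sd = tissue
peak / 20; the blood pool is several times brighter, so blood-referenced
SNR would be a different (much harsher) convention.

The paired-cohort simulator is a statistical stand-in for a two-modality
study: latent true MBF per subject (defaults: stress 2.83 ± 0.73, rest
1.46 ± 0.45 mL/min/g, truncated below at 0.05), observed by a reference
arm (truth + noise) and a test arm (truth + bias + noise). With per-arm
noise 0.70/√2 the paired-difference sd is 0.70 mL/min/g, so an injected
bias of 0.31 reproduces a realistic vessel-level disagreement scenario as
a *simulation input*.

What the generator does **not** emulate: cardiac/respiratory motion and
registration failure, k-space/SENSE acquisition physics, saturation-pulse
profiles, water exchange, PET count statistics, or spatially correlated
noise. Passing tests therefore demonstrate correctness of the computation
under the stated model, not robustness to real-world acquisition artifacts.

# Segmentation and aggregation

AHA 16-segment labelling partitions each annular slice into equal angular
sectors counterclockwise from the RV-insertion reference ray: 6 × 60° on
basal and mid slices, 4 × 90° apical, numbered 1–6 / 7–12 / 13–16 with
territories LAD = {1,2,7,8,13,14}, RCA = {3,4,9,10,15},
LCX = {5,6,11,12,16}. Arrays are indexed (row, col, slice, time) and
angles measured counterclockwise from the insertion ray — stated once here
and used everywhere.

Segment values are pixel means; vessel values are means over all pixels of
the territory (not means of segment means); the participant value is the
global myocardial pixel mean — with heterogeneous segment sizes the two
conventions differ, and the pixel mean is the default because it weights
tissue, not bookkeeping units. Segment MPR is the ratio of segment means,
again not the mean of pixel ratios. Exclusion rules: poor registration
(externally flagged) and thickness < 5 mm; a doubly-flagged segment counts
once with poor registration taking precedence; summary percentages are
rounded half-up to one decimal, matching the reporting style of clinical
tables. Mask-derived thickness is a radial-extent estimate per sector and
an externally measured table should override it when available.

# Agreement statistics

* **Pearson + OLS**: product-moment r with the two-sided t-transform p,
  y-on-x regression.
* **Bland–Altman**: bias = mean(y − x), sample sd, LoA = bias ± 1.96 sd.
* **ICC**: two-way random-effects, absolute-agreement, single-measures
  ICC(A,1), from the two-way ANOVA mean squares with the F-based
  (Satterthwaite) confidence interval. Absolute agreement is chosen over
  consistency because method interchangeability must penalise systematic
  offsets; the package's tests include the case where a pure offset leaves
  r = 1 while ICC < 1. Interpretation bands: < 0.50 poor, 0.50–0.75
  moderate (both boundaries inclusive), up to 0.90 good (inclusive),
  above excellent.
* **TOST**: two one-sided paired t-tests against ±margin; p is the larger
  of the two; equivalence at p < 0.05. Zero-spread differences short-cut
  to |mean| < margin with a degeneracy flag. Margins ship as data:
  0.90 (MBF) / 0.98 (MPR) at participant level, 1.43 / 2.80 at vessel and
  segment level.
* **ROC/AUC**: Mann–Whitney rank form with half-credit ties; orientation
  is explicit (`direction = "lower"`: lower perfusion predicts
  abnormality) and never auto-flipped. Abnormality thresholds: stress MBF
  ≤ 2.3 mL/min/g, MPR ≤ 2.5, boundary inclusive.
* **DeLong**: placement-value covariance, two-sided normal p;
  rank-identical scores give p = 1 with a degeneracy flag.
* **Sample size**: Walter–Eliasziw–Donner approximation
  `n = 1 + 2k(z_{α/2}+z_β)² / ((k−1)·ln²C₀)`,
  `C₀ = F(ρ₀)/F(ρ₁)`, `F(ρ) = (1+(k−1)ρ)/(1−ρ)`, ceiling-rounded. For
  ρ₀ = 0.20, ρ₁ = 0.60, α = 0.05 two-sided, power 0.80, k = 2 it returns
  34; published planning software varies by ±1–2 around such values
  depending on the approximation, which is why the package documents the
  formula rather than a target number.

Segment- and vessel-level rows are treated as independent observations, as
level-wise clinical analyses conventionally do; the subject id is carried
as an annotation but no mixed-effects correction is applied. No
multiple-testing adjustment is made; p < 0.05 throughout.

# Problem sizes and tolerances

The test suite and the acceptance script use: convolution oracle at
dt = 0.5 s against the closed-form mono-exponential-AIF solution (relative
error ≤ 1e-4, O(dt²) convergence verified by halving); noise-free recovery
on a 9-point flow grid 0.5–4.5 mL/min/g × delays {0, 3, 6} s per model
(2 % tolerance, delay within one frame); a 32 × 32 single-slice SNR-20
phantom (236 myocardial pixels, 10 % median-error tolerance); ICC oracle
agreement at 1e-10; a 20 000-replicate stratified bootstrap against the
DeLong p; TOST empirical size at the margin over 2000 replicates of
n = 30; and a 5000-subject cohort for bias recovery within 3 Monte-Carlo
standard errors. These sizes were chosen to make Monte-Carlo error small
relative to each tolerance while keeping the suite quick to run on one
core.

# Known limitations

Input series are assumed registered; there is no motion correction, no
MOLLI T1 fitting (baseline T1 is an input), no water-exchange or B1
correction, and no distributed-parameter (BTEX) models. The Fermi model,
while the field's workhorse, is an empirical shape — its parameters beyond
the initial amplitude should not be over-interpreted physiologically. The
cohort simulator emulates the statistical design of a paired-modality
study, not PET physics; agreement numbers computed on it validate the
statistics code, never any claim about real scanners or patients.
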