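---
title: "Speckle statistics for material differentiation in OCT: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speckle statistics for material differentiation in OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octspeckle)
```

## The model

Coherent imaging of a medium with many sub-resolution scatterers produces
fully developed speckle: the complex field at a voxel is circular Gaussian,
so its amplitude follows a Rayleigh distribution. `octspeckle` fits the
three-parameter extension

$$P(x; a, b, c) = a\,\frac{x - c}{b^2}\,
  \exp\!\left(-\frac{(x-c)^2}{2b^2}\right), \qquad x \ge c,$$

to the intensity histogram of a region of interest. `b` (scale, intensity
units) tracks the mean amplitude; `c` (shift, intensity units) absorbs any
additive offset in the detection chain and may be negative; `a`
(dimensionless once histograms are density-normalised) absorbs residual
shape mismatch. As printed, the expression goes negative for `x < c`; a
density cannot, so the fit uses the standard piecewise extension
`P = 0` below the shift. With `a = 1` the density then integrates to one
over `[c, ∞)` for every `b > 0`.

Three properties make the fit a texture statistic rather than an intensity
statistic:

* it is computed on a **density-normalised** histogram (64 equal-width bins
  spanning the sample range by default), so overall brightness cancels;
* it is **scale- and shift-equivariant**: scaling the sample by `s` maps
  `(a, b, c, R²)` to `(a, sb, sc, R²)`, and shifting by `Δ` maps `c` to
  `c + Δ` only — both are enforced by tests;
* the goodness of fit `R² = 1 − SSE/SS_tot` on the bin heights measures how
  Rayleigh-like the texture is, independently of how bright it is.

A consequence worth stating plainly: because the features are deliberately
scale-free, any two materials that differ *only* in intensity scale (for
example pure detector noise at two gain levels) are indistinguishable in
this feature space. The air and noise classes below are exactly such a pair
and their mutual confusion is expected, not a defect.

## ROI protocol

The default ROI is 6 × 6 × 10 voxels (depth × fast × slow) at voxel pitches
of 7.5, 7.5 and 3.75 µm — physical extents of 45 × 45 × 37.5 µm — pooled
across 24 repeat frames for 8640 pixels per histogram. With 64 bins this
gives ~135 expected counts per bin, balancing shape resolution against bin
noise; the bin count is a parameter. Sliding-window feature maps reuse the
ROI footprint as the window, stride 1, with edge windows masked rather than
padded.

## Fitting procedure

The fit is bounded nonlinear least squares on the
`(bin centre, density)` pairs: Levenberg–Marquardt with
`b ∈ (10⁻¹², 10·range)`, `c ∈ [min − range, min]`, `a ≥ 0`, tolerances
`1e-10`, at most 2000 function evaluations per pass. Starting values come
from the histogram: `c₀` slightly below the sample minimum,
`b₀ = mode − c₀`, `a₀` matching the peak density.

Projected LM steps can stall with the shift pinned spuriously at its upper
bound, so every LM solution is polished by a projected quasi-Newton
(L-BFGS-B) pass and, if that moves, refined by a second LM pass from the
interior; if the solution still sits on a bound, two progressively deeper
shift starts are tried and the best sum of squares wins. On noiseless
model-generated histograms this recovers coefficients to machine precision;
an exhaustive 60³ grid search over the feasible box never finds a lower SSE
(both are enforced by tests). A fit that ends on a bound is reported with
`converged = FALSE` but its coefficients are kept — for strongly
non-Rayleigh histograms a constrained optimum is the honest answer, and low
`R²` is the signal, not an error. Multimodal histograms are likewise fitted
as-is.

Intensities are treated as linear amplitudes throughout; no logarithmic
compression is applied before fitting.

## The synthetic phantom

`generate_phantom()` emulates the scene used to validate the method: a
semi-transparent tube (wall = lymph-vessel analogue) whose lumen holds dyed
water (lymph analogue), a transparent rod (nerve analogue), both running
along the slow axis inside an Intralipid-gelatin scattering background,
under an air gap, with a low-signal noise band at depth. Default geometry:
305/762 µm tube inner/outer diameter, 400 µm rod, 150 µm air gap, noise
band from 1200 µm. The default volume is 200 × 187 × 16 voxels × 24
repeats; label maps are exact analytic geometry (voxel-centre predicates),
which the tests check against closed-form cylinder areas.

Each region's intensities are drawn as `shift + R₁ + R₂`:

* `R₁` is Rayleigh speckle generated through an underlying circular-Gaussian
  field. Repeat frame `r` uses `ρ·frozen + √(1−ρ²)·fresh` with
  `ρ = 1 − decorrelation`, so the Rayleigh marginal is *exact* at every
  decorrelation setting (interpolating amplitudes instead would distort the
  marginal). `decorrelation = 1` gives independent speckle per repeat,
  `0` a frozen pattern.
* `R₂` is an additive Rayleigh noise floor, redrawn every repeat.
* With probability `1 − rayleigh_purity`, a voxel's speckle scale is drawn
  from a dim contaminating component graded linearly from 0.05× to 0.30× of
  the local scale across ROI-depth blocks — a one-parameter stand-in for
  partially shadowed speckle in dense scatterers. The dim grade was chosen
  over a bright-tailed contaminant because it degrades `R²`
  *monotonically* in the contaminated fraction; a bright tail paradoxically
  raises `R²` at small fractions by stretching the histogram range and
  concentrating `SS_tot` in the peak.
* `base_scale` decays as `exp(−depth_attenuation · depth)` inside a region.

Default region models (scales in arbitrary linear units):

| region | scale | shift | floor | purity | decorr | emulates |
|---|---|---|---|---|---|---|
| air | 1.0 | −0.20 | 0 | 1.00 | 1.0 | detector noise above the surface |
| noise | 1.3 | −0.20 | 0 | 1.00 | 1.0 | deep low-SNR band |
| dyed water | 2.2 | −0.22 | 0.30 | 1.00 | 1.0 | clear fluid just above the floor |
| transparent solid | 2.8 | −0.26 | 0.15 | 0.92 | 0.9 | homogeneous polymer rod |
| semi-transparent solid | 5.0 | −0.20 | 0.15 | 0.85 | 0.9 | PTFE-like tube wall |
| Intralipid | 8.0 | −0.30 | 0.15 | 0.60 | 0.9 | dense lipid scatterer |

Two modelling points deserve their rationale:

* **Dyed water is pure speckle on a strong noise floor** (purity 1, floor
  ratio 0.14), not a contaminated scatterer: a clear fluid has almost no
  scatterers to contaminate its statistics, and its weak signal rides just
  above the detector floor. The signal-plus-noise convolution both lands
  the fluid in its observed goodness-of-fit regime (`R² ≈ 0.985`) and gives
  it a shape signature — `a` and `c` biased upward — that separates it from
  air in the scale-free feature space.
* **Decorrelation defaults are near 1 even for static media.** Over the
  tens of milliseconds between repeat frames, Brownian motion of water and
  of gel-embedded scatterers re-randomises the sub-wavelength phases almost
  completely; solids keep a small residual correlation (0.9). Strongly
  frozen speckle (decorrelation ≪ 1) would collapse the pooled histogram's
  effective sample size from 8640 to a few hundred and degrade every
  solid-region fit far below its observed regime.

With these settings the per-region mean `R²` reproduces the qualitative
ordering observed on real materials — air ≈ noise ≈ 0.99 >
dyed water ≈ 0.98 ≥ transparent solid ≈ 0.98 > semi-transparent solid
≈ 0.95 > Intralipid < 0.93 — and the purity → `R²` mapping is monotone
(both test-enforced, 20 seeds).

What the simulator does **not** emulate: coherent point-spread-function
correlations between neighbouring voxels (each voxel's field is
independent), the complex-conjugate mirror artifact, specular surface
reflections, beam roll-off, and any Doppler/flow dynamics beyond the
decorrelation knob. Passing tests therefore demonstrate the *pipeline's*
correctness and the statistic's discriminative mechanics, not instrument
performance; on real data the air class in particular behaves worse (the
conjugate artifact contaminates it).

All generation is deterministic given a seed: one Mersenne-Twister stream
(inversion normals, rejection sampling), seeded explicitly per operation and
restored afterwards.

## Classification protocol

Thirty pixels per class are drawn uniformly per dataset randomization;
features are fitted in the ROI-sized window around each pixel. A candidate
pixel must have its full window inside the volume *and* label-pure: a
supervised training label is only meaningful if the pooled sample it
describes comes from one material (in the physical experiment the
corresponding pixels were picked inside visually identified regions).
Without that restriction ~30 % of lumen pixels carry wall-contaminated
windows and label noise caps the achievable accuracy.

The classifier is an RBF-kernel SVM — kernel scale `√d/4` for `d` features
(the "fine" Gaussian preset, `gamma = 1/scale²`), box constraint 1,
one-vs-one multiclass — with stratified five-fold cross-validation.
Standardisation parameters come from the training folds only (leakage is
test-enforced). One-vs-rest scores for ROC analysis are the summed signed
pairwise decision values; the operating point maximises Youden's
`J = TPR − FPR` with ties broken toward higher TPR, a concrete reading of
"high sensitivity and high specificity". Overall accuracy is the mean of
the six per-class true-positive rates, reported mean ± sd over 10
randomizations of the training sample and folds.

Two baselines are trained identically on the same sampled pixels: the
depth-resolved attenuation coefficient (window-averaged
`μ[i] = I[i]/(2Δz Σ_{j>i} I[j])`, bottom 10 % of depths masked against
tail-sum underflow; the single-scattering tail-sum form, chosen as the
standard depth-resolved formulation) and GLCM texture features (32 grey
levels quantised per window, symmetric co-occurrence matrices at the four
distance-1 offsets in the B-scan plane, Haralick contrast / correlation /
energy / homogeneity averaged over offsets). On the default phantom the
expected ordering — Rayleigh features > attenuation > GLCM — is
test-enforced; the attenuation estimator's 2 % recovery guarantee holds in
its validity regime (`µΔz ≪ 1`, range spanning many attenuation lengths).

## Flow study

The lumen is simulated under three conditions — dyed water flowing, dyed
water static, clear water static — as single-region volumes; dye is an
absorption-only 0.98 intensity scale factor and static water keeps
decorrelation 0.97 (Brownian motion). Ten ROIs per condition are fitted and
every condition pair is compared on mean `R²` and mean `a` with two-sided
Monte-Carlo permutation tests (1000 relabellings). The six pairwise
p-values are Holm-adjusted before flagging at α = 0.05: without family-wise
control a true null would still flag ≥ 1 of 6 tests in roughly a quarter of
runs, which is the multiple-comparison treatment such condition contrasts
conventionally receive. The design is a deliberate null — pooled spatial
statistics are invariant to repeat order and nearly invariant to the
residual decorrelation difference — and the tests confirm no flagged pair
in ≥ 90 % of seeds.

## Numerical choices and edge cases

* Histograms require ≥ 4 bins and a non-degenerate range; constant samples
  are an explicit error. A vanishing Rayleigh scale collapses intensities
  onto the shift, which the simulator reproduces in the limit.
* `R²` on a flat histogram (zero `SS_tot`) is an error, not `NaN`.
* Constant GLCM windows use the zero-variance conventions contrast 0,
  energy 1, homogeneity 1, correlation 0.
* Attenuation voxels with non-positive tail sums are masked, not errors.
* Volumes round-trip bit-identically through the raw binary layout; the
  TIFF layout stores `(x − min)/(max − min)` as 32-bit float pages (the
  container holds [0, 1]) with the range in the YAML sidecar, so its round
  trip is exact to single precision.

## Problem sizes

The shipped studies use a 200 × 187 × 16 × 24 default volume (≈ 14 M
voxels), 2 phantoms × 10 ROIs per region for fitting summaries, 20 seeds
for ordering and flow properties, 200 simulations for parameter-recovery
bias, and 10 classifier randomizations — sizes at which every quantity's
sampling error is comfortably below the margins being tested while the full
suite runs on a laptop-class single core.

## Known limitations

* Scale-free features cannot separate materials differing only in
  brightness (air vs noise); the physical experiment separates them through
  the amplitude coefficient's dependence on absolute intensity range, a
  preprocessing-dependent effect this package deliberately avoids.
* The contaminant model is a single-knob caricature of everything that
  makes dense-scatterer histograms non-Rayleigh (multiple scattering,
  shadowing, local attenuation gradients); it reproduces the goodness-of-fit
  regimes, not their physical mechanism.
* Absolute values of the amplitude coefficient are convention-dependent
  (histogram normalisation); only orderings and signatures are meaningful.
* The depth-resolved attenuation estimator is uncorrected for confocal gate
  and sensitivity roll-off, as is conventional for the tail-sum form.
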