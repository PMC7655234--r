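---
title: "Surrogate-driven 2D respiratory motion modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-driven 2D respiratory motion modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cinemotion)
```

## The problem

During MR-guided radiotherapy of lung tumours, 2D cine-MR images can be
acquired continuously, alternating between two fixed slice locations: a
*surrogate* slice used to read out low-dimensional breathing signals, and a
*motion* slice in which the actual anatomical motion is to be estimated.
A surrogate-driven motion model relates the signals to the motion so that,
once built, the full deformation can be estimated from the signals alone —
including breath-to-breath (inter-cycle) variability and hysteresis
(intra-cycle) variability, which a single phase or amplitude parameter
cannot capture.

`cinemotion` implements this workflow end to end for 2D slices:

1. a seedable synthetic cine-MR generator with known ground-truth motion;
2. surrogate-signal extraction (diaphragm and skin edge tracking, PCA on
   image intensities, PCA on control-point displacements from registration
   of the surrogate slice);
3. cubic B-spline deformation machinery with two sliding regions;
4. linear correspondence models fitted by ordinary least squares;
5. the evaluation protocol: building/test split, evenly spaced training
   subsets with 4-fold cross-validation, and deformation field error (DFE)
   statistics within anatomical masks.

## The model

Motion is parameterized by cubic B-spline control-point displacements
(CPDs). Two full grids are kept, one per *sliding region*: region 2 covers
the lungs, mediastinum and abdominal organs, which slide against region 1
(chest wall and everything else). The composed deformation vector field
(DVF) takes each pixel's displacement from the grid of the region the pixel
belongs to in the source-image segmentation, so discontinuities across the
interface — sliding — are representable.

Every scalar CPD component $M_i$ (one control point, one displacement
direction, one region) is related linearly to the surrogate signals $s_j$:

$$M_i(s_1, s_2) = c_2 s_2 + c_1 s_1 + c_0, \qquad
  M_i(s_1, s_2, s_3) = c_3 s_3 + c_2 s_2 + c_1 s_1 + c_0,$$

with coefficients fitted per component by ordinary least squares. The model
zoo (`model_zoo()`) contains the canonical 7 two-signal and 3 three-signal
combinations of diaphragm, skin, intensity-PCA and CPD-PCA signals with and
without temporal derivatives, plus the no-model baseline (estimated motion
identically zero), which quantifies how much motion the test frames contain.

Accuracy is measured by the DFE: the per-pixel Euclidean norm of the
difference between the estimated and the reference DVF, in mm, summarized
by its mean and 95th percentile within an evaluation mask and a tumour
mask, pooled over all test frames.

## The synthetic generator

Patient data of this kind is not publicly deposited, so the package ships a
generator that emulates the *structure* of such acquisitions:

* **Anatomy** (`make_phantom()`): an analytic sagittal slice (default
  128 × 128 at 1.98 mm) with a dark lung containing bright vessels and a
  tumour, a domed diaphragm over a bright abdomen, an anterior chest-wall
  band and a soft outer skin boundary. All masks (body, sliding region,
  tumour, evaluation) are generated analytically and nest by construction.
* **Breathing** (`generate_breathing()`): a Lujan-type raised-cosine-power
  waveform per cycle, $b_k + a_k(1 - \sin^4(\pi u))$, flat-topped at
  end-exhale, with per-cycle amplitude, period and baseline drawn from
  configurable normal distributions (defaults: period 4 ± 0.4 s, amplitude
  1 ± 0.1, baseline SD 0.05). The *secondary* latent is the same waveform
  with a phase lead of 1/8 cycle, so the (primary, secondary) trajectory
  traces hysteresis loops. An optional breath-hold freezes both latents by
  warping time; its onset can be snapped to a cycle phase so the hold sits
  at a controlled intermediate diaphragm level.
* **Ground truth** (`generate_ground_truth()`): the true motion is defined
  *directly on the control-point grids* as an exact linear function of the
  two latents, $\mathrm{CPD}(p,t) = c_1(p)\,\mathrm{primary}(t) +
  c_2(p)\,\mathrm{secondary}(t) + c_0(p)$, with $c_0$ chosen so the
  reference frame (primary closest to its mean) has exactly zero
  displacement. Region 2 carries a dominant SI excursion peaking at the
  diaphragm (default 15 mm peak-to-peak, realized against the actual trace)
  and decaying towards the apex; region 1 carries a small AP chest
  expansion (default 3 mm). The hysteresis maps are deliberately *not*
  proportional to the primary maps, so the motion has temporal rank 2 and
  genuinely requires two signals. Because the ground truth lives inside the
  model class, an OLS fit against the true latents recovers the generating
  coefficients exactly — parameter recovery is an exact, not approximate,
  test.
* **Rendering** (`render_series()`): frames are the reference image pulled
  back through the inverted forward DVF (fixed-point inversion, tolerance
  0.01 px, warm-started across acquisition-ordered frames), plus additive
  Gaussian noise (default SD 2% of the dynamic range). Surrogate and motion
  series interleave at the same frame rate (default 1.9 fps each, ~63 s),
  offset by half a frame interval. The first surrogate frames are
  intensity-inflated to emulate acquisition before the magnetization steady
  state, which the pipeline must detect and discard.

What the generator does **not** emulate: MR contrast physics and
reconstruction, cardiac motion, through-plane motion (the coronal
acquisitions of the original study), bulk patient motion, and drifts
unrelated to breathing. Passing tests on this generator therefore
demonstrate that the pipeline's algorithms are correct and that the
qualitative findings re-emerge under controlled conditions; they do not
certify performance on patient data.

### The skin surrogate is deliberately impoverished

On patient data of this kind, the skin signal is the least informative
surrogate. In a generator whose ground truth is *exactly* linear in two
latents, any clean reading of the latents is as good as any other, so a
crisp skin edge would make the skin-plus-derivative model as accurate as
the diaphragm models — contradicting the finding the generator is meant to
reproduce. The phantom therefore renders the outer skin boundary with a
deliberately wide soft edge (4 px vs 0.8 px for internal edges): the 3 mm
chest excursion is read with realistically poor signal-to-noise, the
skin-plus-derivative model ranks worst, while the diaphragm-plus-skin model
(where skin only complements a strong signal) stays accurate — both as
observed in the study.

### Breath-hold placement

A hold frozen at a turning point of the cycle is *consistent* with the
(signal, derivative) mapping learned from regular cycles and does not
perturb derivative-driven models. The default hold therefore starts inside
the building period (24 s) at cycle phase 0.35 — an intermediate,
descending diaphragm level. Training rows sampled inside the hold then
carry a derivative of zero paired with an off-pattern motion state, which
corrupts small-n derivative fits specifically, reproducing the mechanism
behind the irregular-breathing patient in the study. Independent-signal
models are immune: their frozen rows remain exactly consistent linear
equations.

## Signal extraction: numerical choices

* **Steady state**: leading frames whose mean intensity exceeds
  (1 + 0.05) × the median frame mean are discarded; only a leading run is
  ever removed.
* **Edge tracking**: within a window around a seed point (defaults
  20 × 10 px for the diaphragm, 6 × 20 px for the skin), each line parallel
  to the tracked axis is smoothed with a Gaussian of σ = 1 px, the
  maximum-gradient sample is refined by a quadratic fit to the three
  neighbouring gradient magnitudes, and the per-frame position is the mean
  over lines. Signals are reported relative to their temporal mean, in mm,
  signed so end-exhale is positive. The original study used an unspecified
  in-house detector; this is a standard, deterministic substitute.
* **Reference frame**: the frame among the first 30 whose diaphragm sits
  closest to the mean position over those frames (ties: earliest).
* **Body mask**: Otsu threshold, morphological closing (disc, radius 6 px)
  to recapture the dark lung, largest connected component.
* **PCA**: mean-centred SVD. Scores are left in natural units; no
  standardization (the OLS coefficients absorb scale). Signs are fixed so
  each score correlates positively with the diaphragm signal (falling back
  to a largest-loading convention), making regression tests deterministic.
  CPD-PCA excludes control points outside the body mask and concatenates
  the SI and AP displacement components unweighted (both in mm).
* **Spline resampling**: signals are carried to motion-frame times by a
  cubic smoothing spline; target times outside the sampled span are
  rejected (reported, never clipped) and the corresponding motion frames
  are dropped. The smoothing level is chosen by generalized
  cross-validation. A residual-matches-noise rule based on successive
  differences was considered and rejected: at ~1.9 fps adjacent samples
  differ by genuine breathing motion, so that estimator treats signal as
  noise and over-smooths drastically (in measurements it dragged the
  correlation between the resampled PC1-on-CPD signal and the true latent
  from 0.99 down to 0.94). Derivatives are the analytic spline derivatives,
  not finite differences.

## Registration (CPD_s)

The surrogate-slice registration is a single-region (non-sliding)
multi-resolution FFD: control-point spacings of 20, 10, 5 px, locally
normalized cross-correlation (Gaussian window σ = 2 px) minus a bending
energy penalty with weight 0.005, maximized by L-BFGS-B with analytic
gradients chained through the B-spline basis. The LNCC average is
restricted to the body mask. For a full series, `register_series()`
registers the first frame with the complete schedule and warm-starts every
subsequent frame's finest level from its temporal neighbour (cap 12
iterations) — breathing is temporally coherent, so this is both several
times faster and slightly more accurate than independent registrations.
Note that registering reference → frame recovers (approximately) the
*inverse* of the forward ground-truth field; the CPD-PCA scores are
therefore mildly nonlinear functions of the latents, which is also true of
registration outputs on real data. This is one reason the explained
variance of PC1 on CPD_s is lower here than the ~70% reported on patients.

The sliding-preserving two-region registration used to produce reference
motion in the original study is prior work and is *not* implemented;
reference motion comes from the synthetic ground truth or from imported
control-point files (`read_cpd()`).

## Evaluation protocol

The first 80 motion frames form the building set; the rest are the test
set. Training subsets of n = 20 … 6 are evenly spaced (step 4) within the
building set; at n = 20 the four cross-validation folds are
[1, 5, …, 77] … [4, 8, …, 80], and for smaller n the earliest frames are
discarded (fold 1 at n = 19 is [5, 9, …, 77]). Reports are 1-based like
these patterns; internal indexing is 0-based only at the array level.

Masked statistics pool pixels over all test frames (the per-frame values
are also emitted, so a per-frame-average convention can be recomputed);
the 95th percentile uses linear interpolation between order statistics.
Masks are warped to each test frame with the frame's *reference* transform;
models are never evaluated against motion they produced themselves.

## Problem sizes and runtimes

The default study conditions are 128 × 128 frames at 1.98 mm, ~119
interleaved frame pairs over 63 s at 1.9 fps, noise SD 2%. The package's
qualitative-reproduction tests run ten seeds of that configuration (plus
ten breath-hold variants evaluated without the registration-based signals,
which the derivative-vs-independent contrast does not need); unit tests use
64 × 64 phantoms and small algebraic fixtures. One full seed — simulation,
signal extraction including ~115 frame registrations, and the
600-combination training-size experiment — takes on the order of a minute
on one CPU.

## Known limitations

* 2D slices only; no through-plane motion, so coronal-specific effects are
  out of reach of the generator.
* The ground truth being exactly linear in two latents makes absolute DFE
  values optimistic relative to patient data; comparisons *between* models
  and protocol behaviour (training-size curves, breath-hold sensitivity,
  overfitting of 3-signal models) are the meaningful outputs.
* CPD-PCA components beyond PC1 are dominated by registration noise and
  inverse-field nonlinearity rather than by the hysteresis latent; the
  intensity-PCA higher components behave similarly.
* The FFD registration is a compact reference implementation tuned for
  128 × 128 cine frames, not a general-purpose registration package.
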