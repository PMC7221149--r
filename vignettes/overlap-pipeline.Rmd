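---
title: "Quantifying baseline-to-recurrence PET overlap with fuzzy Bayesian delineation"
author: "petoverlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying baseline-to-recurrence PET overlap with fuzzy Bayesian delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the pipeline answers

After chemoradiotherapy for locally advanced cervical cancer, a
substantial fraction of patients relapse locally. If the relapse tends to
occur inside the most FDG-avid part of the *pre-treatment* tumor, that
high-uptake sub-volume is a natural target for radiotherapy dose
escalation. Testing this requires three quantitative steps per patient:

1. bring the recurrence PET/CT into the baseline frame (rigid CT-to-CT
   registration, transform transferred to PET);
2. delineate, on baseline PET, the whole metabolically active tumor (VT)
   and its high-uptake core (V1), and on recurrence PET the relapse
   volume (V2);
3. quantify the spatial agreement of V1 and V2.

`petoverlap` implements this pipeline together with a seeded synthetic
generator of paired pelvic PET/CT studies, so that every stage can be
validated against known ground truth — the clinical images such a study
would use are not publicly available.

## Overlap indices

With voxel counts $|V_1|$, $|V_2|$ and intersection $|V_1 \cap V_2|$ on
a common grid:

$$\mathrm{Dice} = \frac{2|V_1 \cap V_2|}{|V_1|+|V_2|},\qquad
\mathrm{OF} = \frac{|V_1 \cap V_2|}{\min(|V_1|,|V_2|)},\qquad
X = \frac{|V_1 \cap V_2|}{|V_1|},\qquad
Y = \frac{|V_1 \cap V_2|}{|V_2|}.$$

OF is always $\max(X, Y)$, and Dice is the harmonic mean of $X$ and $Y$
whenever the intersection is non-empty; `overlap_metrics()` is tested
against a brute-force voxel enumeration oracle and these identities.
Values are banded (after rounding to 2 decimals) into very low (0–0.20),
low (0.21–0.40), moderate (0.41–0.60), good (0.61–0.80) and very good
(0.81–1.00) concordance. Jaccard is deliberately omitted — it ranks
pairs identically to Dice.

When the measured $|V_2| > |V_1|$ the overlap analysis is no longer
informative (a large recurrence can swallow the whole candidate boost
volume and produce high indices regardless of spatial fidelity), so
every result carries a `v2_gt_v1` flag and `summarize_cohort()` reports
all-cases, $V_2 \le V_1$ and $V_2 > V_1$ views.

## The segmentation model

`flab()` fits a fuzzy locally adaptive Bayesian (FLAB-style) mixture.
The label set contains $K$ hard tissue classes (K = 3 on baseline PET:
background, tumor, high-uptake core; K = 2 on recurrence PET) plus a
ladder of discrete fuzzy levels $\varepsilon \in (0,1)$ between each
adjacent class pair. Observation model:

* hard class $k$: $y \sim \mathcal N(\mu_k, \sigma_k^2)$;
* fuzzy level $\varepsilon$ between classes $k, k+1$:
  $y \sim \mathcal N\big((1-\varepsilon)\mu_k + \varepsilon\mu_{k+1},\;
  (1-\varepsilon)^2\sigma_k^2 + \varepsilon^2\sigma_{k+1}^2\big)$.

The fuzzy levels are the model's account of partial-volume voxels: a
boundary voxel genuinely contains a mixture of tissues. The "locally
adaptive" ingredient is the per-voxel prior field: after each posterior
update, each voxel's label prior becomes $0.9\times$ the mean posterior
over its $3^3$ neighbourhood plus $0.1\times$ the global label
frequencies. Estimation is a deterministic EM-type iteration
(posteriors, then posterior-weighted class moments — each fuzzy label
contributing $1-\varepsilon$ and $\varepsilon$ to its two classes — then
the prior field) until the class means change by less than $10^{-3}$
relative, or 100 iterations. Determinism was chosen over stochastic
(SEM-type) estimation for testability; the quantile-based
initialization (means at the 25/75% or 25/60/95% intensity quantiles,
falling back to evenly spread anchors when a dominant class collapses
the quantiles) is likewise deterministic.

### Deriving volumes from the fit

Binary masks come from each voxel's *posterior-mean class membership*
(fuzzy labels count $\varepsilon$ toward their upper class): VT is the
region with tumor-plus-core membership $\ge 0.5$, V1 the region with
core membership $\ge 0.5$ (a subset of VT by construction), V2 the
region with tumor membership $\ge 0.5$; only the connected component
containing the hottest ROI voxel is kept. Two numerical choices here
matter and were validated on phantoms:

* **Fuzzy ladder density.** With only 3 fuzzy levels the inter-plateau
  continuum created by the scanner PSF cannot be represented; transition
  voxels leak into the hard classes, inflate their fitted SDs, and push
  the half-membership contour outward (about +25% on the recurrence
  volume in our phantom experiments). The default ladder is therefore
  7 levels ($\varepsilon = 0.125, \dots, 0.875$); `fuzzy_levels` is an
  argument, so coarser ladders remain available.
* **Peak referencing (2-class fits).** A small hot structure under a
  6 mm PSF has an attenuated interior: the fitted tumor-class mean sits
  below the true plateau, which again moves the membership cut outward.
  Before cutting, the tumor-class mean is re-referenced to the 0.85
  quantile of the voxels it claims. On unblurred or noise-free data the
  quantile coincides with the class plateau and the correction is a
  no-op.

The ROI handed to the fit is a box around the largest connected
component above 2.5 SUV, dilated by 2 voxels. Urine is by far the
hottest pelvic structure, so the bladder is masked out directly from the
image (voxels above 20 SUV, dilated 8 mm); no ground-truth information
enters the analysis path.

The fixed %SUVmax comparator (`threshold_segment()`) keeps ROI voxels
at or above a percentage of the ROI SUVmax — the approach whose overlap
estimates the statistical model is designed to improve upon.

## Registration

Recurrence CT is registered to baseline CT: center-of-mass translation
initialization, then 6-DOF refinement maximizing mutual information
(50 fixed histogram bins) over a seeded random sample of body voxels, on
a coarse-to-fine schedule (Gaussian smoothing 4/2/0 mm with 6k/12k/24k
samples). The optimizer is a greedy step-halving search that accepts
only metric-improving moves, so the accepted-metric trace is
non-decreasing within each level and the whole procedure is
deterministic. The transform (Euler Z-Y-X intrinsic, degrees, explicit
rotation center; JSON on disk) is then applied to the recurrence PET.

The reasoning behind two choices:

* **Interpolation.** The resampling interpolant for PET transfer is not
  dictated by the source study design, so it is our choice: Catmull-Rom
  cubic. On 4 mm PET voxels, linear interpolation adds enough smoothing
  to visibly inflate the subsequently delineated recurrence volume
  (~10–20% in phantom tests); cubic preserves the edge. Masks always
  use nearest-neighbour.
* **Manual correction.** The clinical workflow allowed interactive
  fixes when automatic registration failed (typically from bladder or
  rectum filling changes). That step is modelled reproducibly as an
  optional operator-supplied transform composed after the automatic one
  (`manual_correction` in `run_case()`).

## The synthetic cohort

`phantom_params()` defaults *are* the study conditions: 4 mm isotropic
PET voxels on a 96³ grid and 1.2 × 1.2 × 3 mm CT voxels (typical for the
scanner class involved); whole-tumor volume 41.9 cm³ with the
high-uptake core at 43% of it and a 15.1 cm³ recurrence (the reported
cohort means); background/tumor/core uptake 1.8 / 5 / 14 SUV with hot
urine at 30; 6 mm FWHM isotropic PSF; Gaussian noise whose SD scales
with the square root of local uptake (0.4 SUV at background),
approximating reconstructed OSEM noise without simulating
reconstruction. A piecewise-constant two-level tumor cannot jointly
reproduce the reported SUVmax (19.5), VT-averaged SUVmean (6.6) *and*
the V1/VT volume ratio (0.43); the calibration prioritizes SUVmax and
the volume statistics. Tumors are unions of 2–4 jittered, rotated
ellipsoids (so Dice is not trivially shape-symmetric), volume-calibrated
on the voxel grid; V1 is a connected region grown inside VT to the exact
target fraction; V2 is grown around a seeded anchor so that the
requested true X and Y are achieved to rounding precision (well within
±0.02), with the implied $|V_2| = X|V_1|/Y$ taking precedence over the
volume target when both overlap targets are positive. Tumor, core and
recurrence stay at least 10 mm clear of the maximal-fill bladder by
construction.

Cohorts draw volumes log-normally (moments matched to the reported
41.9 ± 31.6 cm³), and the $V_2 > V_1$ subgroup is a configured
*composition* — exactly `round(n * fraction)` cases draw overlap targets
with $Y < X$ — rather than a Bernoulli sample, because the emulated
quantity is a cohort composition (7 of 21) and a binomial draw would
make small-cohort counts a coin flip. Misalignment between time points
is a drawn rigid transform (up to 8 mm per axis, 5° per axis by
default); the acquired recurrence PET is synthesized in its own
misaligned frame by sampling the blurred aligned uptake field on the
acquisition grid (an isotropic PSF commutes with rigid motion), so the
acquired image carries a single PSF blur exactly like a real scan, plus
its own noise realization. Bladder filling changes between time points
(`bladder_fill_delta`), reproducing the dominant clinical registration
failure mode.

What the generator does **not** emulate: intra-tumoral uptake gradients
(plateaus only), organ deformation beyond bladder volume change,
respiratory motion, sinogram-level physics (scatter, randoms,
reconstruction artefacts), and inter-patient anatomical variability
beyond seeded jitter of a fixed pelvic layout. Passing phantom tests
therefore demonstrates correctness of the algorithms under controlled
conditions, not clinical performance on patient data.

## Validation batches and problem sizes

The test-suite and `scripts/acceptance.R` batches, with the sizes the
package uses:

* overlap identities against a brute-force voxel-enumeration oracle on
  200 random mask pairs;
* registration recovery on 25 full phantom cases (misalignments within
  ±8 mm / ±5° per axis): target registration error over the tumor ROI
  below half a PET voxel (2 mm) in at least 90% of cases — observed
  median ≈ 0.4 mm;
* segmentation recovery on 25 PET-only phantoms at default noise with
  the PSF off: median Dice vs truth for VT, V1 and V2, and median class
  mean error as a fraction of class separation. The PSF is off here
  deliberately: under blur, the observable plateau of a small hot
  structure sits well below its emission level (partial-volume effect),
  so pre-blur class means are not recoverable by any intensity-space
  estimator and the batch would measure scanner resolution rather than
  estimator quality. Noise-free, blur-free phantoms must be segmented
  *exactly* (Dice 1.0);
* end-to-end accuracy on 5 low-noise (class SD 0.1) cases at the default
  study conditions with the full 6 mm PSF: measured X and Y within
  ±0.07 of the planted truth;
* the threshold-bias experiment: 10 true-Dice strata (0 to 0.9, X = Y),
  2 cases each, recurrence synthesized at the low-contrast
  post-treatment level (SUV 7) — the regime the fixed-threshold critique
  concerns. The ground-truth oracle must show zero bias; the fixed
  40%/40% threshold pipeline must overestimate low true overlaps
  (Dice ≤ 0.2) more than the FLAB pipeline;
* cohort calibration: 50-case ground-truth mean VT within 41.9 ± 10 cm³,
  mean tumor SUVmax within 19.5 ± 7.4, and an n = 21 cohort at a 1/3
  configured fraction carrying 7 ± 2 $V_2 > V_1$ flags.

These sizes keep the full suite comfortably within a few minutes on a
single core while leaving the per-case conditions at the study defaults.

## Known limitations

* The exact estimation scheme of the original FLAB method is described
  in its own literature; this package implements the documented
  model class (hard + fuzzy labels, spatially adaptive priors,
  deterministic EM) without claiming bit-compatibility.
* Overlap is always computed on the baseline PET grid; whether the
  source study computed volumes on native grids is unknown.
* The half-membership cut and the peak-referencing quantile (0.85) are
  calibration choices validated on this generator's phantoms; strongly
  non-plateau clinical uptake patterns may behave differently.
* Cohort-level summary statistics of the original 21 patients cannot be
  reproduced — the patient images are not public; the package validates
  the *method* on synthetic ground truth instead.
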