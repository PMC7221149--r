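# petoverlap

Quantifies how well the high-uptake sub-volume on a *baseline* FDG-PET/CT
study predicts the location of the *metabolic relapse* on a follow-up
study — the question behind PET-guided radiotherapy dose escalation in
locally advanced cervical cancer, where local recurrence after
chemoradiotherapy remains common. The package is aimed at imaging
researchers who want a fully tested, reproducible implementation of that
analysis, validated end to end on synthetic pelvic phantoms with known
ground truth (the patient images such studies use are not public).

The pipeline per case:

1. **Registration** — rigid recurrence→baseline CT alignment
   (center-of-mass initialization, Mattes-style mutual information over
   a multi-resolution schedule, deterministic greedy optimizer), with
   the transform then applied to the PET; an operator correction can be
   composed on top.
2. **Delineation** — a fuzzy locally adaptive Bayesian (FLAB-style)
   mixture fitted by deterministic EM. Hard classes are Gaussian,
   `y ~ N(mu_k, sigma_k^2)`; a fuzzy level `eps` between adjacent
   classes models partial-volume voxels,
   `y ~ N((1-eps) mu_k + eps mu_{k+1}, (1-eps)^2 sigma_k^2 + eps^2 sigma_{k+1}^2)`;
   per-voxel priors blend 3×3×3 neighbourhood posteriors with global
   label frequencies. Three classes on baseline PET jointly yield the
   whole tumor VT and its high-uptake core V1; two classes on the
   resampled recurrence PET yield V2. Fixed %SUVmax thresholding is
   included as the comparator it is meant to replace.
3. **Overlap** — with voxel counts `|V1|`, `|V2|`, `|I| = |V1 ∩ V2|`:

   ```
   Dice = 2|I| / (|V1| + |V2|)      OF = |I| / min(|V1|, |V2|)
   X    = |I| / |V1|                Y  = |I| / |V2|
   ```

   plus concordance bands (very low … very good), SUVmax / SUVmean /
   total lesion glycolysis, cohort summaries, and the rule that flags
   cases with `|V2| > |V1|` (for which overlap analysis is unreliable).

A seeded phantom module generates paired baseline/recurrence PET/CT
studies — pelvic anatomy with variable bladder filling, an
ellipsoid-union tumor calibrated to the reported cohort volumes, PSF
blur and intensity-dependent noise, a planted recurrence with a
controllable true overlap, and a known rigid misalignment — so every
stage is tested against ground truth.

## Worked example

```r
library(petoverlap)

case   <- generate_case(phantom_params(), seed = 42)  # truth: X 0.70, Y 0.77
report <- run_case(case)
report
```

```
Overlap pipeline report (method: flab)
  registration: converged, final MI 0.2361 (11/7/9 iterations)
V1 19.58 cc, V2 16.32 cc, intersection 12.93 cc
  DICE 0.72 (good)
  OF   0.79 (good)
  X    0.66 (good)
  Y    0.79 (good)
```

The phantom planted a recurrence with true X = 0.70, Y = 0.77
(Dice 0.73); the full pipeline — registration, PET transfer, 3-class and
2-class segmentation — measures Dice 0.72 with every index in the
"good" concordance band, i.e. the measured overlap is within a few
hundredths of the planted truth. The underlying segmentation is an
ordinary R model object:

```r
fit <- flab(case$baseline$pet, k = 3,
            exclude = bladder_exclusion_from_pet(case$baseline$pet))
fit
```

```
FLAB segmentation fit: 3 classes, 17 labels, 5472 ROI voxels
Class means (SUV):  1.874,  4.597, 11.022
Class SDs  (SUV): 0.487, 1.475, 3.123
Converged after 62 iterations (relative change 0.00094)
```

with the usual `summary()`, `coef()`, `predict()`, `residuals()`,
`plot()` and `simulate()` methods;
`masks_from_segmentation(fit)` returns the VT/V1 binary masks. Cohort
tools (`generate_cohort()`, `run_cohort()`, `summarize_cohort()`,
`bias_experiment()`) build seeded multi-case studies, including the
configurable fraction of V2 > V1 cases and the threshold-vs-FLAB bias
comparison.

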