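---
title: "Anatomy-driven dose prediction and rectal NTCP estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomy-driven dose prediction and rectal NTCP estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

In prostate volumetric modulated arc therapy (VMAT), the risk of late
rectal bleeding is driven by how much of the anterior rectal wall sits in
the high-dose region, which in turn is fixed by the patient's anatomy —
chiefly the gap between the planning target volume (PTV) and the rectum.
Interventions such as hydrogel spacer implantation must be decided
*before* treatment planning, so a tool that estimates the baseline risk
directly from anatomy, without running a planning system, is useful for
triage. `rtdosepred` implements such a pipeline end to end:

1. a **synthetic pelvic phantom generator** that emulates a cohort of
   VMAT plans (74.8 Gy in 34 fractions) so every stage of the pipeline is
   testable without patient data;
2. **preprocessing** from plan volumes to model-ready channel stacks;
3. a **2D U-net** that predicts the 3D dose distribution from the CT
   image and six structure masks, trained with 5-fold cross-validation
   and applied as a fold ensemble;
4. **DVH metrics** and **isodose Dice similarity** comparing planned and
   predicted doses;
5. **NTCP models** (Lyman–Kutcher–Burman and relative seriality, with
   per-bin EQD2 conversion) turning rectal dose–volume histograms into
   complication probabilities;
6. **statistical evaluation**: per-metric percent mean absolute errors,
   regression goodness-of-fit with Wald tests, and the power analysis
   behind the design.

# The phantom generator

## What it emulates

Each phantom is one "patient-equivalent": a CT-like image, six binary
masks (PTV, rectum, bladder, both femoral heads, body) and a planned dose
on one grid. Geometry is sampled in physical millimetres, so the same
statistics hold on any grid; the default is 64 x 64 x 32 voxels at 3 mm
(a 192 mm field of view), which keeps the whole pipeline trainable on one
CPU while preserving the anatomical relationships the analysis depends
on. Axis order is (slice, row, column): slice increases superiorly, row
posteriorly, column toward the patient's left.

Key anatomical choices:

* the **PTV** is an ellipsoid (semi-axes ~14–28 mm, sampled per axis)
  near the grid centre;
* the **rectum** is a tube with elliptical cross-section whose anterior
  wall *tracks the posterior PTV surface* at a sampled gap of 0–4 mm.
  This conformal contact is deliberate: the prostate indents the anterior
  rectal wall, and a straight circular tube would only line-contact the
  ellipsoid, producing a hot contact patch far smaller than real rectal
  DVHs show;
* the **bladder** sits antero-superior, the **femoral heads** lateral,
  the **body** is an elliptical cylinder; organ overlap is zero except
  that the PTV–rectum interface may touch when the sampled gap is 0;
* all masks are restricted craniocaudally to the PTV extent ± 1 cm,
  mirroring the clinical contouring convention for this treatment site
  (this materially affects rectal relative volumes, so it is fixed
  project-wide);
* image orientation (left/right) follows the column-axis convention
  above; the generator defines it since nothing in the analysis depends
  on chirality.

## The analytic dose model

The planned dose is analytic, not a beam or optimizer simulation — the
analysis needs realistic DVH/NTCP structure, not physical deliverability.
Outside the PTV the profile is a logistic penumbra on a plateau plus a
low-dose bath, as a function of the Euclidean distance `d` (mm) from the
PTV surface (computed by an exact separable distance transform):

```
f(d) = max( plateau / (1 + exp((d - 15) / 3)),  0.10 * exp(-d / 60) )
```

with `plateau = 1.03` in prescription units. Inside the PTV the dose
rises from the surface value toward the centre (saturating boost of
0.10), which makes D50% strictly exceed D95% so coverage rescaling and
the homogeneity index are non-degenerate. A multiplicative attenuation
ramps from 1 to 0.30 over 12 mm starting 2.5 mm posterior to the anterior
rectal wall (tracked per slice), carving the concave rectum-sparing
isodose pattern characteristic of optimized prostate plans. Smooth
Gaussian noise (SD 0.8 Gy, correlation length 2 voxels) is added, the
result is clamped at 110% of the prescription (the planning-goal maximum)
and zeroed outside the body.

These constants were calibrated once, against three anchors, and then
frozen: (i) cohort planned G2 late-rectal-bleeding LKB NTCP concentrated
in the 8–17% band; (ii) the rectum planning constraints V75.1Gy = 0 and
V57.7Gy ≤ 18% satisfied by ≥ 90% of plans; (iii) a strong negative rank
correlation between the sampled PTV–rectum gap and rectum V70Gy. The last
anchor is the learnable signal: across a cohort, anatomy (the gap)
determines rectal exposure, which is exactly what the network must
recover. NTCP anchors are evaluated on coverage-rescaled planned doses,
matching the analysis convention that all dose data are rescaled before
comparison.

What the phantom does *not* emulate: multi-planner variability in
optimization trade-offs, hip prostheses or rectal gas artefacts,
deliverability constraints, inter-fraction motion, and hydrogel-spacer
anatomy. Passing tests on phantoms therefore demonstrates that the
pipeline can recover a dose–anatomy relationship of realistic DVH/NTCP
structure; it does not validate performance on clinical images.

# Preprocessing

The chain mirrors standard practice for CNN dose prediction:

* **Crop and resize.** Each axial plane is cropped to a square window
  centred on the body-mask centroid (a couch-centred field of view
  without registration) and resampled — bilinear for image and dose,
  nearest-neighbour for masks. At clinical resolution the convention is
  512 → 400 crop → 128 target (0.98 mm → 3.06 mm pixels); phantom grids
  use the full plane by default.
* **Slice selection.** Consecutive slices covering the PTV ± 1 cm, with
  a cap (default 80); when coverage exceeds the cap the window is
  truncated symmetrically about the PTV centroid slice, preserving
  target context.
* **Coverage rescaling.** Every dose (training and test, planned and
  predicted) is scaled so 95% of the PTV receives 95% of the
  prescription: D95% = 71.06 Gy at 74.8 Gy. The factor uses the *exact
  voxel quantile* with the same tie convention as the DVH inverse
  (largest dose whose covered volume is at least the target). This makes
  rescaling exactly idempotent (the binned-DVH estimator is not
  scale-equivariant at the 1e-9 level; the two agree within one 0.1 Gy
  interpolation bin, which is far below the 0.01 Gy reporting precision).
* **Global normalization.** Training doses are divided by the single
  cohort-wide maximum; predictions are denormalized by the same training
  constant.
* **Channel assembly.** Fixed order (CT, rectum, bladder, femoral L,
  femoral R, PTV, body); CT intensities windowed to [0, 1] over a
  soft-tissue window (−160 to 240) fixed by configuration.

At prediction time the order of operations is: denormalize by the
training constant, then coverage-rescale the *prediction* using the
predicted PTV D95% (the `rescale_by = "planned"` variant is exposed for
sensitivity analysis; predicted is the default since a deployment setting
has no planned dose).

# The network

The model is a 2D U-net acting slice by slice: encoder blocks halve the
spatial size `depth` times while doubling features from `base_features`;
decoder blocks mirror them with skip concatenations. Every block is
`conv3x3 – BN – ReLU – conv3x3 – BN – dropout – (+ shortcut) – ReLU`,
with a 1x1 projection shortcut when channel counts differ — residual
connections within blocks, and dropout (rate 0.1) after every second
batch-normalization layer. Downsampling is a learned 2x2 stride-2
convolution, upsampling a 2x2 stride-2 transposed convolution; "same"
padding keeps the output at input size; a final 1x1 convolution yields
the single-channel dose map.

No deep-learning framework is assumed: forward, backward and Adam run in
single-precision compiled code (im2col + BLAS sgemm for every
convolution), with all randomness (He-normal initialization, shuffling,
dropout) drawn from one seeded generator, so a training run is exactly
reproducible on a given platform. The gradient implementation is verified
in the test suite by finite differences.

Training follows the clinical-scale recipe: Adam (learning rate 1e-3, beta1
0.9, beta2 0.999, no weight decay), mini-batches of 15 slices, MSE on
normalized doses, 5-fold cross-validation with fold assignment by
patient. "Averaging the 5 U-net models" is implemented as averaging
*predictions*, not weights — weight averaging across independently
initialized networks is meaningless. Dropout is disabled at inference
(standard practice). Predictions are clamped non-negative after
denormalization.

Desk-scale defaults: `base_features = 8, depth = 3` for the model
constructor; the end-to-end feasibility run in the test suite uses
`base_features = 4, depth = 3` and 60 epochs on 40 training phantoms
preprocessed to 48 x 48 in-plane (about 700 slices), which trains all
five folds in minutes on one CPU. The 48-pixel target (4 mm pixels on
the phantom field of view) keeps the rectal wall about three pixels wide
— coarser targets blur the PTV edge slices badly enough to destabilize
the coverage anchoring of predictions. These are capacity/precision
trade-offs, exposed in configuration; the clinical-scale recipe
(128 x 128, 250 epochs) remains expressible. Predicted-vs-planned NTCP
agreement across a 10-phantom test cohort is seed-sensitive at this
scale, so the feasibility test pins every seed; its conclusion is that
the learnable anatomy-to-risk signal is recoverable, not a precise
accuracy figure.

# DVH and NTCP conventions

* DVHs are cumulative, binned at 0.1 Gy by default (interpolation error
  well below the 0.01 Gy reporting precision), with right-open bins so a
  dose exactly on an edge counts toward it. A refinement-stability test
  (halving the bin) replaces any attempt to guess an unstated bin width.
* `D_x%` resolves ties on flat curve segments to the *largest*
  qualifying dose ("minimum dose delivered to the hottest x%");
  `V_xGy` interpolates linearly between edges.
* All structure volumes are voxel counts on the evaluation grid times
  voxel volume; every metric is evaluated on the sample's own grid.
* R50% counts the half-prescription isodose within the body mask (air
  excluded) relative to PTV volume.
* NTCP: the rectal DVH (of the craniocaudally restricted rectum — the
  contoured structure) is converted bin by bin to EQD2 with
  `alpha/beta = 3` Gy at the plan's fraction count, using bin-centre
  doses; the LKB model evaluates the generalized mean
  `Deff = (sum v_i EQD2_i^(1/n))^n` in log space (stable down to
  n = 0.001) and a probit response through the standard-normal CDF
  (`pnorm`, double precision — not a lookup table, since results are
  reported to 0.01%); the relative-seriality model combines the Poisson
  response `P(D) = 2^(-exp(e^gamma (1 - D/D50)))` across bins in log
  space. The endpoint registry (seven LKB endpoints and one RS endpoint)
  ships as versioned YAML and is validated on load.
* The isodose Dice coefficient is standard Dice
  `2|A∩B| / (|A| + |B|)`; when both isodose volumes are empty (levels
  above both maxima) it is defined as 1, which keeps the mean over
  levels up to the prescription well-defined. The level step for the
  mean is 1 Gy, with a step-halving sensitivity value included in the
  report. A typeset union in the defining ratio cannot be meant
  literally, since Dice of identical sets must be 1.
* %MAE follows the two-convention definition: Gy-valued metrics are
  normalized by the prescription; %-valued metrics (V_xGy, NTCP) are
  absolute differences in percentage points. Predicted doses are
  coverage-rescaled before pairing.

# Statistical evaluation

`regress()` is ordinary least squares of predicted on planned with the
two-sided Wald t-test for zero slope (a constant prediction is defined
as R² = 0, no association). `power_r2()` ships both conventions for the
power of that test at a target R² — the large-sample normal
approximation `Phi(sqrt(n f²) − z_{1−α/2})` (primary; gives 0.81 at
n = 15, R² = 0.35, α = 0.05, consistent with a stated 80%) and the exact
noncentral-F computation — because the design statement it reproduces
does not name its convention; both are labelled rather than silently
merged.

# Numerical and degenerate-input policy

* Empty masks are rejected (a DVH of nothing is undefined — mirroring
  the clinical exclusion of a case with missing rectum delineation);
  empty cohorts and zero-dose PTVs likewise raise errors rather than
  returning NaN.
* Cohort generation, preprocessing, training and reporting are pure
  functions of configuration + seed; per-sample seeds derive from the
  master seed so cohorts are reproducible element-wise.
* Distance transforms are exact (Felzenszwalb–Huttenlocher separable
  parabolic envelopes) with anisotropic spacing, tested against brute
  force.
* Single-precision training arithmetic bounds reproducibility to one
  platform/BLAS; all scientific outputs downstream of the network
  (DVH, NTCP, statistics) are double precision.

# Known limitations

* The phantom's dose model is analytic; its absolute NTCP level is
  calibrated, not emergent, so only *relative* recovery (correlation,
  error) across a cohort is scientifically meaningful in tests.
* 2D slice-wise prediction loses craniocaudal context (a 3D variant is
  out of scope).
* The desk-scale network is far smaller than a clinical-scale model;
  reported desk-scale accuracy does not transfer to clinical images.
* NTCP parameters are fixed published sets; fitting them to outcome
  data, and bladder/femoral endpoints, are out of scope.
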