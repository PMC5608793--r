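---
title: "Semi-automated thigh cross-section segmentation: models and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated thigh cross-section segmentation: models and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thighseg)
```

## The problem

A single axial T1-weighted MR slice of the mid thigh carries most of the
morphometric information used in knee-osteoarthritis and training-intervention
research: the cross-sectional areas (CSAs) of the quadriceps, hamstrings,
adductors and sartorius, of the subcutaneous fat (SCF) ring, of the
intermuscular fat (IMF) inside the fascial envelope, and of the femoral bone.
Manual outlining of these structures takes on the order of an hour per slice;
`thighseg` implements a semi-automated alternative that needs only a coarse
initial placement of a statistical shape model and then runs without
interaction, together with the statistical machinery needed to validate such
a method (overlap agreement, inter-observer precision, sensitivity to
longitudinal change) on a fully synthetic, ground-truthed phantom test bed.

## The segmentation model

The pipeline has four stages, run in this fixed order by `segment_thigh()`:

1. **Preprocessing.** Contrast-limited adaptive histogram equalization
   (CLAHE, 8x8 tiles, clip fraction 0.01), then a 2x2 lower-median filter,
   then range normalization to [0, 1] (`preprocess_image()`). The shape
   model search and the threshold statistics both operate on this image.

2. **Active shape model search.** A point distribution model is trained by
   generalized Procrustes alignment of multi-component outline shapes
   (thigh circumference, fascia, femur circumference, medulla, quadriceps,
   hamstrings, sartorius, gracilis — one concatenated landmark vector)
   followed by PCA (`align_shapes()`, `train_pdm()`). Appearance is a
   classic per-landmark gray-profile model: normalized first-derivative
   intensity profiles of half-length k = 6 sampled along the outline
   normal, with ridge-regularized covariances (`train_profiles()`).
   `fit_asm()` runs the standard iterative search (30 iterations by
   default): best Mahalanobis profile match within +/- 8 px along each
   normal, similarity (4-dof) pose update, mode-weight projection with a
   hard clamp at 3 standard deviations. Initialization is an explicit
   similarity pose — the programmatic stand-in for placing the model on the
   image by hand; experiments derive it from the truth shape and perturb it.

3. **Active contour refinement.** Each component mask boundary is resampled
   to uniform arc length and evolved as a closed snake with the
   semi-implicit pentadiagonal update; elasticity/rigidity are
   alpha = 0.4 / beta = 10.0 for all components except the hamstrings
   (alpha = 0.9 / beta = 0.5, their boundary is more strongly curved). The
   femur circumference and the medulla are evolved first on a 6x6
   lower-median filtered copy and then refined on the unfiltered image; all
   other structures attach directly to the unfiltered image.

4. **Compartments.** SCF is the thigh minus the convex hull of the fascia;
   the fat/muscle threshold is the midpoint of the mean SCF intensity and
   the mean quadriceps+hamstrings intensity on the normalized image;
   residual intra-fascial pixels are classified by that threshold, grouped
   by 8-connectivity, and muscle-like groups of more than 70 pixels become
   adductors while smaller groups become "other intermuscular tissue"
   (vessels etc.). Label-map assembly applies a fixed precedence (cortex >
   medulla > named muscles > adductors > other > IMF > SCF) and reports
   areas in pixels and cm².

### Numerical choices worth knowing

* **Even median windows.** A 2x2 or 6x6 window has no central pixel: the
  output pixel is anchored at the top-left of the window's central 2x2
  block, padding is reflective, and the *lower* median of the k² values is
  taken. This makes the filter exactly reproducible by enumeration.
* **Raster rule.** Everywhere a polygon becomes a mask, a pixel belongs to
  the polygon iff its center is inside (even-odd rule), with boundary ties
  broken toward lower row/col — an axis-aligned 10x10 square outline covers
  exactly 100 pixels. The convex hull is rasterized *inclusively* (centers
  on the hull boundary belong to the hull), so the hull of a convex mask is
  that mask.
* **Threshold formula.** The class-mean midpoint is evaluated on the
  range-normalized image, which realizes a denominator of
  2·(pixel_highest − pixel_lowest) on raw intensities; the rule is
  therefore invariant to affine intensity rescaling. Because T1 fat is
  bright, the default assigns each residual pixel to the *nearer* class
  mean (fat-like above the midpoint); `literal_threshold = TRUE` applies
  the printed inequality direction verbatim ("< t" fat) for comparison.
* **Snake discretization.** Evolved contours carry at least 96 points
  (target spacing 1 px, cap 400). The discrete internal forces scale with
  (2π/n)², so a sparsely sampled small contour is pulled inward by its own
  elasticity; the dense floor keeps that bias below ~0.05 px.
* **External energy.** −‖∇(G_σ ∗ I)‖ rescaled to [−1, 0], forces by central
  differences with replicated (zero-flux) borders. The default smoothing is
  σ = 0.7 px and the snakes attach to the *raw* range-normalized image, not
  the CLAHE output: equalization amplifies within-tissue texture into
  spurious gradient minima, and σ = 1 measurably biased small-structure
  equilibria inward (medulla, sartorius) — with σ = 0.7 on the raw image,
  refinement is never worse than the shape-model result by more than 0.02
  Dice on any structure, which the test suite asserts.
* **Degenerate inputs.** Constant images pass through equalization
  unchanged and are rejected by range normalization; empty masks propagate
  as empty with warnings; self-intersecting outlines rasterize by the
  even-odd rule.

## The phantom generator

Real thigh MRIs cannot ship with the package, so all tests run on a seeded
synthetic cohort (`generate_cohort()`). A phantom is built from a canonical
template (256x256 grid, 0.98 mm isotropic spacing; the grid can be reduced
with the field of view held fixed) carrying the eight model outlines plus
truth-only structures: an adductor blob (well above the 70-pixel rule), and
2–6 "vessel" dots each below it. Inter-subject variation is a linear 4-mode
generative model — global size, SCF ring thickness, quadriceps/hamstrings
balance, femoral offset — with unit-normal amplitudes truncated at 3 SD;
infeasible geometries (nesting violations) are resampled. A whole-anatomy
similarity pose (SD: 4 px translation, 4° rotation, 3% log-scale) emulates
positioning. Rendering draws per-class intensities (fat 0.80 ± 0.05, muscle
0.35 ± 0.04, cortical bone 0.10 ± 0.02, medulla 0.75 ± 0.05, background
0.05 ± 0.01) plus 0.01 global noise, clipped to [0, 1] — a T1-like contrast.
Everything is bit-reproducible from the seed.

Longitudinal change scales targeted outlines about their centroids so the
*truth area* changes by a requested percentage; SCF and IMF targets are hit
by solving for the thigh and fascia scale given the (possibly changed)
inner structures. Per-subject changes are drawn from a configured mean ± SD
per structure (the defaults used in the experiments emulate effect sizes
typical of a 12-week lower-limb strength-training intervention:
SCF −5.9 ± 10.2%, IMF −12.2 ± 17.2%,
quadriceps +2.7 ± 4.1%, hamstrings +3.1 ± 5.5%, adductors +10.4 ± 12.5%,
sartorius +5.3 ± 7.4%); draws that make the nesting infeasible are redrawn.

What the phantoms deliberately do **not** emulate: Rician noise, partial
volume, bias fields (available but off by default), anatomy beyond the
eight-component template, and repositioning error between timepoints.
Passing on phantoms therefore demonstrates the correctness and internal
consistency of the algorithms, not clinical performance on scanner data.

## Validation machinery

* `dice()` — overlap agreement 2|M∩S|/(|M|+|S|).
* `bland_altman()` — mean difference (semi-automated − manual) and limits
  of agreement ± 1.96 sample SD (n − 1 throughout).
* `srm_stats()` — standardized response mean (mean/SD of changes); the
  paired t statistic is SRM·√n by construction, p two-sided, no
  multiple-testing correction.
* `rms_cv()` — inter-observer RMS coefficient of variation over duplicate
  measurements.
* `crossvalidate_twofold()` — random disjoint halves, train on one, fit the
  other (shape-model search only, no contour refinement), swap; 10
  repetitions = 20 applications by default.
* `learning_curve()` — training-set size increased in steps of 5 with 5
  random draws per size against a fixed held-out test set, reporting
  mean/min/max test Dice per structure.
* `run_longitudinal_experiment()` — segments paired baseline/follow-up
  cohorts and summarizes per-subject percent CSA changes per structure.

### Experiment design choices

The repeated-training experiments (cross-validation, learning curve,
longitudinal runs) use a 128-px grid with 24 outline points per component —
the method scaled to half resolution — so that hundreds of model fits stay
desk-sized; single-fit accuracy checks use the full 256-px scale. The
fixed 2x2/6x6 filter windows are resolution-bound, so small-structure
refinement (medulla radius ≈ 4 px at 128) is only meaningful at full scale,
and the refinement-quality assertions run there.

The model used for the longitudinal experiment is trained on a pool that
includes generic zero-mean 10%-SD per-structure area variability. A pool
without it spans only the 4 generator modes, so a per-structure area change
is *out of model*: the clamped shape search cannot follow it and occasional
fits fail badly, attenuating recovered changes. A real training population
of a hundred-odd subjects spans tissue-proportion variability naturally;
the enriched pool mirrors that, with the PCA cut at 99.9% so the
low-variance proportion modes survive.

Twofold cross-validation runs on a 20-phantom cohort and the learning curve
on a 60-phantom pool with an 8-phantom test set — scaled-down analogues of
a full-scale design with ~100 training and ~20 test images. At these sizes
the curve is expected to rise
from n = 5 and be nearly flat beyond n ≈ 50, which is asserted
qualitatively (monotone within 0.01; the gain beyond 50 no larger than the
gain up to 50).

## Known limitations

* 2D single-slice only; no volumetric extension, no DICOM, no bias-field
  correction of real scanner data.
* Initialization is explicit: there is no automatic femur/gracilis
  detection. A poor initial pose (beyond roughly the ±8 px profile search)
  is not recovered.
* IMF/adductor separation inherits the threshold rule's sensitivity to
  intensity overlap between fat-like and muscle-like residual tissue; the
  "other intermuscular tissue" class absorbs only sub-threshold connected
  groups.
* The snake has no balloon or user-constraint forces; it refines an
  already-close boundary rather than finding distant ones.

## A minimal run

```{r example, eval = FALSE}
ds <- generate_cohort(12, seed = 1)
pre <- lapply(ds$subjects, function(s) preprocess_image(s$image)$fitted$pixels)
shapes <- lapply(ds$subjects[1:10], `[[`, "shape")
al <- align_shapes(shapes)
model <- train_pdm(al$aligned)
profiles <- train_profiles(pre[1:10], shapes)
tm <- list(model = model, profiles = profiles)

s <- ds$subjects[[11]]
init <- perturb_pose(init_pose_from_shape(model, s$shape), dx = 4, dy = -4)
seg <- segment_thigh(s$image, tm, init)
seg$areas
dice((s$labels == LABEL_CODES[["quadriceps"]]) + 0L,
     (seg$label_map == LABEL_CODES[["quadriceps"]]) + 0L)
```
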