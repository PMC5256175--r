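---
title: "Quantitative tractogram evaluation and fiber up-sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative tractogram evaluation and fiber up-sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractoval)
```

## The problem

Streamline tractography reconstructs white-matter fiber trajectories from
diffusion MRI, but the raw streamline count of a bundle is not a
quantitative measure: tractography algorithms over- and under-represent
fiber populations systematically, and a connectome or along-tract analysis
built on such a tractogram inherits those biases. `tractoval` implements a
validation loop around any tractography algorithm:

1. **Segment** bundles with waypoint-ROI pairs (fibers must traverse ROI 1
   then ROI 2; fibers meeting ROI 2 first are flipped so every bundle is
   consistently oriented).
2. **Up-sample** under-represented bundles by learning a generative model
   of the bundle's geometry and drawing new plausible streamlines.
3. **Optimize** the combined streamline set against the measured signal
   with a convex microstructure fit, assigning every streamline a
   non-negative contribution weight.
4. **Quantify the residual** — not just its size (NRMSE) but its
   *direction*: a fiber population missing from the tractogram leaves a
   directionally structured residual that points along the missing bundle.
5. **Profile** the error measures along each bundle and test differences
   between pipeline variants with a nonparametric permutation test.

Optimization runs strictly *after* segmentation and up-sampling: weights
assigned to a partial fiber population would otherwise compensate for
fibers that are added later, biasing both.

## Forward model: Stick-Zeppelin-Ball dictionary

Each voxel's b0-normalized signal is modeled as a non-negative combination
of compartment attenuations at b-value $b$ and gradient direction
$\mathbf g$:

* **Stick** (intracellular, one per streamline segment with tangent
  $\mathbf v$): $e^{-b d_\parallel (\mathbf g\cdot\mathbf v)^2}$ with
  $d_\parallel = 1.7\times10^{-3}\,\mathrm{mm^2/s}$;
* **Zeppelin** (hindered extracellular, one per voxel-level FOD peak):
  $e^{-b(d_\perp + (d_\parallel-d_\perp)(\mathbf g\cdot\mathbf v)^2)}$ with
  $d_\perp = 0.5\times10^{-3}$;
* **Ball** (isotropic partial volume, two per voxel):
  $e^{-bd}$ with $d \in \{1.7, 3.0\}\times10^{-3}$ (gray-matter-like and
  CSF-like).

The sparse operator $A$ stacks these profiles per voxel over all volumes;
an intracellular column is weighted by the streamline's segment length in
each voxel (b0 rows carry the geometric weight itself), so the fitted
weight has the meaning of a per-streamline cross-sectional contribution.
The fit solves

$$\arg\min_{x \ge 0} \lVert Ax - y\rVert_2^2$$

with forward-backward FISTA: step size $1/L$ with $L$ the largest
eigenvalue of $A^\top A$ from power iteration, projection onto
$x \ge 0$, and a monotone restart. Stopping follows a maximum of 500
iterations or a relative objective change below $10^{-4}$ — appropriate
for measured data, where the noise floor is reached much earlier. For
noiseless recovery experiments those defaults measure solver truncation
rather than model capacity, so the validation experiments below run the
solver to convergence (8000 iterations, no tolerance); this is a numerical
choice, not a change to the model. Columns are $\ell_2$-normalized
internally (weights rescaled on return): dictionary columns span orders of
magnitude in norm, and without this preconditioning FISTA's useful work
per iteration collapses.

## Residual analysis

The signal estimator $\hat s = A\tilde x$ (rescaled by the per-voxel b0)
gives a per-voxel NRMSE: RMSE over the diffusion-weighted directions
divided by the voxel's mean measured DW signal. The normalizer is a
convention choice (the mean keeps the map dimensionless and comparable
across voxels; the alternative, the signal range, is config-exposed).
Whether to average per voxel first or pool all voxel-direction pairs is
likewise unspecified in the framework this follows; the package computes
per-voxel NRMSE and reports the mean over the analysis mask.

The **error signal** is the element-wise squared residual
$s_{err,i} = (s_i - \hat s_i)^2$ per DW direction (no b0 sample exists in
it). Deconvolving a squared residual with a signal response is physically
unusual — the error signal is not an attenuation profile — but it is the
defined quantity and is implemented as such, with an `absolute` residual
switch for sensitivity checks.

* **Error FOD**: constrained spherical deconvolution of the error signal
  at $l_{max} = 8$, re-using the single-fiber response estimated from the
  *measured* signal (so error FODs are comparable with signal FODs). The
  response comes from a single-pass FA-threshold selection (FA $\ge$ 0.7,
  relaxed stepwise with a warning when too few voxels qualify, falling
  back to the highest-FA voxels on degenerate data), with each voxel's
  signal rotated so its principal eigenvector maps to $z$ and projected
  onto zonal harmonics.
* **Error FA**: a log-linear tensor fit of the error signal. A single
  shell cannot identify an $S_0$ intercept ($\sum_i g_i^2 = 1$ makes it
  collinear with the tensor trace), so the per-voxel reference is the
  maximum DW value; this keeps the error FA invariant to global scaling
  of the residual and is exact for noiseless single-compartment profiles.
  Negative eigenvalues are clipped to zero before the FA.

### CSD numerics and an inherent trade-off

The deconvolution follows the iterated regularized least-squares scheme:
an order-4 initial fit, then up to 50 iterations in which constraint-sphere
directions (300 points) whose amplitude falls below $\tau = 0.1\times$ the
initial mean amplitude are penalized with weight $\lambda$ until the
active set stabilizes. At a fixed $l_{max}$, non-negativity and data
fidelity genuinely compete: the exact non-negatively-constrained optimum
for a single-fiber signal (computed by quadratic programming) still has
~18% forward-projection error, because the band-limited delta's negative
ringing cannot be removed without distorting the fit. $\lambda$ is
therefore exposed: small values ($\le 0.25$) reproduce the band-limited
signal to < 5%, large values ($\ge 5$) push negative lobes below 1% of the
peak; the default $\lambda = 1$ sits between. Peak orientations — what the
pipeline actually consumes — are stable across this range (argmax within
2 degrees throughout).

## Fiber up-sampling

Each segmented bundle is resampled to 80 equidistant points per fiber
(240-dimensional descriptors); centered PCA truncated to 80 dimensions
retains > 99% of the variance on smooth bundles. New fibers are drawn from
the bundle-specific multivariate Gaussian in PCA space — diagonal
covariance with the component variances, which *is* the general Gaussian
since components are uncorrelated on the training data — and mapped back.
Candidates are rejected when their distance to the population-mean fiber
(sum over the candidate's 80 points of the distance to the nearest mean
point; deliberately asymmetric and point-discrete, with segment projection
as an option) exceeds the maximum such distance inside the initial
population, or when any point leaves the white-matter mask. Survivors are
re-segmented with the bundle's ROI pair, so synthetic fibers face the same
classification criteria as real ones. Generation proceeds in batches until
the target count is accepted or ten times the target has been drawn; both
the generated and accepted counts are reported, since the literature fixes
one number (10,000 per bundle) and reports ~75% subsequent classification
survival without stating which count is the invariant.

## Tract profiles and statistics

Bundle metrics are summarized at 100 nodes between the ROIs: each oriented
fiber is clipped to its first-ROI-1-hit-to-next-ROI-2-hit segment,
resampled, and weighted per node by $\exp(-D^2/2)$ with $D$ the
Mahalanobis distance to the node's point cloud (covariance regularized by
$10^{-6}\times\mathrm{tr}/3$). Scalar maps (NRMSE, error FA) are sampled
trilinearly at node points; SH coefficients are likewise interpolated
trilinearly before evaluation, because profiles are sub-voxel curves —
node-point evaluation rather than traversed-voxel-center evaluation is a
stated convention. The directional measures evaluate the error FOD on an
antipodally symmetric sampling sphere (~724 points by default): the
**longitudinal** amplitude is the maximum over directions strictly inside
a cone of half-angle $\pi/6$ about the fiber tangent (the opening angle is
read as the half-angle from the axis; angles use $\lvert\cos\rvert$ so a
symmetric FOD's two lobes count as one orientation), the **perpendicular**
amplitude the maximum outside; a direction exactly on the boundary counts
as perpendicular.

Group comparisons use a nonparametric max-statistic permutation test
(5000 permutations, $\alpha = 0.05$ by default): node-wise mean difference
over its standard error, null built from sign flips of subject differences
(paired) or label shuffles (unpaired), identity permutation included, and
the corrected p at a node is the fraction of permutations whose maximum
absolute statistic over all 100 nodes reaches the observed one — the
standard FWE scheme of permutation tools. Under a simulated null the
family-wise false-positive rate sits inside the binomial confidence band
around $\alpha$ (checked in the test suite with 500 repetitions of 200
permutations).

## The phantom: what it emulates, and what it does not

The generator emulates a single-shell acquisition — 64 directions spread
by electrostatic repulsion on a half-sphere at $b = 3000\,\mathrm{s/mm^2}$
plus one b0 volume, 2.3 mm isotropic voxels — over tube-shaped bundles:
cubic-spline centerlines swept with Gaussian cross-sectional offsets
($\sigma$ = radius/2) and smooth low-frequency per-fiber jitter. Waypoint
ROIs are one-voxel-thick slabs perpendicular to the centerline at 15% and
85% arc length; the white-matter mask is the traversed voxels dilated by
one voxel. Ground-truth per-voxel compartment fractions are derived from
the streamline segment lengths themselves and scaled so the densest voxel
reaches the target intracellular fraction (0.6 by default, with hindered
fraction 0.4 $\times$ intracellular and the remainder split 70/30 over the
two balls, summing to exactly 1 in every masked voxel). Because the
simulator and the dictionary share one kernel code path, a noiseless
phantom's signal lies exactly in the span of the ground-truth dictionary —
which is what makes the exact-recovery experiment a sharp test. Rician
noise uses two independent Gaussian channels with $\sigma = s_0/\mathrm{SNR}$.

What passing these tests does **not** show about real data: the phantom
has no partial-volume complexity beyond three compartments, no dispersion,
no EPI distortion, motion or eddy artifacts, no gray-matter anatomy, and
its bundles are geometrically simple tubes. Phantom results validate the
machinery (construction, optimization, error localization, statistics),
not in-vivo effect sizes.

## Validation experiment sizes

The packaged experiments use desk-scale problems chosen to exercise every
stage: crossing phantoms on $16^3$–$20^3$ grids with 60–200 fibers per
bundle, 500-fiber bundles for PCA checks, 10,000 generated candidates for
the up-sampling benefit experiment, and 500 null repetitions at 200
permutations for the calibration check. The missing-bundle and
up-sampling experiments run the genuine pipeline path (response estimation
from the data, CSD signal FOD, peak extraction, dictionary, FISTA,
residual CSD, Mahalanobis profiles) rather than shortcuts.

## Known limitations

* Single-shell kernels only (the scheme type permits multi-shell data, but
  zeppelin/ball diffusivities are not re-estimated per shell).
* Peak "uniqueness" has no canonical definition; the relative amplitude
  threshold (0.1) and minimum separation (25 degrees) are exposed
  configuration, not ground truth.
* Whole-brain (non-bundle-wise) up-sampling is deliberately unsupported:
  a single Gaussian in descriptor space is not a valid model of a
  whole-brain fiber population.
* The error-FOD of a *squared* residual inherits the squaring's scale
  distortion; interpret amplitudes comparatively (between pipeline
  variants, along a profile), not absolutely.
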