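---
title: "Automated cartilage morphometry and change-biomarker qualification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated cartilage morphometry and change-biomarker qualification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartMorph)
```

# Scope and model

cartMorph implements a fully automated analysis chain for femorotibial
cartilage morphometry from segmented 3D knee volumes, and the group-level
statistics used to qualify longitudinal cartilage thickness change as an
osteoarthritis progression biomarker:

1. **Synthetic knee generation** — phantoms with analytic ground truth
   stand in for clinical MRI, so every downstream stage is testable without
   any data download.
2. **Segmentation** — a compact 2D U-Net per tissue target (cartilage,
   subchondral bone area) and acquisition protocol, or a ground-truth
   oracle so the rest of the chain never depends on training.
3. **Post-processing** — per-plate bone-area atlas, rigid ICP registration,
   reconstruction of incomplete bone-area segmentations, cartilage-to-bone
   linking, and automated correction of gaps, disconnected fragments and
   implausible cartilage. No human is in the loop.
4. **Morphometry** — femoral region-of-interest (ROI) definition from
   automatically detected landmarks, per-plate mean cartilage thickness
   over the total subchondral bone area (tAB), denuded-area percentage
   (dAB), and compartment aggregation (MFTC = MT + cMF, LFTC = LT + cLF).
5. **Biomarker statistics** — standardized response mean (SRM = mean
   change / SD of change) with BCa bootstrap confidence intervals, Cohen's
   D (pooled-SD, noncentral-t interval), paired and two-sample t-tests,
   threshold-based progressor classification, and chi-square comparison of
   progressor proportions, assembled into a per-region report table.

The four cartilage plates are MT and LT (medial/lateral tibia) and cMF and
cLF (weight-bearing medial/lateral femoral condyle). Thickness is stored in
mm; change statistics are reported in µm.

# The phantom and what it emulates

The phantom is deliberately minimal anatomy: a flat tibial plateau (tilted
3° in the sagittal plane — real anatomy is never aligned with the voxel
grid, and an exactly grid-aligned interface would produce a systematic
half-voxel digitization bias that no real acquisition shows) and a
hemicylindrical femoral condyle whose cartilage spans a 175° arc from the
trochlear notch, through the inferior weight-bearing surface, to the
posterior condyle end. The arc is kept below 180° so that the normalized
anterior–posterior coordinate — measured along the straight notch→posterior
chord projected on the sagittal plane — is monotone over the surface, which
is what the chord-based ROI definition requires.

Each plate carries a continuous thickness field
$t(u, v) = t_0 + g\,(u - U/2) + \eta(u, v)$, with $u$ the
anterior→posterior plate coordinate (mm), $t_0$ the base thickness, $g$ an
AP gradient (mm/mm; negative by default, i.e. posteriorly thinner, matching
the usual pattern in the femur), and $\eta$ a smooth random field (sum of 8
random cosines; RMS amplitude 0.12 mm, correlation length 8 mm). Focal
lesions multiply the field by a residual fraction inside a disc; residual 0
produces a denuded area (full-thickness loss). Default base thicknesses
(MT 1.6, cMF 1.7, LT 2.0, cLF 1.9 mm) put the compartment sums near 3.3 mm
(MFTC) and 3.9 mm (LFTC), the range reported for knees with radiographic
osteoarthritis.

Acquisition protocols follow the two standard geometries: sagittal
DESS-like (0.36 × 0.7 × 0.36 mm; slices stacked medial–lateral; femoral
ROI 75 %) and coronal FLASH-like (1.5 × 0.31 × 0.31 mm; slices stacked
anterior–posterior; femoral ROI 60 %). The published +0.15 mm FLASH–DESS
thickness offset is modelled as a generator parameter of the cohort
simulator, not as an emergent property: the observation is an emulation
target, and the published attribution (partly the 60 % vs 75 % ROI) is not
quantified, so the two knobs are kept independent.

The **analytic region summary** is computed by dense midpoint quadrature of
the continuous field — never from the voxel data — so the voxel pipeline
can be checked against ground truth it does not share code with. Denuded
points contribute thickness 0 and stay in the denominator: the mean is
taken over the *total* subchondral bone area, which is the convention
consistent with emphasizing denuded-area accuracy (a plate that loses
cartilage must lose mean thickness).

The longitudinal cohort simulator draws per-knee 24-month changes from
per-stratum Gaussians; only means and SDs of change are published, so no
higher moments are modelled. Its defaults are the published medial-
compartment strata: −160 ± 223 µm in 157 radiographic progressors vs
−8 ± 110 µm in 165 non-progressors. In *exact-moment mode* each stratum
sample is affinely rescaled to match the requested mean and SD to machine
precision, which turns printed summary statistics into exact worked
examples. Regions are simulated as independent endpoints; the simulator
does not enforce MFTC = MT + cMF additivity across separately specified
regions.

**What passing tests do and do not show.** Phantoms have no osteophytes,
menisci, synovial fluid, MR contrast physics, motion or field
inhomogeneity; segmentation of the phantom's three-band intensity image is
far easier than real MRI segmentation. Tests therefore validate the
*measurement and statistics machinery* — geometry handling, ROI logic,
thickness integration, repair logic, statistical formulas — not clinical
segmentation performance.

# Numerical choices in the morphometry

* **Thickness metric**: per bone-area point, the chord length of the
  plate's cartilage along the outward surface normal, computed by
  integrating a trilinearly interpolated cartilage indicator along the ray
  (step = min(spacing)/6). Partial-volume interpolation places each
  boundary crossing halfway between the last inside and first outside
  voxel center, which is unbiased when boundary phases vary across a
  plate. Coarser, commensurate step sizes interact with voxel edges and
  were measurably biased; the fine step removes this.
* **Normals**: the negative gradient (in physical mm) of a smoothed bone
  indicator (two/three binomial passes per axis), averaged over the 6
  nearest neighbours. Small-neighbourhood plane fits — the obvious
  alternative — degenerate on strongly anisotropic grids (1.5 mm slices
  vs 0.31 mm in-plane), where all near neighbours lie inside one slice.
* **Covered/denuded decision**: a point is covered if its normal ray meets
  plate cartilage within 2.5 mm; rays that exit sideways (noisy normals at
  plate margins) are retried along the dominant axis of the normal. A
  Euclidean nearest-cartilage fallback is deliberately *not* used: it
  would erode detected denuded areas by its search radius.
* **Area weighting**: region means weight each point by the squared
  distance to its 7th nearest neighbour (clamped at twice the median), a
  local area estimate that removes the angle-dependent density of
  boundary-voxel sampling on anisotropic grids.
* **Landmarks**: circle fit (algebraic least squares) to the sagittal
  projection of the femoral bone area; the two angular extremes of the
  arc, averaged over a one-voxel band, are the landmarks; the anterior one
  is the trochlear notch. On a volume rotated 180° about the vertical axis
  the two consistently swap roles.
* **Degenerate inputs**: surfaces below 10 points (or with a degenerate
  sagittal projection) are rejected for landmark detection; ICP requires
  three non-collinear points; SRM and Cohen's D refuse zero-variance
  input; ROI fractions outside (0, 1] are rejected before any compute.

At FLASH-like resolution the 1.5 mm slice spacing digitizes a ~1.7 mm
curved femoral shell with a per-plate error of a few percent that does not
vanish with averaging (staircase phases are correlated across a plate).
The phantom-accuracy checks therefore run at DESS-like resolution, where
the pipeline tracks the analytic truth to within 2 %; FLASH-like geometry
is exercised for its ROI and offset logic. This mirrors the practical
situation: thin-slice protocols are the accuracy reference.

# Post-processing design

* **ICP**: point-to-point with singular-value-decomposition (Kabsch)
  updates; initialization tries the identity and principal-axes
  pre-rotations combined with centroid and bounding-box-center
  translations (the latter is robust to missing patches that shift the
  centroid); correspondences farther than 3× the median distance are
  trimmed each iteration, which prevents a planar plate with an edge
  defect from sliding into a shifted local minimum. Pure (untrimmed) ICP
  is available via `icpConfig(trimFactor = Inf)` and has a monotone
  residual trace. Defaults: 50 iterations, 10⁻⁴ mm tolerance.
* **Atlas**: surfaces aligned to the first mask's surface; corresponding
  points (nearest neighbour after alignment) averaged; centroid moved to
  the origin. With a single input the atlas is that surface, centered.
* **Reconstruction**: atlas points mapped into the knee frame that have no
  partner in the segmented surface within the correspondence radius
  (default 1 mm ≈ one voxel) are added; input points are never removed.
* **Autocorrection** operationalizes "gaps, disconnected fragments,
  implausible segmentations" as three explicit rules —
  the package's own concrete definitions, since no published
  operationalization exists:
  1. *Gaps*: bone columns whose outward ray meets no cartilage are gap
     candidates; connected candidate patches whose deepest point is farther
     from covered bone than `maxGap`/2 (plus one voxel) are genuine
     denuded areas and are left untouched — this is the scale test that
     separates segmentation slits from real full-thickness lesions.
     Qualifying gaps are bridged by morphological closing plus a
     normal-ray infill for oblique slits, with every added voxel kept
     below the local cartilage-surface ceiling (median entry + chord of
     the nearest covered columns) so repairs stay flush.
  2. *Fragments*: connected components other than the largest, below
     `minFragment` voxels (default 30), are removed; the largest component
     is always kept, so output is never empty.
  3. *Implausible cartilage*: voxels farther than `maxThickness` (default
     8 mm, box metric) from the plate's bone surface are cropped.
  The three rules are iterated to a fixed point, making the operation
  idempotent; every change is logged with voxel counts.

# Statistical choices

* **SD convention**: sample SD (n − 1) throughout; this is what reproduces
  the published SRM values from the printed moments.
* **BCa bootstrap**: the bootstrapped statistic is the SRM itself (not the
  mean change); bias correction from the bootstrap CDF at the point
  estimate, acceleration from jackknife skewness, 1000 iterations by
  default, fully seeded and bit-reproducible. The implementation is
  cross-checked against `boot::boot.ci` in the test suite.
* **Cohen's D interval**: inversion of the noncentral-t distribution (the
  standard reference method); a normal-approximation variant is available
  for cross-checking.
* **t-tests**: the published analysis names a paired t-test yet reports
  between-group p-values, so both are computed and labelled: within-group
  (change vs zero, the paired equivalent) and between-group (Welch by
  default).
* **Progressor thresholds**: applied to loss only (change < −threshold);
  the published per-region smallest-detectable-change values are cited but
  not printed in the source material, so thresholds are a required user
  input — the package deliberately ships none.
* **Report formatting**: SRM and Cohen's D to 2 decimals, changes to whole
  µm; cell-level failures (degenerate samples) propagate as NA without
  aborting the table.

# Problem sizes used in the checks

The test suite and the acceptance script size their simulations to run on
a single CPU in a few minutes: 10 random phantoms for the accuracy
criterion; one corrupted phantom (1.8 mm gaps, 3 fragments, 20 % bone-area
deletion) with a two-mask atlas for the repair criterion; 500 replicates of
n = 150 with 1000 bootstrap iterations for BCa coverage; 40 training slices
and 14 epochs for the U-Net smoke test (the loss-weight convention —
background at half the foreground weight — is asserted on the training
configuration directly). These sizes are the package's validation choices,
not statements about the sizes a production analysis would use.

# Known limitations

* The U-Net is a compact CPU implementation (three levels, one 3×3
  convolution per level, leaky-ReLU activations — plain ReLU units died
  irrecoverably under some seeds at the 0.01 learning rate — and
  coordinate channels appended to the input);
  it demonstrates the training recipe (weighted cross-entropy with
  background at half weight, Adam at learning rate 0.01 with moment
  decays 0.9/0.999) and the slice-wise prediction path, not
  state-of-the-art segmentation capacity. Because a single sagittal slice
  cannot distinguish the medial from the lateral side, the network
  predicts tissue classes (tibial/femoral cartilage or bone area) and the
  medial/lateral plate label is assigned from slice position relative to
  the volume midline.
* Phantom realism is limited to what the measurement logic needs (see
  above); no claim is made about performance on clinical MRI.
* The cohort simulator treats regions independently; compartment
  additivity holds only for regions measured by the image pipeline, not
  for independently specified per-region moments.
* FLASH-like volumes carry an irreducible slice-digitization error of a
  few percent for single-knee thickness (see the morphometry section).
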