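---
title: "Synthetic-CT dosimetry and rectal toxicity prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic-CT dosimetry and rectal toxicity prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the package addresses

MR-only prostate radiotherapy replaces the planning CT with a synthetic CT
(sCT) derived from MR, so that dose — and everything downstream of dose,
including normal-tissue complication probability (NTCP) used to guide
toxicity-driven adaptive treatment — is computed on surrogate electron
densities. `sctDose` quantifies how much the choice of sCT strategy
perturbs the dose-derived rectal toxicity predictors: the
Lyman-Kutcher-Burman (LKB) NTCP for grade-2 rectal bleeding and late
faecal incontinence computed from rectal dose-volume histograms (DVH), and
the two Buettner dose-surface-map (DSM) parameters (relative 51 Gy area,
relative lateral extent of the 61 Gy region).

Because clinical trial imaging is not redistributable, the package ships a
synthetic-data generator that emulates the study conditions — co-registered
pelvic CT and T2-like MR volumes at 2.5 mm slice thickness and 0.98 mm
in-plane pixels, closed-polygon contours, and a 60 Gy in 20 fraction
prostate plan — and runs the entire comparison on seeded phantoms. Checks
against published numbers are limited to quantities that are themselves
printed (per-patient HU accuracy summaries, Bland-Altman limits of
agreement); the clinical effect sizes of the original cohort are not
reproducible without the patient data and are not claimed.

# The pelvic phantom

`generatePhantom()` builds a labelled anatomy on a 40 x 128 x 128 grid at
(2.5, 0.98, 0.98) mm: an elliptical body with a 9 mm subcutaneous fat
shell, femoral-head cylinders with a 3.5 mm cortical shell around a spongy
core, a urine-filled bladder, an ellipsoidal prostate CTV (PTV60 and PTV48
at 5 and 9 mm margins), and a gently curved rectal tube posterior to the
prostate with randomly placed interior gas pockets (present with
probability 0.8). The CT is painted as tissue mean plus Gaussian noise
(default SD 10 HU); small high-density speckles inside the CTV emulate
calcifications and fiducial markers.

Two families of tissue means are provided:

* **Default (realistic)**: fat -98, muscle 45, spongy bone 250, cortical
  bone 1100, rectal gas -650 HU. These deliberately differ from the
  nominal stratification values so that a tissue-stratified sCT carries a
  realistic systematic HU bias, as it does on real anatomy.
* **Nominal (`nominalPhantomConfig()`)**: exactly the stratification HUs
  (-75, 0, 204, 1067, -500) with zero noise and no calcifications. On this
  phantom, stratifying the CT and substituting nominal values reproduces
  the CT identically, giving the end-to-end exact-recovery control.

The pseudo-MR maps tissues to T2-like intensities (fat and urine bright,
muscle mid, cortical bone dark), applies a smooth multiplicative bias
field (amplitude 0.15) and Rician noise (sigma 0.02). The mapping is
deliberately not an affine function of HU — bright fat has low HU, dark
bone has high HU — so learning MR-to-CT translation is a genuine,
non-trivial task; the body-wise MR-CT correlation is well below 0.9.

What the generator does *not* emulate: MR physics (no sequence simulation,
no distortion or susceptibility artefacts), population anatomy variation
beyond smooth jitter of organ sizes and positions, intra-organ texture,
and real registration error between modalities (the volumes are
co-registered by construction; `perturbRegistration()` adds a smooth
bounded displacement to the MR side when residual misregistration is to be
modelled). Passing tests on phantoms therefore demonstrates correctness of
the *pipeline*, and plausibility of relative method behaviour, not
clinical performance on patients.

All randomness flows from one integer seed through named sub-streams
(anatomy, gas, CT noise, MR bias, MR noise, calcifications), so phantoms
are bit-reproducible.

# Synthetic-CT strategies

* `makeSCT(ph, "bdw")` — bulk density: every body voxel 0 HU (water).
* `makeSCT(ph, "bdp")` — bulk density at the population mean body HU,
  computed by `populationMeanHU()` over a training cohort.
* `makeSCT(ph, "ts")` — tissue stratification: threshold classes
  (breakpoints -200 / -30 / 100 / 400 HU bracketing the five nominal
  values; the product the thresholds emulate does not publish its
  boundaries, so these are declared, configurable stand-ins), nominal-HU
  replacement, plus two reassignment rules: fat/spongy/cortical voxels
  inside the CTV (calcifications, fiducials) become muscle, and fat/muscle
  voxels inside the bone interior become spongy bone. Because a real
  stratified sCT is delineated on the MR side and carries residual
  deformable-registration error, the "ts" method displaces the class
  boundaries by a smooth random field capped at 3 mm.
* `makeSCT(ph, "ts_ct")` — the same stratification applied directly to
  the planning CT, with no misregistration: the registration-free control.
* `makeSCT(ph, "ai", model = m)` — U-Net inference from the phantom MR.

The spongy-bone reassignment needs to know the bone interior; the phantom
provides it as the `BONES_INTERIOR` structure. On real data this
compartment would come from the same segmentation that provides `BONES`.

# The deep-learning sCT

No deep-learning framework is assumed: the package contains a
self-contained CPU implementation (RcppArmadillo) of a 2D U-Net — per
level two 3 x 3 convolutions with ReLU, 2 x 2 max pooling, a
nearest-neighbour upsampling path with 3 x 3 up-convolutions and skip
concatenation, element dropout (rate 0.2) after each encoder and
bottleneck block, and a linear 1 x 1 output head. Four levels with base
width 32 doubling per level realize the published "32 layers within 4
levels" recipe; width and depth are configurable and the desk-scale
experiments use base widths 8 (single-phantom overfit runs) and 16 (the
cohort network) at 128 x 128.

Normalization follows the published recipe exactly: CT is clipped at
2000 HU and mapped by HU/3000 + 1/3 (the unique affine map taking
[-1000, 2000] onto [0, 1] consistent with the stated cut-off); MR is
divided by its per-volume 99.995th percentile, values above it left
unclipped. Training minimizes MSE on the normalized scale with Adam
(default learning rate 1e-4) and, by default, one whole-batch gradient
step per epoch, as in the original description. Whole-batch stepping is
extremely slow to converge at small scale — a few hundred Adam steps move
the parameters by at most a few hundredths — so the desk-scale protocols
use the mini-batch option (`batchSize = 1`, one Adam step per slice) and a
raised learning rate (1e-3 to 2e-3), calibrated once in pilot runs; the
architecture and loss are unchanged. Training is deterministic given the
config seed (weight initialization and dropout share one generator;
mini-batches are traversed in fixed order).

Two training designs are provided. `trainPhantomUNet()` overfits one
network per phantom on a subset of its own slices — the protocol used for
the self-consistency checks, where the question is how small the
dose/toxicity error of a voxel-wise sCT can be, not how well it
generalizes. `trainCohortUNet()` fits one network to slices pooled over a
phantom cohort, the analogue of the study's single-network design, and is
what the method-comparison experiments use. Its schedule has two guards,
both blind to dose and toxicity results: a few short seeded probe runs are
trained first and the one with the lowest eval-mode error on the training
slices is continued (occasional poor initializations otherwise produce
networks that confuse the dark-on-T2 classes — cortical bone, gas,
exterior air — and bias the recalculated dose); training then proceeds in
ten-epoch segments with one held-out slice per phantom, keeping the
checkpoint with the lowest held-out MSE and stopping once it has
plateaued. Early (underfit) checkpoints underestimate bone and bias dose
upward; late ones overshoot; the validated checkpoint is the principled
reading of "trained until the loss plateaued". The kernels run in single
precision, which halves memory traffic on CPU; training remains exactly
reproducible for a fixed seed.

# The dose engine

The engine is a declared simplification standing in for a clinical
algorithm, designed so that HU errors propagate to dose with realistic
density sensitivity; it makes no claim of agreement with any commercial
system. HU maps to relative electron density (RED) through a monotone
piecewise-linear calibration anchored at air (-1000, 0) and water (0, 1)
with representative densities at the nominal tissue HUs. Seven equispaced
coplanar parallel beams (emulating VMAT-era conformality at desk scale)
carry a conformal aperture — the beam's-eye-view projection of PTV60 plus
a 6 mm margin, in the lateral coordinate and cranio-caudally — smoothed by
a Gaussian penumbra (sigma 4 mm). Primary fluence is attenuated as
exp(-mu_eff * radiological path length), mu_eff = 0.005/mm (approximately
6 MV in water), with the radiological path integrated by 1 mm ray
marching with bilinear in-plane sampling. Scatter, dose-to-medium
conversion and beam divergence are out of scope.

Planning fixes the global fluence scale so the PTV60 voxel median equals
the 60 Gy prescription; that `muScale` is then frozen, and
`recalcFixedMU()` replays the identical engine on any sCT with no
renormalization — the fixed-monitor-unit contract. A bit-identical sCT
therefore reproduces the planning dose bit-identically, which the null
tests exploit. On every default phantom the resulting plan meets
PTV60 D95 >= 57 Gy, PTV60 median 60 +/- 0.1 Gy, PTV48 D95 >= 45.6 Gy and
rectal V60 < 0.05%.

Dose comparison uses 3D local gamma analysis (default 2%/2 mm over voxels
above 20% of the reference maximum): the search minimizes
sqrt((dose difference / (2% of local reference))^2 + (distance / 2 mm)^2)
over a sphere of radius 3 x DTA, sampling the evaluated dose trilinearly
at 0.5 mm steps, with an exact early-exit (offsets are visited in distance
order). The implementation is verified against an exhaustive-search oracle
on small grids.

# DVH, EQD2, gEUD and LKB NTCP

DVHs are voxel-count histograms (0.1 Gy bins, equal voxel volumes) with
the cumulative curve evaluated at bin edges. D-metrics take the largest
dose at which the linearly interpolated cumulative curve still covers the
fraction, right-continuous at jumps (so the median of a half-40/half-60
distribution is 60); V-metrics interpolate the covered fraction.
Fractionation is corrected per voxel to the equivalent dose in 2 Gy
fractions, EQD2 = D * (D/n_fx + a/b) / (2 + a/b) with a/b = 3 Gy, before
the DVH used for NTCP is built — both published parameter sets quote
a/b = 3, and per-voxel conversion (rather than per-DVH-bin) is the
default because it commutes with binning to within bin width. gEUD is the
power mean with exponent 1/n over bin centers; the LKB probability is
Phi((gEUD - TD50) / (m * TD50)) with (TD50, m, n) = (97.7 Gy, 0.27,
0.085) for grade-2 rectal bleeding and (105.0 Gy, 0.43, 1.0) for late
faecal incontinence. For n = 1 the gEUD reduces exactly to the DVH mean
dose.

# Dose-surface maps

For each axial rectal contour the posterior-most vertex is located (ties
broken toward patient-right), the contour is traversed clockwise as seen
from inferior — declared conventions; any fixed pair works because all
comparisons are within-convention — and resampled at 100 equal-arc-length
points (the published method samples surface pixels without stating a
count; 100 oversamples a ~40-pixel contour and is configurable), sampling
dose by bilinear in-plane interpolation. Rows (slices, inferior to
superior) by columns (circumference) are then interpolated bilinearly to
exactly 42 x 42, periodic in the circumferential direction, matching the
published choice of 42 elements for 2.5 mm slices. The interpolated map
is EQD2-converted cell-wise, then binarized at 51 and 61 Gy. The 51 Gy
parameter is the true-cell fraction of the 1764 cells. For the 61 Gy map,
clusters are labelled with 8-connectivity and circumferential wrap-around;
the largest cluster (ties: smallest centroid row, then column) is
summarized by its moment-equivalent ellipse — cells treated as unit
squares, adding 1/12 per-cell variance — and the lateral extent is the
ellipse's full projection onto the circumferential axis,
4 * sqrt(cov_cc), normalized by 42. The moment ellipse was chosen over an
iterative boundary fit for determinism; the published work does not
specify its fitting algorithm, nor the extent normalization, so both are
declared here (the /42 normalization makes the 0.591 cut-off read as a
fraction of circumference). An empty 61 Gy map yields the defined
degenerate fit with extent 0. Whether the original maps used a distinct
rectal-wall structure or the contoured surface is not stated; the
contoured surface is used.

# Statistics

Per method and metric the package reports the mean and sample SD (n - 1)
of per-case differences (absolute values for absolute-percent risk
errors), Bland-Altman 95% limits of agreement (mean +/- 1.96 SD, the
arithmetic that reproduces the published bounds from published means and
SDs), a two-sided paired t-test, and Shapiro-Wilk normality (Royston
approximation via `stats::shapiro.test`, n restricted to 3..50).
Zero-variance difference vectors follow a declared contract: p = 1 when
the mean is also zero (the identity method), p = 0 with a warning
otherwise. No multiple-testing correction is applied, matching the
original analysis; the report records the number of tests performed.
`buildReport()` is a pure function of its inputs: per-metric CSVs, a
summary JSON and box-plot figures, byte-identical on regeneration.

# Numerical choices and degenerate inputs

* Axis order is (slice, row, col) = (inferior-superior,
  posterior-anterior, right-left); indices are 1-based as everywhere in
  R, with voxel-center coordinates.
* Rasterization uses the even-odd rule on voxel centers; there is no
  inter-slice interpolation.
* Resampling fills outside-extent voxels with -1000 HU (CT), 0 (MR/dose)
  or FALSE (masks); nearest-neighbour for masks and labels.
* DVH/DSM tie-breaks and the gamma search discretization (0.5 mm, radius
  3 x DTA) are fixed and oracle-tested.
* Degenerate inputs have defined outcomes rather than silent behaviour:
  empty masks, all-below-threshold gamma, constant-zero MR volumes and
  sub-3-vertex contours raise errors; the empty binary DSM returns the
  zero ellipse.

# Problem sizes used by the test suite

The shipped experiments run at desk scale, chosen once: phantoms of
40 x 128 x 128 voxels; five-seed cohorts for the method-ordering and
plan-validity properties; U-Net widths 8 and 16 at 128 x 128 with one to
three thousand per-slice Adam steps; oracle comparisons on 8^3 grids. These sizes keep the full pipeline — including network training —
reproducible on a single CPU while exercising every code path of the
method.

# Known limitations

The dose engine omits scatter and divergence, so absolute dose accuracy
is not meaningful — only differences between sCT recalculations under a
fixed-fluence contract are. The phantom's tissue palette is piecewise
constant plus noise; a network trained on it cannot be expected to
transfer to real MR. DSM tolerances (0.374 / 0.591) originate from
conformal-era planning and are applied here only as decision thresholds
on the computed parameters. The DICOM dialect is a minimal
Explicit-VR-Little-Endian image-series reader/writer sufficient for
round-tripping volumes; structure sets and dose objects use the NIfTI +
JSON-contour dialect.
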