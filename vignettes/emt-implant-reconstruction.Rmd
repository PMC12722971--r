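---
title: "EMT-based implant reconstruction for HDR prostate brachytherapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMT-based implant reconstruction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emtrecon)
```

## The problem

In intraoperative high-dose-rate (HDR) prostate brachytherapy, hollow
needles are implanted under transrectal ultrasound (TRUS) guidance and a
stepping radioactive source dwells at discrete positions inside each
needle. The treatment plan needs an accurate *implant reconstruction*: the
3D path of every needle and its dwell positions in the planning (DICOM)
coordinate system. Manual TRUS-based reconstruction is slow and
user-dependent, and misreconstructions (wrong tip depth, swapped
needles) directly distort the delivered dose.

An afterloader with an electromagnetic tracking (EMT) sensor in its check
cable can measure each needle's path from the inside: the sensor is
stepped through the needle ("step-and-shoot"), stopping at fixed arc
increments starting at the most distal dwell position. `emtrecon`
implements the complete software chain from those raw EMT samples to an
adapted DICOM RT plan, two registration workflows, the evaluation
statistics used to characterize such a system, and a synthetic phantom
simulator that stands in for the tracking hardware.

## Coordinate conventions

All geometry is in millimetres, in right-handed DICOM patient axes:
x medio-lateral (+left), y anterior-posterior (+posterior), z
inferior-superior (+superior). Rotations are stored as unit quaternions
`(w, x, y, z)` canonicalized to `w >= 0` (so `q` and `-q`, which encode
the same rotation, have a single representative); matrices are derived
from quaternions only at application time. The only alternate
serialization is the row-major 12-number rigid 3x4 block used in
configuration files.

The simulator defines its own quaternion ordering (scalar first), since
tracker vendors differ; files written and read by this package are
self-consistent.

## Acquisition model

Raw step-and-shoot files are TSVs with columns
`channel step x y z [qw qx qy qz rx ry rz] [quality]`; step 0 is the most
distal position (needle tip side), and the optional pose columns carry the
6DoF reference-sensor pose measured alongside every sample.

Each (channel, step) group of repeated samples is reduced to a robust
center: the coordinate-wise median after discarding samples whose distance
to the group median strictly exceeds `outlier_mad_threshold` (default 3.5)
times the MAD of those distances. Two details matter:

* the MAD is taken **about zero** — the distances are already deviations
  from the robust center, so centering the MAD on their own median would
  make the scale estimate collapse for the handful of samples (3-10)
  a step-and-shoot stop typically yields;
* ties are kept (only strict exceedances are rejected), so a group of
  identical samples is never thinned.

A vendor quality indicator, when present, gates samples below 0.5 before
aggregation; groups left empty by the gate or the outlier rule are hard
errors naming the channel and step. Consecutive aggregated points whose
chord length falls outside [0.5, 1.5] x the nominal 5 mm step raise a
warning flag on the series but do not stop the pipeline.

## Registration

**Workflow 2 (reference sensor).** A 6DoF reference sensor is integrated
in the template holder; its pose relative to the DICOM frame
(`TemplateCalibration`) is fixed by the holder design and read from the
run configuration. With the measured sensor pose `P` in the EMT frame
(per-sample poses are averaged: translations by the mean, rotations by the
chordal mean of canonicalized quaternions, renormalized), the EMT-to-DICOM
mapping is the exact composition `calibration o inverse(P)` — there is no
fitting step, so noiseless inputs register to machine precision.

**Workflow 1 (point correspondence).** When no reference sensor is
available, the EMT measurement points are matched to an existing
TRUS-based (pre)reconstruction by (channel, step) and the least-squares
rigid transform is found by the closed-form SVD (Kabsch) solution on
centered coordinates, with a reflection correction guaranteeing a proper
rotation. The RMS of post-fit pair distances is reported. Collinear
correspondence sets are rejected (no unique rotation exists).

On noiseless data the two workflows agree to machine precision, which the
test suite asserts; this is the package's workflow-equivalence invariant.

## Needle reconstruction

The registered measurement points of each needle are interpolated by a
cubic spline per coordinate against the cumulative chord-length
parameter. End conditions are the cubic-extrapolation kind of Forsythe,
Malcolm and Moler (as in `stats::splinefun(method = "fmm")`): each end
cubic is the polynomial through the outermost four points. This choice is
deliberate: clinical needles bow gently and nearly quadratically, and FMM
ends reproduce a quadratic path *exactly*, whereas natural (zero second
derivative) ends flatten the curvature in the end segments and bias the
tip-side arc length by about 1e-6 mm over 50 mm — enough to matter for
the package's own micrometre-level identity checks, and with no
compensating benefit at these low curvatures. With exactly two points the
path is the straight segment.

Arc length is computed by adaptive quadrature of the parametric speed
(tolerance 1e-10 per segment) and inverted by bracketed root finding, so
positions at prescribed arc offsets are accurate to well below 1e-6 mm.
Dwell positions sit at `tip_offset + k * step` (default: tip-anchored,
5 mm) from the distal tip, matching the measurement protocol that starts
at the most distal dwell; control points are resampled at a configurable
arc spacing (default 5 mm) plus the exact proximal end, standing in for
the treatment planning system's unpublished control-point formalism.
When a baseline plan fixes the dwell count per channel, a measured path
that falls a fraction of a step short of the nominal grid (a noise
effect) has its most proximal dwell clamped to the path end rather than
failing the run.

The free length (arc length from the template-plane crossing to the
proximal end) is computed only as a verification quantity and only when
the measured path actually crosses the plane.

## RT plan I/O

No DICOM library ships with this package's R dependency stack, so
`emtrecon` includes a purpose-built minimal DICOM codec: part-10 files,
Explicit VR Little Endian, with full sequence support (defined and
undefined lengths). It covers the brachy RT Plan and RT Structure Set
subsets the workflow touches and carries everything else opaquely through
read/write round trips. Files written by the package are read back
bit-faithfully in the fields that matter (geometry to better than 1e-6 mm
via shortest-round-trip decimal strings, time weights as verbatim decimal
strings), and are verified in the test suite against an independent DICOM
implementation.

Dwells are encoded in the conventional paired-control-point form: each
dwell is two control points sharing a 3D position, with the cumulative
time weight flat across travel and stepping across the dwell. The dwell
time of dwell *j* is `(w[2j] - w[2j-1]) / final_weight * channel_total_time`.
`replace_reconstruction()` swaps only geometry (positions, relative
positions, channel length) into a plan and never touches a time-related
field — the adapted plan delivers the clinical dwell times at the
corrected positions, which is the entire point of the workflow. Channel
dwell counts must match exactly; mismatches are hard errors rather than
silent truncations.

## Dosimetry

Dose is computed with the 1D TG-43 point-source formalism:

$$D(\mathbf{r}) = \sum_j S_K \,\Lambda\, \left(\frac{r_0}{r_j}\right)^2 g(r_j)\,\phi_{an}\, t_j$$

with `S_K` the reference air-kerma rate (default 40820 U, a typical fresh
Ir-192 source), `Λ = 1.109 cGy/(h U)`, a constant anisotropy factor 0.98,
and a packaged *synthetic generic* radial dose function `g(r)` shaped like
published HDR Ir-192 consensus curves (log-linear interpolation,
`g(1 cm) = 1`). Distances below 0.5 mm are capped. This engine exists to
*compare* reconstructions of the same plan — systematic source-model
errors cancel in the difference — and is explicitly not a commissioned
clinical dose calculation.

Structures are rasterized by even-odd polygon fill per contour plane with
voxel-center inclusion and half-open plane slabs. V100% is the fraction
of structure voxels at or above the prescription; hot-spot metrics
DX cm³ (X = 0.1, 1, 2) take the minimum dose of the hottest X cm³ with
linear interpolation at the cut boundary, which stabilizes the 0.1 cm³
metric on 1-2 mm grids. Differences between plans are reported in the
conventional units: percentage points of structure volume for V100 and
percent of prescription for the D metrics. The prescription is always an
explicit input — no default is silently applied.

## Evaluation statistics

Two reconstructions are compared strictly by (channel, dwell index) — the
afterloader's channel link removes assignment ambiguity, so
nearest-neighbour matching is deliberately absent. Per-dwell Euclidean
distances are summarized by mean ± 2SD and median (range). Dwell-time
weighting appears only in displays, never in statistics.

Reproducibility over repeated reconstructions is expressed at k = 2 (two
standard deviations, ~95% coverage): deviations of each repeat from the
per-dwell mean position are pooled, and the per-axis k2 is twice the
pooled within-dwell standard deviation computed on
`n_dwells * (n_repeats - 1)` degrees of freedom. The degrees-of-freedom
correction matters: with 4 repeats, a naive SD of mean-subtracted
deviations underestimates sigma by ~13%, while the within-group estimator
is unbiased — the test suite verifies the calibration (mean per-axis k2
within 10% of 2 sigma) by simulation. The radial k2 is defined as twice
the SD of the pooled Euclidean deviations from the per-dwell mean; since
"radial" pooling is genuinely ambiguous in the field, this definition is
fixed and documented here, and per-axis and radial values are always
reported separately. Observer averaging (the reference reconstruction of
an interobserver study) is the per-dwell coordinate-wise mean, with the
same k2 machinery quantifying the spread.

Paired significance tests are the two-sided Wilcoxon signed-rank and
paired Student t. The signed-rank test is exact for up to 25 nonzero
pairs via distribution counting over all 2^n sign assignments (the
convolution also handles midranks from ties); beyond that a
tie-corrected, continuity-corrected normal approximation is used. All-zero
differences are reported as p = 1 with a flag rather than an error. The
implementation is checked against brute-force enumeration (n <= 12) and
against `stats::wilcox.test` on untied data.

## The phantom simulator

The simulator replaces the clinical hardware and defines the study
conditions under which the package's claims are tested:

* **Implant**: 4 needles (a 13 x 13, 5 mm-pitch template hole array;
  holes drawn near the array center), inserted along +z with the template
  plane at z = 0, tips at 55 mm, and quadratic lateral bows vanishing at
  the proximal end with tip deflection drawn uniformly up to 1.5 mm.
  Dwells sit at 5 mm arc spacing over 50 mm from the tip — 11 per needle,
  the step-and-shoot protocol's geometry.
* **EMT session**: a random rigid EMT-to-DICOM frame offset (uniform
  random rotation, translations up to ±150 mm), per-sample Gaussian
  sensor noise (default sigma 0.05 mm per axis), and a per-sample noisy
  reference pose (0.05 mm / 0.5 mrad) consistent with the frame offset
  and the fixed template calibration. Repeat sessions re-randomize the
  frame offset, emulating afterloader reconnection and field-generator
  repositioning between repeats.
* **TRUS observers**: dwell positions plus anisotropic noise (defaults
  0.2, 0.2, 0.05 mm — lateral localization in ultrasound is harder than
  depth, which is constrained by free-length measurement), with
  injectable, logged gross errors: tip-depth errors, channel swaps, and
  lateral (wrong-hole) misassignments.
* **Anatomy and plan**: a prostate-like ellipsoid around the implant, a
  central urethra cylinder guaranteed to contain no dwells, a superior
  bladder and a posterior rectum, plus a clinical-style plan carrying the
  ground-truth geometry with positive dwell times drawn once (uniform
  5-15 s, rounded to 0.1 s) and exact 6-decimal cumulative weights so
  files round-trip losslessly.

Noise magnitudes are deliberately *not* taken from any published
measurement results (that would be circular when the simulated studies
are compared against them); they are order-of-magnitude assumptions,
stated here, all overridable. Every generator output is deterministic per
seed (R's default Mersenne-Twister, one `set.seed` per operation).

What the simulator does **not** model: electromagnetic field distortion
near metal, ultrasound image formation, tissue deformation and
needle-tissue interaction, or template-holder aging. Passing tests
therefore demonstrate the correctness of the *software chain* — parsing,
robust aggregation, registration algebra, spline geometry, DICOM
encoding, dose bookkeeping, statistics — under idealized sensor physics,
not the hardware accuracy of any real tracking system.

## Numerical choices

* Quadrature and arc-length inversion tolerances: 1e-10 (mm scale);
  quaternion unit-norm tolerance 1e-9 with hard rejection at 1e-3 for
  measured poses.
* Rigid fits reject configurations whose centered point cloud has a
  second singular value below 1e-9 x the largest (collinearity).
* DICOM decimal strings use the shortest representation that reproduces
  the value to 1e-9 within the 16-character DS limit.
* Degenerate inputs fail loudly: empty raw files, missing pose columns,
  zero chords, non-monotone time weights, dwell-count mismatches,
  zero-extent grids, structures rasterizing to zero voxels.

## Problem sizes used in the checks

The shipped verification suite runs the full chain on the 4-needle,
44-dwell phantom; statistic calibrations use 200 simulated four-repeat
studies per noise level and 500 null replicates for the signed-rank
uniformity check; the closed-form sphere DVH comparison uses a 0.5 mm
grid. These sizes give sub-percent Monte-Carlo error on every calibrated
quantity while keeping a complete run in the order of a minute.

## Known limitations

* The dose engine is 1D TG-43 with a generic source curve — adequate for
  reconstruction comparisons, not for absolute dosimetry.
* The DICOM codec reads only Explicit VR Little Endian and the modules
  the workflow touches; it is not a general conformance implementation.
* Dwell-count mismatches between a baseline plan and a reconstruction are
  treated as errors, not resolved; dwell-time (re)optimization is out of
  scope by design.
* Continuous-motion (non-step-and-shoot) acquisition protocols are not
  supported.
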