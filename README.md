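# emtrecon

Automated implant reconstruction for intraoperative high-dose-rate (HDR)
prostate brachytherapy from electromagnetic tracking (EMT) measurements.

In TRUS-guided HDR prostate brachytherapy, the treatment plan needs the 3D
path and dwell positions of every implanted needle in the DICOM planning
frame. Reconstructing them manually from ultrasound is slow and error
prone — wrong tip depths and swapped needles translate directly into
misdelivered dose. An afterloader with an EMT sensor in its check cable
can instead measure each needle from the inside with a step-and-shoot
protocol (11 stops spaced 5 mm apart, starting at the most distal dwell
position, covering 50 mm). `emtrecon` turns those raw measurements into a
registered, dwell-position-bearing RT plan, and provides the machinery to
evaluate such a system:

* **Acquisition** — parsing of raw step-and-shoot sample streams and
  robust per-point aggregation (coordinate-wise median with MAD outlier
  rejection).
* **Registration** to the DICOM frame, two ways: *Workflow 2*, exact
  direct registration via a template-mounted 6DoF reference sensor
  (`T = calibration ∘ pose⁻¹`); *Workflow 1*, closed-form least-squares
  rigid fit (SVD/Kabsch, reflection-corrected) to a TRUS-based
  pre-reconstruction.
* **Needle reconstruction** — interpolating cubic splines
  (chord-length parameterized), arc-length-exact control points and dwell
  positions anchored at the distal tip, free-length verification.
* **DICOM RT Plan / RT Structure Set I/O** — a minimal Explicit-VR
  Little-Endian codec; `replace_reconstruction()` swaps channel geometry
  into a clinical plan while keeping every dwell time bit-identical.
* **Dosimetry** — a 1D TG-43 point-source engine
  (`D = Σ S_K Λ (r₀/r)² g(r) φ_an t`) with V100% and D0.1/1/2 cm³
  hot-spot metrics for plan comparison.
* **Evaluation statistics** — per-dwell Euclidean distances matched
  strictly by (channel, index), k = 2 reproducibility with unbiased
  within-dwell pooling, observer averaging, exact Wilcoxon signed-rank
  and paired t tests.
* **Phantom simulator** — ground-truth implants, noisy EMT sessions with
  reference poses, TRUS observers with injectable gross errors (tip-depth,
  channel swap, lateral misassignment), synthetic anatomy and plans; it
  replaces the tracking hardware so the whole chain is testable.

## Worked example

Simulate a 4-needle phantom, a noisy EMT session and a clinical-style
plan, run the fully automated workflow, and compare the adapted plan with
the baseline:

```r
library(emtrecon)
dir <- tempfile(); dir.create(dir)
gt <- generate_implant(phantom_spec(seed = 7))
simulate_emt_session(gt, noise_spec(), n_samples_per_point = 5, seed = 7,
                     path = file.path(dir, "emt_session.tsv"))
generate_anatomy_and_plan(gt, seed = 7,
                          plan_path = file.path(dir, "plan.dcm"),
                          struct_path = file.path(dir, "structures.dcm"))
res <- run_workflow2(list(
  paths = list(raw_emt = file.path(dir, "emt_session.tsv"),
               plan = file.path(dir, "plan.dcm"),
               structures = file.path(dir, "structures.dcm"),
               out_dir = file.path(dir, "run")),
  registration = list(
    method = "reference_sensor",
    calibration = rigid_to_matrix12(gt$calibration$ref_in_dicom)),
  dosimetry = list(grid_spacing = 2, prescription_gy = 8.5),
  seed = 7))
res$agreement
#> agreement over 44 dwells: ED 0.06 (+/- 0.06) mm, median 0.05 (0.02 - 0.11) mm
#>   x: 0.00 (+/- 0.06) mm
#>   y: -0.01 (+/- 0.06) mm
#>   z: -0.02 (+/- 0.10) mm
```

The adapted plan's 44 dwell positions sit a few hundredths of a
millimetre from the baseline geometry (which here *is* the simulated
truth), with per-axis biases consistent with zero — the reconstruction
chain adds essentially no error beyond the simulated sensor noise. The
run directory also contains `dwell_comparison.tsv`, `dvh_comparison.tsv`
(V100 deltas in percentage points, D-metric deltas in percent of the
8.5 Gy prescription) and a `manifest.json` with input hashes and stage
timings.

The four-repeat reproducibility protocol (each repeat re-randomizes the
EMT frame offset, as reconnecting the afterloader would):

```r
repro_study(gt, noise_spec(), n_repeats = 4, seed = 7)$report
#> reproducibility (k = 2) over 4 repeats x 44 dwells:
#>   per-axis: x 0.055, y 0.055, z 0.069 mm; radial 0.033 mm
```

With the default 0.05 mm sensor noise and 5 samples per point, repeated
reconstructions agree to better than a tenth of a millimetre at k = 2 on
every axis.

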