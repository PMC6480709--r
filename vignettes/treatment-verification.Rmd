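---
title: "Treatment verification from MLC dynalog files: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treatment verification from MLC dynalog files: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynaverify)
```

## The problem

During a dynamic radiotherapy delivery (VMAT or sliding-window IMRT) the
Varian MLC controller writes a *dynalog* record every 50 ms (20 ms on
TrueBeam): beam status, hold-off flag, segment number, gantry angle, jaw
positions, the cumulative fraction of delivered dose, and — crucially — the
*expected* and *actual* position of every leaf. These files are a
high-resolution record of the aperture sequence the patient actually
received, independent of the treatment planning system. `dynaverify`
implements the analysis chain that turns a dynalog pair into a verdict about
the delivered dose: plan reconstruction, controlled error magnification, and
quantitative dose-agreement statistics.

## Conventions

Leaf positions are kept in cm at the isocenter plane, with each leaf's
coordinate increasing in its *opening* direction. The physical bank-A edge
sits at `-posA` and the bank-B edge at `+posB`, so the aperture width of an
opposed pair is `posA + posB` and subtracting a positive quantity from
either coordinate always shrinks the aperture. This convention is what makes
the absolute-value mode of error magnification (below) guaranteed
aperture-shrinking. Leaf errors are reported in mm, matching clinical QA
practice: `eps = P_e - P_a` (expected minus actual).

Two file dialects ship with the package. The `clinac` dialect stores
positions as integers in hundredths of a millimetre (the controller's own
resolution), gantry in tenths of a degree and cumulative dose on a 0–25000
counter; the `native` dialect prints full-precision decimals and is used for
synthetic data interchange. A dialect descriptor isolates this format drift
from the algorithms; `parse_bank_file()` / `write_bank_file()` are exact
inverses under both dialects (for `clinac`, on values quantized to its
resolution, which is all the controller can produce).

## Plan reconstruction

`reconstruct()` turns the merged A/B record stream into a deliverable beam.
Three sampling strategies are provided:

* **UR** (uniform): records at a fixed time interval, minimum one tick, in
  which case every record becomes a control point.
* **PSR** (per-segment): only records at which the stored segment number
  changes. Since a segment is the transition interval between two original
  control points, this reproduces the original plan's control-point count
  whenever every transition was logged.
* **PSR-ED** (PSR with error detection): the PSR records plus every record
  where some leaf error exceeds a tolerance. Tolerance 0 selects all
  records; a tolerance at or above the maximum leaf error reduces to PSR.

Control points take cumulative meterset weight from the recorded dose
fraction, renormalized so the last selected record has weight 1, and MLC
positions from either the expected or the actual stream — the two
reconstructions differ in nothing else, which is what makes their dose
difference attributable to leaf misplacement alone.

Decisions the record format forces but does not dictate:

* The first and last eligible records are always included, so every
  reconstructed beam has well-defined weight-0/weight-1 endpoints.
* Beam-hold records deliver no dose; they are never selected by PSR/PSR-ED
  and trigger a warning when a UR grid lands on them.
* In PSR-ED, the over-tolerance test is strict (`|eps| > t`) so that
  `t >= MLE` reduces exactly to PSR; `t = 0` is special-cased to select
  every record rather than only records with nonzero error.
* Records with no dose increment produce zero-weight segments; they are
  retained (harmless to dose) rather than pruned.

## Error magnification

Sensitivity studies rescale the recorded errors up to a target maximum
error Σ:

$$P'_a = P_e - f\,\epsilon, \qquad f = \Sigma/\mathrm{MLE},$$

where MLE is the maximum absolute leaf error found in the files before
scaling. Two modes: *signed* (conserve the sign of each error) and
*absolute* (replace ε by |ε|, forcing every altered leaf to define a
smaller aperture — the signature of a systematic one-directional failure
such as a stuck carriage). Errors at or below a floor of 0.01 mm — the
position resolution of the log itself — are not magnified. Because expected
positions are untouched and the largest error is by construction above the
floor, the magnified field has MLE exactly Σ, and in signed mode the RMS

$$\mathrm{RMS} = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N}(P_{e,i}-P_{a,i})^2}$$

scales by exactly *f* whenever all errors exceed the floor. The default
sweep is Σ ∈ {2, 3, 4, 5, 10, 30} mm.

Magnified positions are clipped to the leaf travel range (±20 cm; the count
of clipped values is attached to the result). Opposed-leaf *crossing* after
magnification is deliberately **not** repaired in the dynalog itself: the
invariant MLE = Σ is what calibrates the sweep, and moving positions to
enforce a non-negative gap would silently break it. Instead the crossing is
handled where it is physically meaningful — the dose engine treats a pair
with non-positive gap as closed. The aperture a crossed pair delivers is
zero either way; the log keeps the faithful magnified coordinates.

## Dose-agreement statistics

**DVH percentage of agreement (PA).** For two cumulative DVHs on a common
bin grid (width Δd),

$$\mathrm{PA} = 100\left[1-\frac{\delta_A}{\max(A_1,A_2)}\right],\qquad
\delta_A = \Delta d \sum_{i=0}^{N} |V_{1,i}-V_{2,i}|,$$

with $A_k = \Delta d \sum_i V_{k,i}$. PA is symmetric, 100 exactly for
identical histograms and 0 against an all-zero histogram. DVH volumes are
relative (percent of structure volume) so PA is comparable across
structures; the default bin width is 1/1000 of the reference maximum.

**Gamma pass rate (GPR).** The standard dose-difference /
distance-to-agreement composite, globally normalized to the reference
maximum over the body. The evaluated grid is tri-linearly interpolated on a
search lattice of step `dta/10` within a radius `3*dta` (both configurable);
the minimum search is exact on that lattice — offsets are visited in
increasing distance and abandoned only when the pure distance term can no
longer improve the current minimum, so the optimized C++ path returns
bit-identical gamma values to an exhaustive scan. Voxels below a low-dose
cutoff (default 10 % of the normalization dose) are excluded.

**Systematic differences (α/Δ).** For dose pairs that carry per-voxel
statistical uncertainty, the per-voxel systematic magnitude is estimated by
quadrature subtraction, $s_i = \sqrt{\max(0, d_i^2 - \sigma_{1,i}^2 -
\sigma_{2,i}^2)}$, and reported as α/Δ pairs: α is the percentage of
analyzed voxels with $s_i$ at least Δ percent of the reference maximum.
The analysis domain is the body region above 30 % of the maximum reference
dose. This voxelwise quadrature estimator follows the standard reporting
convention for separating systematic differences from Monte Carlo noise,
but it is a deliberately simple variant: it suppresses pure noise well when
the uncertainty is a few times smaller than the Δ of interest (the package
tests use 0.3 % noise against Δ = 1 %), and it is not claimed to match any
specific published estimator in detail.

## The toy dose engine

`compute_dose()` is **not** a radiation transport code and makes no claim
of dosimetric realism. It exists so the verification pipeline is
exercisable end to end with the dose responding to aperture changes in the
physically sensible direction. Per control-point interval it builds a binary
MLC/jaw aperture at the isocenter plane, blurs it with a Gaussian penumbra
(σ = 3 mm), projects it through the phantom as a cone diverging from a
source at 100 cm, attenuates exponentially with depth (0.04 cm⁻¹, roughly a
6 MV percent-depth-dose slope) and accumulates with the interval's meterset
weight. The engine is linear in meterset, additive over beams, and — the
property the sensitivity analysis rests on — pointwise monotone: shrinking
any single leaf opening never increases dose anywhere. Optional seeded
Gaussian noise emulates Monte Carlo statistical fluctuation and populates
the per-voxel σ used by the α/Δ analysis. Heterogeneity, scatter,
tongue-and-groove, interleaf leakage and absolute calibration are all out
of scope.

## The synthetic study case

The generator defaults define the package's reference study conditions:

* **Plan**: one 178-control-point arc spanning 358° (crossing the 0° wrap),
  60 leaf pairs of 0.5 cm, 400 MU; a breathing window (half-width
  1.3–3.7 cm) slides across a round ~6 cm field. Cumulative weights are
  uniform.
* **Delivery**: 9 records per control-point segment at the 50 ms tick —
  1594 records, the regime of a clinical arc (~1500 records for ~180
  control points). The record grid aligns with segment boundaries, so PSR
  on an error-free delivery recovers the original control points exactly
  (up to the 0.01 mm recording quantization).
* **Errors**: Gaussian σ = 0.5 mm for two-directional errors (typical
  recorded dynalogs are a few tenths of a millimetre RMS); unidirectional
  mean 1 mm for one-directional failures; drift at 0.05 mm/s.
* **Phantom**: 41×41×21 voxels at 0.5 cm; ellipsoidal body, 2.5 cm-radius
  spherical PTV at the isocenter, 3 cm cubic OAR 4.5 cm lateral.

What passing tests on this case do show: the statistics behave as designed
(PA/GPR identities, exact magnification calibration, reconstruction-mode
set relations), and the qualitative sensitivity structure — one-directional
(aperture-shrinking) errors degrade PTV PA strictly monotonically with Σ,
while sign-preserving errors of the *same RMS* perturb the DVH far less —
emerges end to end. What they do not show: clinical magnitudes. Absolute
PA/GPR values depend on the toy engine and the synthetic anatomy and are
not comparable to values obtained with a Monte Carlo dose engine on patient
CTs.

## Numerical choices

* Gantry interpolation is circular (shortest arc, via unwrapping), so VMAT
  arcs crossing 0° densify and resample correctly.
* `densify_plan()` inserts control points on a uniform cumulative-weight
  grid, keeping all originals; linear interpolation conserves each leaf's
  weight-integral, so densification never changes the meterset-weighted
  mean aperture.
* Aperture rasterization uses strict interval bounds, so a zero-gap
  (parked or crossed) leaf pair contributes no fluence at all.
* The DICOM codec writes explicit-VR little-endian with defined lengths and
  fresh SOP instance UIDs per write; everything else is deterministic.
  RT Dose pixels are 32-bit scaled integers (relative quantization ~5e-10).
* DVH bins extend one bin beyond the maximum dose so every cumulative
  histogram ends at zero; PA clamps to [0, 100] against floating-point
  undershoot.
* Degenerate inputs fail loudly: empty masks, selections of fewer than two
  records, magnification of an error-free field, gamma with no eligible
  voxels, and dose grids without σ in the α/Δ analysis are all errors, not
  silent results.

## Problem sizes

The shipped tests run the full case (1594 records, 35k voxels) for the
end-to-end sensitivity check and smaller instances (10–30 control points,
~20k voxels, grids of ≤ 512 voxels for the exhaustive gamma oracle)
elsewhere; the whole suite completes in about a minute and a half on one
core, and `scripts/acceptance.R` in under a minute.

## Known limitations

* Trajectory logs (TrueBeam `.bin`) are not read; only the text dynalog
  dialects above.
* The per-record jaw positions are copied, not modelled; couch and
  collimator dynamics are ignored.
* The α/Δ estimator is the simple quadrature variant described above.
* The toy engine's verdicts calibrate the *pipeline*, not clinical
  tolerances; the PA ≤ 99 % failure threshold default is a convention to be
  recalibrated against a real dose engine before clinical use.
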