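---
title: "Retrospective rigid-motion correction for 3D multishot MRI: models and methods"
author: "mocoMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrospective rigid-motion correction for 3D multishot MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mocoMRI)
```

## The problem

A 3D multishot Cartesian brain acquisition samples the `ky`-`kz`
phase-encode plane over minutes, one shot (a fixed number of lines, the
turbo factor) at a time. Subjects move; rigid head motion between shots
turns into ghosting and blurring in the reconstruction. The package
implements a navigator-free retrospective correction: the acquisition is
partitioned into *segments* (a whole number of consecutive shots, each
treated as one motion state), each segment's tiny fraction of k-space is
reconstructed into an approximate volume, the segment volumes are aligned
by groupwise rigid registration, and the estimated per-segment transforms
enter the forward model of a final motion-corrected CG-SENSE
reconstruction. An alternating image/motion optimizer over the same
forward model is included as the classic baseline.

## Forward model

The acquisition is modelled as `y = A x` with

    A = M F S C_theta

* `C_theta` - rigid transform of the image into the segment's motion
  state, trilinear interpolation; rotations are extrinsic x-y-z Euler
  angles in degrees about the grid centre (0-based index `floor(n/2)`),
  translation in mm applied after rotation. The package implements the
  exact transpose of the interpolation operator as the adjoint, so the
  operator passes the adjoint dot test to machine precision and CG theory
  applies (an approximate inverse-transform adjoint is not used).
* `S` - multiplication with complex coil-sensitivity maps, RSS-normalized
  so the squared magnitudes sum to one over the support.
* `F` - centred orthonormal 3D FFT (DC at index `floor(n/2)` 0-based per
  axis); Parseval's identity holds exactly, which fixes the scaling of all
  residuals.
* `M` - selection of the segment's `(ky, kz)` lines at all readout
  positions.

Motion is piecewise constant per shot (the finest granularity the
segment model can express); `simulateAcquisition()` encodes each shot
from the volume moved into its shot's state and assembles segments, which
makes the simulator and the reconstructor share one operator
implementation (their consistency is asserted by tests rather than
assumed).

## Sampling order

`generateDisorderScheme()` builds a random-checkered distributed order:
the phase-encode plane is tiled into `tfeFactor` near-equal rectangles
(the divisor grid of the turbo factor closest in aspect to the plane, with
remainders absorbed at the edges) and every shot takes exactly one
location in every tile, so each shot - and therefore each segment - spans
low and high spatial frequencies. Within a tile, the assignment of cells
to shots is a seeded draw without replacement; within a shot, the tile
visiting order is a seeded permutation. At the published scale (240 x 240
plane, 320 shots of 180 lines, 64 segments of 5 shots) each segment holds
900 lines, 1/64 = 1.5625% of k-space. Whole segments survive
`accelerateByShotDiscarding()`, which realizes acceleration by a seeded
discard of shots.

## Segment reconstruction

`reconstructSegments()` dispatches one of

* `zero_filled` - magnitude of `S^H F^-1 M^H y`;
* `cg_tikhonov` (default) - CG on `(E^H E + lambda I) x = E^H y`;
* `tv` - edge-preserving (Charbonnier-smoothed total variation) via
  iteratively reweighted least squares;
* `learned` - a pluggable callable applied to the zero-filled volume, the
  hook where a trained reconstructor would sit.

The defaults (`lambda = 0.01`, three to eight iterations) come from a phantom sweep of
normalized correlation between segment reconstructions and the (moved)
ground truth; the sweep is flat between 5 and 15 iterations and favours
weak regularization. An important honest caveat: at the package's default
desk scale each segment holds 1/16 of k-space, and no classical
reconstructor in this list recovers more than gross anatomy from that
(normalized correlation with the truth plateaus near 0.5). This is a
known property of the problem - the production-scale approach this
package mirrors uses a network trained on hundreds of scans precisely
because classical segment reconstruction is insufficient - and it shapes
the estimation pipeline below.

## Groupwise registration

`groupwiseRegister()` minimizes the sum-of-squared-differences groupwise
objective: every segment volume, resampled by the inverse of its
transform, is compared against the common template (the voxelwise mean of
the aligned volumes, which is the exact minimizer of the quadratic
objective for fixed transforms), plus a quadratic regularizer
`regWeight * (||t||^2 + (c * rot)^2)` pulling transforms to the identity
(`c` = 1 mm per degree by default). The optimizer alternates closed-form
template updates with per-segment coordinate pattern searches of
shrinking radius against the leave-one-out mean of the other aligned
volumes; with the template term implicitly re-minimized, each fit is an
exact coordinate-descent step, so the objective trace is non-increasing
within a pyramid level. A Gaussian multiresolution pyramid (smooth +
factor-2 decimation, 4 levels by default) is traversed coarse to fine and
the schedule can be repeated.

Two genuinely open choices are fixed as follows:

* **Gauge.** The objective is invariant under one common transform
  composed into every estimate (the template simply moves). After every
  level the transforms are right-composed with the inverse of their
  Frechet mean (arithmetic translation mean; chordal rotation mean
  projected to SO(3)), so the mean transform is the identity.
  `removeGlobalOffset()` applies the same idea against a reference
  trajectory - translation in closed form, rotation by Nelder-Mead from
  the chordal mean - and is what makes trajectory errors comparable.
* **Identity regularizer.** The distance functional's form is not pinned
  down by the published description; the quadratic combined metric with a
  documented mm-per-degree scale is this package's choice.

An optional final polish iteration runs on 2x sinc-upsampled (Fourier
zero-padded) volumes: halving the voxel size halves the trilinear kernel's
blur relative to the anatomy, which otherwise biases rotation estimates at
the 0.1-0.2 degree level.

Two empirical properties of this registration are documented because they
set expectations for the tests: on clean transformed volumes at 64-cubed,
recovery (with the upsampled polish) reaches a few hundredths of a voxel
in translation and close to a tenth of a degree in rotation; rotation
identifiability
degrades sharply below about 48-cubed (interpolation blur biases the SSD
minimum), which is why small-grid unit tests assert sub-degree rather
than sub-0.2-degree rotations. And on classical segment reconstructions
of 1/16-sampled segments, image-domain registration plateaus around 2 mm
/ 3 deg regardless of smoothing or reconstruction strength - the aliasing
artifacts, which carry more energy than the anatomy, are chased by the
SSD metric.

## Data-consistency refinement

Because of that plateau, the pipeline polishes the registration estimate
in the measured-data domain: `refineTrajectory()` alternates between
rebuilding a motion-corrected CG reference reconstruction under the
current estimates and minimizing each segment's k-space residual
`|| M_s F S C_theta x_ref - y_s ||^2` by a shrinking-radius pattern
search. For speed the estimates live in an SVD-compressed virtual-coil
basis and all passes but the last run in a Fourier-cropped
(half-resolution) k-space world. Facts that shape the design, all
verified directly on residual landscapes:

* the residual is computed against measured samples, so segment aliasing
  never enters;
* a moderately iterated CG reference built from a *single* wrong segment
  among correct ones keeps a sharp residual minimum at the true state;
  when all estimates are wrong the reference is blurred and the fits
  contract toward the truth only gradually, so several cheap coarse
  alternations precede one full-resolution polish;
* zero-filled leave-one-out references do *not* work: their spectrum is
  missing exactly the lines being compared, which skews the minimum;
* translations converge quickly and accurately; rotation errors contract
  more slowly and retain a residual of a degree or so at this desk scale
  - the price of the classical segment reconstructions upstream.

After the passes, the gauge (a common transform, which only changes the
reconstruction frame) is fixed so the mean transform is the identity, and
the refined trajectory is compared against the zero-motion null model by
a leave-one-out cross-validated data residual: each segment's residual is
evaluated against a reconstruction from the other segments only, which -
unlike a consensus reconstruction - cannot absorb that segment's
inconsistency. On still data the null model wins and the pipeline returns
the exact zero-motion trajectory, so correction provably does no harm
there; on corrupted data the refined estimates win on the same score.

## Motion-corrected reconstruction

`motionCorrectedCgSense()` solves `A^H A x = A^H y` by plain CG from
`x0 = A^H y`, stacking the per-segment encoders with the estimated
transforms. Defaults follow the published practice: 10 iterations for
clean simulations, 3 when noise is present (over-iteration amplifies
noise, and the tests assert the non-monotone SSIM-versus-iterations curve
on a seeded noisy run). Segments sharing a transform are merged before
solving - their masking projections add - which makes the zero-motion
(uncorrected) reconstruction an order of magnitude cheaper.

## Alternating baseline

`alternatingMoco()` alternates CG image updates with per-segment
derivative-free motion updates on the k-space residual. One structural
caveat is documented rather than hidden: in a noiseless, fully sampled
acquisition the consensus image can absorb a segment's motion
inconsistency exactly on that segment's own lines, leaving zero motion
spuriously optimal. The motion update therefore searches against
leave-one-out reconstructions, and a candidate sweep is only accepted if
the total data-consistency residual does not increase, which keeps the
reported residual trace non-increasing by construction.

## Synthetic data

The phantom (`makePhantom()`) is a deterministic head-like object:
scalp/skull shell, brain, paired ventricles, an off-centre frontal
structure (which breaks the half-turn symmetry), a neck column in the
lowest slices (so the head-only registration mask excludes something
real) and 24 seeded ellipsoidal lesions of 1-4 voxel extent for
registration-relevant texture; intensities lie in [0, 1] on an isotropic
1 mm grid so voxel and mm units coincide in tests. Coil maps
(`makeCoilMaps()`) are Gaussian lobes on a ring with seeded linear phase
ramps, RSS-normalized; `svdCompressCoils()` reproduces the standard
virtual-coil compression. Random motion follows the published protocol:
per-axis zero-mean normal translations and rotations, (2 mm, 1 deg) for
medium and (12 mm, 6 deg) for extreme motion - the resulting mean
pairwise displacement of the volume centre, 4.5 mm and 27.1 mm, is
reproduced by `meanPairwiseCentreDistance()` as a Monte-Carlo statistic
(rotation about the centre leaves the centre fixed, so the closed form is
the 3D chi mean of the translation difference; whether the average runs
over consecutive or all pairs has the same expectation for i.i.d. states,
and all pairs is used). Intrasegment motion refines each state into
per-shot states with 1/16th-severity perturbations; scripted gradual /
jittery / stepwise-extreme patterns emulate the volunteer instructions.

What the simulation does *not* emulate - and therefore what passing tests
do not show - includes realistic MR contrast, B0 inhomogeneity,
spin-history effects, motion-dependent coil sensitivities, and nonrigid
(neck, swallowing) motion. The simulator and reconstructor also share the
operator implementation, so simulations cannot expose model mismatch in
the operator itself beyond what the oracle tests (array-rotation
quarter-turn, single-state equivalence, adjoint dot test) cover.

## Default experiment and problem sizes

`defaultExperimentConfig()` fixes the desk-scale study: 64-cubed phantom,
8 coils, 16 shots of 256 lines fully covering the 64 x 64 plane, one shot
per segment (16 segments, 1/16 of k-space each), random intersegment
motion at (2 mm, 2 deg) per axis, CG-Tikhonov segment reconstruction, a
4-level registration pyramid, two-pass data-consistency refinement, and
a 10-iteration final CG-SENSE. These sizes are scaled down from the
published 240-cubed / 320-shot setting so that a full experiment runs in
minutes; unit tests use 12- to 32-cubed grids. Numerical conventions
worth knowing: seeded generators save and restore the global RNG state;
ties in the pattern search are broken toward the incumbent (a candidate
must strictly improve); Euler-angle geodesic distances inherit an `acos`
noise floor of about 1e-6 degrees, so "exact" rotation assertions are
made at 1e-4-1e-5; degenerate inputs (empty masks, all-zero k-space,
single segments) return the natural zero or identity objects rather than
erroring.

## Known limitations

* Classical segment reconstruction limits image-domain registration at
  high segment counts; the data-consistency refinement compensates in
  simulation, but on real data with model mismatch (B0, spin history) the
  refinement's residual would partly chase unmodelled physics.
* Rotation estimation below ~48-cubed grids is biased by interpolation
  blur; results on very small grids are for testing, not science.
* The alternating baseline is a simplified stand-in: comparisons with the
  published alternating method are qualitative.
* `RigidTransform` covers rigid motion only; nonrigid correction is out
  of scope.
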