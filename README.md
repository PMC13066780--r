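# mocoMRI

Retrospective rigid-motion correction for 3D multishot Cartesian brain MRI,
in R.

Long 3D acquisitions are vulnerable to head motion: a subject who moves
between shots leaves ghosting and blurring in the reconstruction, sometimes
badly enough to force a re-scan. `mocoMRI` implements a navigator-free,
purely retrospective correction pipeline for simulated (or user-supplied)
multicoil data, aimed at people studying motion-correction algorithms:

1. **Distributed-incoherent sampling.** A random-checkered ordering of the
   `ky`–`kz` phase-encode plane assigns every shot one sample per k-space
   tile, so any group of shots (a *segment*) spans low and high spatial
   frequencies.
2. **Segment reconstruction.** Each segment — under 2% of k-space at the
   published scale — is reconstructed to an approximate volume (zero-filled,
   CG-Tikhonov, edge-preserving TV, or a pluggable learned reconstructor).
3. **Groupwise registration.** The segment volumes are aligned rigidly to an
   evolving mean template, avoiding a fixed reference; the gauge freedom is
   fixed so the mean transform is the identity.
4. **Data-consistency refinement.** The registration estimate is polished
   per segment in the measured-data domain against motion-corrected
   reference reconstructions.
5. **Motion-corrected CG-SENSE.** The estimated per-segment transforms
   enter the forward model `A = M F S C_theta` and the image is recovered by
   conjugate gradients on `A^H A x = A^H y`.

An alternating image/motion optimizer over the same forward model
(`alternatingMoco()`) serves as the classic baseline, and
SSIM/PSNR/NMSE/trajectory-error metrics quantify the result. The forward
model, its exact adjoint (including the transpose of the trilinear
interpolation), the sampling generator, phantom/coil simulators and all
motion tooling are exported and unit-tested individually.

## The model

The acquisition of segment `s` is

```
y_s = M_s F S C_theta_s x + noise
```

with `C_theta` a rigid transform (3 translations in mm, 3 extrinsic x-y-z
Euler rotations in degrees about the volume centre), `S` complex
RSS-normalized coil sensitivities, `F` the centred orthonormal 3D Fourier
transform and `M_s` the segment's phase-encode line selection. Motion
correction estimates `{theta_s}` from the data alone and inverts them inside
the reconstruction. Simulated motion follows per-axis zero-mean normals —
(2 mm, 1°) "medium", (12 mm, 6°) "extreme", giving 4.5 mm and 27.1 mm mean
displacement of the volume centre between states — plus scripted gradual /
jittery / stepwise patterns.

## Worked example

```r
library(mocoMRI)

phantom <- makePhantom(48, seed = 1)                  # 48^3 head phantom
coils   <- makeCoilMaps(48, nCoils = 8, seed = 2)     # 8 RSS-normalized coils
scheme  <- generateDisorderScheme(48, 48, nShots = 16, tfeFactor = 144,
                                  shotsPerSegment = 1, seed = 3)
motion  <- sampleRandomTrajectory(16, transStdMm = 2, rotStdDeg = 2, seed = 4)

ks <- simulateAcquisition(phantom, motion, scheme, coils)

corrected   <- motionCorrectedCgSense(ks, motion, coils, nIters = 10)
uncorrected <- uncorrectedRecon(ks, coils, nIters = 10)

ssim3d(uncorrected, phantom)
#> [1] 0.1626518
ssim3d(corrected, phantom)
#> [1] 0.9055918
```

Correcting with the known trajectory restores the reconstruction almost to
the motion-free value; the uncorrected image shows heavy ghosting (the SSIM
values above are what the code prints for these seeds). The full estimation
pipeline — where the trajectory is *not* known and is estimated by segment
reconstruction, groupwise registration and data-consistency refinement —
runs as one call:

```r
report <- runExperiment(defaultExperimentConfig())
report$metrics$ssim_corrected > report$metrics$ssim_uncorrected
#> [1] TRUE
report$trajectoryError     # gauge-invariant mean error, mm and degrees
```

A thin command-line front end over the same functions lives at
`inst/cli/moco.R` (`sample`, `run`, `sweep`, `evaluate` subcommands).

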