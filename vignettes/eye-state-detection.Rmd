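---
title: "Detecting eye state from EPI time series: models, parameters and design choices"
author: "eyestate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting eye state from EPI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyestate)
```

## The problem

Whether a subject's eyes are open or closed modulates activity across many
brain networks, so uncontrolled eye state is a confound in resting-state
and task fMRI alike. Cameras and EEG/EOG can monitor it but are costly,
slow to set up, and unavailable for data already acquired. The eye bulbs,
however, sit inside every whole-head EPI field of view, and two physical
effects make them an eye-state sensor:

* **Bell's phenomenon** — lid closure rotates the bulb upward by a few tens
  of degrees, tilting the bulb's long (antero-posterior) axis;
* **motion-dependent signal loss** — EPI signal is attenuated in moving
  tissue, and the vitreous moves far more with the eyes open (saccades,
  pursuit, blinks) than closed, so the mean in-bulb intensity is *higher*
  with the eyes closed.

`eyestate` turns both effects into per-volume features and classifies each
time point, entirely from the images.

## Segmentation: continuous max-flow

Inside each eye's ROI box the bulb/background cut minimizes

$$E(u) \;=\; \langle 1-u,\,C_s\rangle + \langle u,\,C_t\rangle +
\int_\Omega \omega(x)\,\lvert\nabla u\rvert\,dx ,
\qquad u:\Omega\to[0,1],$$

the convex relaxation of the binary min-cut. Capacities use the simplest
model consistent with segmenting by intensity: $C_s = |I-\mu_{bg}|$,
$C_t = |I-\mu_{fg}|$ with $\mu_{fg},\mu_{bg}$ the class means of the Otsu
split of the ROI histogram (the bright class is the vitreous), and a
constant weight $\omega \equiv \lambda$, default $0.1\times$ the ROI
intensity range. Because levels are re-estimated per volume, segmentation
is invariant to global affine intensity rescaling and insensitive to slow
drift.

The solver is a first-order augmented-Lagrangian max-flow scheme with
fixed steps (multiplier `c = 0.35`, flow step `0.11`, capacities rescaled
to unit magnitude for conditioning — the minimizer is unaffected).
Augmented-Lagrangian iterations are not intrinsically monotone in the
primal energy, so each sweep evaluates $E$ at the clipped labeling and the
*incumbent* (best-so-far) iterate is retained and returned; the reported
energy trace is therefore non-increasing by construction and the answer is
never worse than any intermediate iterate. Iterations stop when the mean
absolute labeling change per voxel falls below `tol` (default `1e-4`,
`maxIter = 300`; hitting the cap warns but does not fail). The relaxed
labeling is thresholded at 0.5 with ties to foreground; anisotropic
(forward-difference, reflective-boundary) total variation makes the
discretized energy identical to a 6-connected graph cut, which is how the
test suite verifies the solver against an exact max-flow oracle (within
1 % on random instances; in practice the relaxation is tight and the
energies agree to ~0.02 %).

After thresholding, only the largest 6-connected component survives, and a
volume is flagged when the mask is empty, fragmented (largest component
< 90 % of foreground), or implausibly sized (> 50 % or < 2 % of the ROI
box — a bulb occupies ~20 % of the standard boxes). Flags propagate: the
per-volume feature values are linearly interpolated across flagged volumes
before temporal filtering and remain marked in every output table.

## Geometry: the maximum-diameter vector

Each bulb is reduced to the longest chord between vertices of its surface.
Surface extraction is a marching-cubes construction written for this
package: marching-squares segments on every face of every mixed
$2^3$ sample cell (ambiguous faces always separate the inside corners — an
orientation-free rule, so adjacent cells agree and the mesh is watertight),
cycles traced within each cell and fan-triangulated. All vertices lie on
lattice edges; on a binary mask each vertex sits exactly half a voxel from
the inside sample. The case table is derived programmatically at first use
rather than copied from published implementations.

`maxDiameter` is an exhaustive all-pairs search (verified against a
brute-force oracle), so the only modeling freedom is *which surface* the
vertices come from, and this matters greatly at 3 mm resolution. The
longest chord of a near-spheroid is an ill-conditioned direction estimate:
for semi-axes $a > c$ the chord at angle $\theta$ off the major axis is
shorter by only $\Delta r(\theta) \approx \theta^2\, a(a^2-c^2)/(2c^2)$,
about 0.03 mm at $\theta = 5^\circ$ for an eye-sized bulb — far below the
half-voxel quantization of a binary mask surface. Empirically, the chord
direction of the voxelized mask barely responds to a programmed 0–28°
rotation. The pipeline therefore extracts the isosurface from the ROI
*intensity field* at the midpoint between the in-mask and out-of-mask mean
levels, restricted to a 2-voxel dilation of the mask and regularized with
a 0.7-voxel Gaussian: partial-volume boundary voxels then localize the
border at sub-voxel precision (this mirrors running `isosurface` on
continuous segmentation output rather than on a 0/1 array). The binary-mask
surface remains available (`vectorTimeseries(..., surface = "mask")`) and
is the documented default of `extractSurface` itself.

A diameter is an unordered pair, so $\hat u$ is defined up to sign. The
package canonicalizes to the **anterior hemisphere**, $\hat u_y \ge 0$
(ties: $\hat u_z$, then $\hat u_x$): the long axis points out of the orbit
for any physiological gaze, so this fixes the sign consistently over time
— and, unlike folding on $\hat u_z$, it leaves the elevation component
*signed*. With the eyes open the true elevation is near zero; a $\hat
u_z \ge 0$ rule would rectify estimator noise into a spurious positive
elevation (we measured open-state $\bar{\hat u}_z \approx 0.4$ instead of
0 under the default noise), compressing the open/closed difference. With
the anterior rule the phantom's programmed 28° difference is recovered to
within ~2–3°. Angles are reported in radians against the positive axes:
`horizontal` $= \arccos(\hat u_x)$, `vertical` $= \arccos(\hat u_z)$; eye
closure lowers the vertical angle ($90^\circ \to 62^\circ$ for a 28°
elevation).

Remaining length ties (within $10^{-9}$ mm, typical for symmetric digitized
shapes) resolve to the pair whose canonical unit vector is
lexicographically largest by $(y, z, x)$ — determinism without geometric
consequence.

## Intensity: traces, filtering, rescaling

The mean intensity at each volume is taken over *that volume's own* mask,
so the sample follows the bulb; `"both"` averages the left and right means
before filtering (filtering first and averaging after is available by
processing the eyes separately). Filtering is a zero-phase 4th-order
Butterworth band-pass, 0.01–0.1 Hz by default: the 27 s block alternation
(54 s period, 0.0185 Hz) passes with gain ≈ 1, scanner drift and DC are
removed exactly (zeros at $z=1$), and phase distortion is zero so state
transitions are not shifted. The filter is designed from the analog
prototype via bilinear transform with prewarping and applied
forward-backward with odd-reflection padding of three filter lengths and
steady-state initial conditions; one filter length of padding is too short
for a 0.01 Hz corner at TR 2.52 s, which is why the longer convention was
chosen. Coefficients were verified against an independent reference
implementation to ~1e-12 during development, and the test suite checks the
realized gains against the filter's own analytic transfer function.

One physical limit deserves note: at TR 2.52 s the 0.01–0.1 Hz band spans
~45 % of the representable frequencies, so *no* realization of this
band-pass can attenuate a single-volume spike by more than ~55 % (the
zero-phase impulse peak equals the mean of $|H|^2$ over frequency,
≈ 0.45). Blink artifacts are therefore damped but not removed; the
classifier's tail thresholds, not the filter, provide the remaining
robustness.

Rescaling subtracts the mean and divides by the maximum absolute value.
The fully symmetric target "mean 0, max +1, min −1" is over-constrained
for asymmetric series; this realization satisfies all three whenever they
are jointly satisfiable and degrades gracefully otherwise. It is
idempotent, and the half-range categorization applied afterwards (label 1
strictly above `min + range/2`, boundary to 0) is invariant under positive
affine transforms, so the order of rescaling and categorization does not
matter.

## Classification and evaluation

A random `holdoutFraction` (default 10 %) of volumes is held out
(reproducibly under an integer seed). On the remaining 90 %, the
`tailFraction` (10 %) and `1 − tailFraction` quantiles of the processed
feature become the open/closed cuts (linear interpolation between order
statistics — quantile type 7 — for cross-implementation determinism). At
prediction, tail values get the tail's label; mid-range values go to the
nearer cut (exact midpoint → closed) so that every volume is labeled, and
carry an `uncertain` flag. With 10 % tails on a roughly symmetric bimodal
trace most mid-block values are formally "mid-range" yet far from the
decision boundary; the flag is deliberately conservative. Congruency is
the percent agreement on the held-out volumes; with truth supplied the
report also carries feature/state correlations, inter-eye correlations and
control-ROI correlations. The default feature is the both-eye mean
intensity (the most reliable single feature); the vertical angle, the raw
$\hat u_z$, and a combined rule (majority of intensity and vertical angle,
intensity breaking ties — which coincides with the intensity labels but
narrows the uncertainty flags) are available through `runConfig`.

## The phantom: what it emulates and what it does not

`phantomSpec()` states the emulated world once:

| parameter | default | why |
|---|---|---|
| grid, voxel | 36×20×22 at 3 mm | two orbits plus margin |
| TR, volumes | 2.52 s, 600 | the emulated acquisition |
| block length | 27 s, starting closed | alternating instruction protocol |
| semi-axes | (10.5, 14, 11.66) mm | $(4/3)\pi abc \approx 7180$ mm³, the adult mean; antero-posterior major axis, max/next = 1.2, resolvable at 3 mm |
| elevation | 0° open → 28° closed | mean physiological Bell rotation |
| intensity | 800 open → 880 closed, background 200 | ~10 % closed-state gain from reduced motion loss |
| noise sd | 200 | calibrated so the pre-filter trace/state correlation is ≈ 0.9 over ~266 bulb voxels — the regime of real group data |
| drift | ±20 at 300 s period | slow scanner drift, below the pass band |
| blinks | 2 % of open volumes | only blinks overlapping the eye-slab acquisition perturb a volume; modeled as a single-volume jump to the closed intensity with unchanged geometry |

Bulbs are rendered with partial-volume edges (per-voxel inside fraction,
supersampled 4×4×4), as on real EPI where border voxels mix vitreous and
orbital signal; the *ground-truth masks* keep the centre-inside rule so
the voxel count stays checkable against the analytic ellipsoid volume
(within ~1.5 % at 3 mm).

The phantom does **not** emulate: susceptibility dropout and ghosting near
the orbits, head motion, physiological noise, the warping of the bulb by
spatial normalization, or the anatomical detail (lens, optic nerve) that
makes real bulb surfaces more directionally distinctive than an ellipsoid.
A green phantom test therefore establishes that the algorithms recover a
stated signal from stated noise — not that every real scan will behave as
well. One measurable consequence: the inter-eye correlation of $\hat u_z$
on the phantom is ~0.55, whereas real data can reach ~0.99, because the
ellipsoid's chord direction is intrinsically noisier than that of a real
segmented bulb.

## Numerical choices

* 0-based, inclusive voxel bounds everywhere in the API; mm bounds map
  through the inverse affine corner-wise (robust to flips), round to
  nearest, clip to the grid.
* Smoothing is stated as FWHM (neuroimaging convention); "3 mm kernel"
  is read as FWHM = 3 mm, separable, reflective boundaries (total
  intensity preserved to < 0.1 %).
* NIfTI-1 I/O is little-endian, float64 on write (lossless round trip),
  with TR in `pixdim[4]`; header floats are presented at float32
  precision. The space tag maps to sform code 4 (MNI) vs 1.
* TR precedence: an explicit argument beats the header, with a warning
  when they disagree by > 1 %.
* The jackknife split, the phantom, and nothing else consume randomness;
  both restore the caller's RNG state.

## Known limitations

* Angle features are ill-conditioned at 3 mm for near-spherical bulbs (the
  $\Delta r \propto \theta^2$ flatness above); mean intensity is the
  robust feature, matching the empirical finding that it correlates best
  with the true state.
* Blink spikes are attenuated by at most ~55 % at this TR/band (see the
  filter section); occasional blink volumes may be labeled closed.
* The classifier assumes both states occur in the run; a run with eyes
  always closed would make tail thresholds meaningless (the half-range and
  threshold operations refuse constant input rather than guessing).
* Native-space runs need user-supplied ROI boxes; only normalized images
  can fall back to the built-in MNI boxes.
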