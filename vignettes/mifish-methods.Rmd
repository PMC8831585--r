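---
title: "Models and methods behind mifish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mifish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mifish` analyses combinatorial multi-color DNA FISH experiments in which 16
loci on the q-arm of human chromosome 2 are visualized simultaneously:
10 probes carry two of the five dyes AF488/AT542/AF594/AT647N/AF700
(spectral barcodes — all C(5,2) = 10 unordered pairs) and 6 probes carry a
single dye, one per dye including AF790. This vignette explains the models
the package implements, the tunable parameters, and the choices made where
the design was genuinely open.

## The color scheme

A `mifish_scheme` holds the probes in genomic order plus the injective map
from unordered dye pair to probe identity. The nominal layout places 11
probe midpoints every 3 Mb (55–85 Mb) and 5 more every 20 Mb (105–185 Mb),
each probe spanning 66 kb; exact coordinates can be supplied as a BED-like
file (`chrom, start, end, probe_id, dye1[, dye2]`, 0-based half-open,
probe position = interval midpoint). For a diploid nucleus the design
predicts 10 dots per channel for the five dual-combination dyes and 2 dots
in the AF790 channel; these counts drive candidate selection during
decoding.

## Synthetic scenes

The simulator provides ground-truthed inputs for every stage. Nothing in the
decoding pipeline depends on it; it exists so that detection, correction,
decoding and validation can be tested against a known truth.

* **Nuclei** are ellipsoids (defaults: semi-axes 7.0 x 6.4 x 2.7 µm, the
  flat geometry of adherent RPE-1 nuclei), rendered in the DNA channel as
  filled volumes, G2 cells at twice the integrated intensity.
* **Chromosome territories.** Each allele's 16 loci form a Gaussian chain:
  the displacement between consecutive loci is isotropic normal with
  standard deviation `step_scale_nm * gap_Mb^nu` (defaults 550 nm/Mb^0.5 and
  nu = 0.5, an ideal-chain scaling), reflected to stay inside a territory
  sphere (default radius 3.2 µm) and inside the nucleus. The two territories
  are placed at least 7.4 µm apart, reflecting the spatially distinct
  homolog territories that make k-means homolog clustering meaningful —
  the analysed cells in this kind of experiment are those with two clearly
  identifiable clusters.
* **Dots.** A dual-color probe contributes one true dot per dye at the same
  position, `photons_per_dye` each (default 15 000); a single-color probe
  contributes one dot with twice the photons, because it carries twice the
  labelled oligos. `detection_efficiency` models per-dye hybridization
  dropout; `coloc_jitter_nm` models residual chromatic registration error
  as an isotropic offset per dye-dot.
* **Rendering.** Dots are pixel-integrated 3D Gaussians with the channel's
  expected sigma (Table of PSF widths below); sensor noise is
  Poisson(signal + background) followed by additive Gaussian read noise
  (sigma = 5 counts), clipped at zero — Poisson before Gaussian, mirroring
  photon shot noise then camera read noise.

Two named condition sets are used in the tests:

* *high SNR*: `photons_per_dye = 15000`, `background = 100`,
  `detection_efficiency = 1`, `coloc_jitter_nm = 0`, with a spread-out
  territory geometry (`step_scale_nm = 800`, territory radius 3.8 µm,
  separation 9.2 µm, nucleus 8.6 x 8.0 x 2.7 µm). This regime probes
  decoding fidelity where dots are mostly optically resolvable; residual
  failures come from genuinely unresolvable same-channel locus pairs.
* *realistic SNR*: `photons_per_dye = 3000`, `detection_efficiency = 0.95`,
  `coloc_jitter_nm = 80` at the default geometry. Here probes drop out
  through hybridization failure and co-localization misses, reproducing the
  13–16 probes-per-cluster regime that dominates real data.

What the generator does **not** emulate: sister chromatids, aneuploidy,
off-target oligo binding, autofluorescent debris, uneven illumination,
depth-dependent aberrations, and touching nuclei. Passing tests therefore
validate the algorithms' correctness and calibration, not robustness to
every artifact of real microscopy.

## PSF widths and spot detection

Expected dot widths per channel (lateral FWHM in nm and in 130-nm pixels):
AF488 282/2.17, AT542 302/2.32, AF594 332/2.55, AT647N 357/2.75, AF700
389/2.99, AF790 438/3.37; sigma = FWHM / (2 sqrt(2 ln 2)). The axial FWHM
defaults to twice the lateral, in 200-nm planes — the usual lateral/axial
resolution ratio of a high-NA wide-field objective.

Detection finds strict 6-connectivity local maxima of the raw image and
keeps those whose response in a difference-of-Gaussians filter reaches the
channel threshold. The DoG narrow sigma is 1.72x the expected dot sigma; the
wide sigma is 1.6x the narrow one (the standard blob-detection ratio; the
original implementation's exact pair is not documented). Maxima are
detected on the raw image rather than on the DoG so that nearby dots the
band-pass blur would fuse remain separable. The default threshold
(5 counts) was calibrated once on background-only synthetic stacks
(background 100, read noise 5) to yield zero false positives with margin,
while keeping dots down to ~2500 photons detectable.

Localization is a two-stage maximum-likelihood fit with a Gaussian noise
model (least squares), optimized with the Nelder–Mead simplex: first a
pixel-integrated 2D Gaussian in the seed plane (parameters x, y, photons,
background, sigma), then a 1D Gaussian fit of the axial profile interpolated
at the fitted lateral position. Starting values are the seed voxel, the
patch median background and the channel's expected sigma; non-convergent or
out-of-bounds fits are discarded and counted. Fits closer than 0.5 px to an
already-kept brighter fit are dropped — neighboring noise maxima of one dot
converge to the same position. Total dot photons are the in-plane photons
scaled by the fitted axial profile, with the axial offset clamped to one
sigma so a noisy z estimate cannot inflate the brightness estimate (dot
brightness ranks candidates during decoding, so heavy-tailed intensity
errors would corrupt single-color assignment).

Sub-voxel fitting matters: localizing to the brightest voxel center alone
leaves a mean absolute 3D error of ~74 nm at 130 x 130 x 200 nm voxels
(`pixel_center_localization_error()`), while the fit reaches a few tens of
nm; precision scales as sigma/sqrt(N) with N the photon count, which the
localization experiment verifies by quadrupling photons and observing the
RMSE halve.

## Chromatic aberration correction

Bead fields visible in all channels calibrate a per-channel model: a
2nd-order polynomial in (x, y) for the lateral displacement (six
coefficients per axis, fitted per-axis by least squares — the original
report does not state whether the axes were fitted jointly) plus a constant
axial shift, relative to the AT647N (`cy5`) reference channel. Matching is
mutual-nearest-neighbor within a radius. The correction is applied to dot
coordinates rather than by image resampling: for point data the two are
equivalent, and coordinate application is exactly testable (the model's own
field is inverted to machine precision). Registration error is reported as
mean squared pair distance in pixels (axial distance scaled by the 200/130
voxel anisotropy) before correction (3D) and after (2D and 3D).

## Nuclei, G1 gating and lamina distances

Nuclei are segmented from the DNA stain by a global Otsu threshold,
per-plane hole filling and 26-connected component labelling with a volume
filter; no deconvolution is applied (the proprietary step is omitted, and
segmentation quality is verified against analytic ellipsoids instead). G1
cells are gated by an Otsu split of the pooled integrated DNA intensities —
the lower mode is G1, the upper G2/M; a degenerate (unimodal or constant)
distribution leaves cells unassigned with a warning, so gating should only
be trusted on datasets containing both populations.

The normalized lamina distance of a dot is d_E / (d_E + d_C), where d_E is
the anisotropic Euclidean distance-transform value at the dot's voxel
(distance to the nuclear edge, exact EDT via the lower-envelope algorithm
with physical voxel sizes) and d_C the anisotropic distance to the nearest
voxel of the nuclear center set — voxels whose edge distance is in the top
percentile (default 99th; the original value is not stated) of the in-mask
distribution. On a sphere this reduces to (R - r)/R up to voxelization.

## Homolog clustering and barcode decoding

Dots of a G1 nucleus are split into the two homolog clusters by k-means
(k = 2, best of 10 seeded restarts) on physical coordinates; dots farther
than 40 lateral pixels (5.2 µm) from their centroid are outliers; centroid
separation below 1 µm flags a failed split. Per cluster and channel the
brightest dots are kept — twice the number of probes carrying the dye (10,
or 2 for AF790).

Decoding assigns dots to probes in the order: (1) enumerate cross-channel
candidate pairs within the channel-pair co-localization threshold — 0.25 µm
when both channels sit behind the same multi-band dichroic cube
(AT542/AT647N, AF594/AF700), 0.55 µm otherwise — and map each pair to its
dual-color probe; (2) assign probes with a unique candidate pair first,
tightest pair first; (3) for contested probes take the shortest pair, ties
broken by intensity sum then stable dot id; (4) on every assignment remove
the used dots from the dual-color lists together with same-channel dots
within 0.50 µm of them (the split-dot filter; such dots stay eligible for
single-color probes, which are assigned by brightness afterwards); (5) give
each single-color probe the brightest unassigned dot of its channel
(singles carry twice the oligos and are expected brighter); (6) drop
assigned dots farther than 5 µm from every other assigned dot as outliers.
Unassignable probes are reported missing — missing probes are data, not
errors. Two published variants are exposed as flags: multi-assignment
(dots may serve several dual probes) and the relaxed same-cube threshold
(0.55 µm everywhere).

The random-allocation null redraws each dual probe's first dot until a
partner lies within 0.55 µm, reiterates the assignment per cluster, and
ranks the resulting allocations lexicographically by total intensity,
fewest doubly-used dots, most sub-threshold pairs, fewest failures, fewest
same-channel pairs within 0.25 µm — the combination rule for the published
priority list is not stated, so strict lexicographic order was chosen and
is documented here.

## Geometry and Hi-C concordance

Chromosome traces interpolate the present probe positions (dual-color
position = midpoint of the two dots; the original report does not say which
dot represents the probe) with a natural cubic spline under chord-length
parameterization, sampled 50 points per segment. Curvature uses the
standard space-curve formula evaluated analytically on the spline
polynomials; profiles are normalized by their per-structure maximum, and
peaks are strict local maxima above 0.1 (plateaus are flagged, not
resolved; the global maximum is always reported when unique). Curvature is
rigid-motion invariant and scales inversely with uniform rescaling, which
the tests verify against circle and helix closed forms.

For validation, per-pair 3D distances aggregate across clusters into
medians and into contact frequencies (fraction of clusters with distance
<= 1 µm, inclusive). Hi-C enters as a plain-text binned contact matrix plus
a bedGraph-like eigenvector track with a declared sign convention;
compartments are called only where |eigenvector| > 0.01. On chain-model
synthetic data with a matched synthetic contact matrix (contacts = fraction
of an independent batch of structures closer than 1 µm), median distances
anti-correlate and FISH contact frequencies correlate positively with the
matrix, and the decode variants order as strict > relaxed/multi > random
null in absolute correlation. Pairs with fewer than 5 distance samples are
excluded from correlations to avoid unstable medians.

## Numerical choices and problem sizes

Reflection into ellipsoids uses radial folding (u -> u(2 - rho)/rho);
chord-length ties in the spline are broken by a 1e-9 floor; Otsu thresholds
use 256 histogram bins; k-means uses `nstart = 10` under a caller-supplied
seed; all randomness in the simulator flows through one seed argument, so
equal seeds give bit-identical scenes. The test-suite problem sizes —
hundreds of simulated cells for distance statistics, tens of rendered
fields of view for imaging round-trips, 1000 patches per localization
condition — were chosen to keep the default suite comfortably reproducible
on a laptop-class single core while leaving the statistical checks
well-powered.

## Known limitations

The decoder resolves at most two alleles and assumes aberration-corrected
coordinates; thresholds are configuration, not learned. Same-channel loci
that fall within the optical merge radius (~2 sigma) produce one detected
dot and cost the affected probe; this is the dominant failure mode at high
SNR and mirrors the published completeness of 13–16 probes per cluster.
Sequential-hybridization decoding, aneuploid cells, image-resampling
correction and raw Hi-C processing are out of scope.
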