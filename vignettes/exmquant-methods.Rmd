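---
title: "Quantitative validation and multi-round analysis of expansion microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative validation and multi-round analysis of expansion microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exmquant)
```

Expansion microscopy (ExM) physically enlarges a specimen embedded in a
swellable hydrogel so that conventional optics resolve nanoscale structure.
Every quantitative claim built on ExM rests on two measurements — how
*uniform* the expansion is (distortion) and how *large* it is (the expansion
factor) — and, for multiplexed experiments, on two processing steps: aligning
sequential staining rounds and separating the signal each round adds from the
signal carried over from previous rounds. `exmquant` implements this full
quantitative layer together with seeded synthetic generators that provide
exact ground truth for testing every stage.

## Distortion and the expansion factor

The geometric model linking a pre-expansion image to its post-expansion
counterpart is a similarity transform: uniform scale $s$, rotation $\theta$,
translation $t$. Anything the similarity cannot absorb is distortion.

The measurement chain is:

1. **Keypoints.** Blob keypoints are detected as scale-normalized
   Laplacian-of-Gaussian extrema (3×3 spatial and scale neighbourhoods,
   parabolic sub-pixel refinement). The detected scale makes descriptors
   comparable across an unknown expansion factor. Descriptors are log-polar
   intensity patches, rotation-normalized by the intensity-centroid
   orientation and matched by nearest neighbour with a ratio test
   (default 0.8). No SIFT binding exists in the R ecosystem, so the
   detector/descriptor is our own; the *contract* — scale-invariant keypoints
   filtered by a similarity-only consensus — is what downstream code relies
   on.
2. **Consensus fit.** RANSAC with minimal two-point similarity hypotheses
   (closed-form, via complex regression), inliers at `inlier_tol` (default
   3 px), least-squares refit on the consensus set. The fit is deterministic
   given its seed, and exact on clean data (machine precision; verified
   against `vegan::procrustes` as an independent oracle).
3. **Distortion field.** Residuals of inlier correspondences after the best
   similarity, divided by $s$ and multiplied by the pre-expansion pixel size:
   displacements in biological micrometres anchored at pre-image positions.
4. **RMS curve.** The error of a length measurement between two features is
   the difference of their residual vectors. Random anchor pairs (seeded,
   capped at $10^5$) are binned by separation; each bin reports the RMS
   error. For i.i.d. Gaussian residuals of s.d. $\sigma$ per axis the curve
   plateaus at $2\sigma$, which the tests verify by brute-force enumeration.
5. **Percent distortion.** The RMS curve is the primary readout; where one
   number is needed we report $100\cdot\mathrm{rms}(L)/L$ pooled over the
   well-populated bins in the upper half of the length range. A single
   largest bin is noticeably noisier at realistic keypoint counts, which is
   why the plateau is pooled; the definition travels with the value.

Pre/post pairing in depth uses the fact that one pre-expansion plane maps to
a slab of post-expansion planes: all contiguous max-projection windows with
lengths 5–30 planes are matched and the window with the most consensus
inliers wins.

Expansion factors come by four routes, matching how different specimen types
are actually measured: the keypoint similarity scale; particle areas
(threshold → 26/8-connected labeling → $\sqrt{\bar A_{post}/\bar A_{pre}}$)
for suspensions; mean length ratios for cell-width measurements; and whole
tissue size ratios. Thresholding for the particle route defaults to an exact
Otsu on a 256-bin histogram with a 5 px absolute and 10%-of-median relative
particle-size floor — the relative floor is what keeps the estimate stable
when noise fragments the shallow contours of strongly expanded particles.
`normalize_to_biological_scale()` then divides the pixel sizes by the factor
so all downstream measurements read in pre-expansion units; repeated
normalizations compose multiplicatively.

## SOFI pre-processing

Pre-expansion reference images use second-order fluctuation imaging: with
independently blinking emitters, the zero-lag second-order cumulant
$\langle \delta F_a\,\delta F_b\rangle_t$ of pixel time series squares the
PSF, narrowing it by $\sqrt 2$, and cross-terms between distinct pixels
cancel uncorrelated noise. `sofi_xc2()` places auto-cumulants on physical
pixels and flanking-pair cross-cumulants on the in-between virtual pixels of
a twice-denser grid (diagonal virtual pixels average the two diagonal
pairs); the absolute-value convention makes the image non-negative.
Conventions for the virtual-pixel weighting are ours and are stated rather
than inherited — published pipelines differ in these details.

Before cumulants, `correct_drift_intensity()` aligns each frame to the
temporal mean by iteratively refined cross-correlation (unwhitened — phase
correlation equalizes noise-dominated high frequencies and is biased for
smooth images — with the parabolic-peak bias removed by re-estimation, about
0.01 px on clean data). Because mechanical drift is smooth in time, the
per-frame track is passed through a running median, which rejects the
spurious estimates that frames with few active emitters occasionally
produce. Frames are then normalized to a common spatial mean and the borders
invalidated by the maximum drift are cropped. Drift beyond 25% of the frame
is an error, not a warning.

`lucy_richardson()` is the standard multiplicative Poisson EM deconvolution;
it preserves non-negativity by construction and conserves flux on
interior-supported objects. The XC2 image's PSF is the optical PSF squared,
so `sofi_reconstruct()` deconvolves with $\sigma_{opt}/\sqrt2$ (times two
grid units on the virtual grid), 10 iterations by default.

## Multi-round registration

Sequential staining rounds are aligned on the shared nuclear reference
channel. No expansion occurs between rounds, so the consensus fit locks
scale to 1 (rigid). Keypoint localization noise leaves a few-hundredths-px
translation error; a cross-correlation refinement on the reference
projection removes it. Minor local misalignment is then handled by
diffeomorphic demons: intensity-driven forces, Gaussian-smoothed increments
composed into the running field (fluid), light smoothing of the total
(diffusion), with two stabilizers:

* forces are suppressed where the residual is within 3 MAD of the noise
  level estimated from the *high-frequency* part of the residual
  (misalignment is spatially smooth; sensor noise is not) — otherwise
  noise in flat, already-aligned regions drives O(1) spurious forces;
* if the residual rises three iterations running the loop stops with a
  warning and returns the best field.

The field lives on the fixed grid (`warped(x) = moving(x + d(x))`), so the
reference-channel field applies unchanged to the other channels of its
round. 3D stacks are registered plane by plane; this keeps each solve small
and is the right model when inter-round motion is lateral stage error.

## Signal unmixing across rounds

Staining without stripping accumulates signal: round $i$ observes
$\mathrm{Image}_i = \mathrm{ImageR}_i + \alpha\,\mathrm{Image}_{i-1}$
(recursively, on the accumulated previous round). Since consecutive rounds
target distinct molecules, the true signal $\mathrm{ImageR}_i$ should share
no information with the previous image, so $\alpha$ is found by enumerating
a grid (default 0 to 1.5, step 0.01) and minimizing the mutual information
$I(\mathrm{Image}_{i-1};\ \mathrm{Image}_i - \alpha\,\mathrm{Image}_{i-1})$
from a 64×64-bin joint histogram of min–max-normalized images, after
subtracting each image's 1st percentile so shared background does not
dominate. Two points matter:

* **The search residual is not clipped.** Clipping negative residuals
  *inside* the search lets arbitrary oversubtraction drive the residual's
  entropy — and with it the MI — to zero, so the minimum degenerates to the
  top of the grid. Unclipped, oversubtraction re-introduces (negative)
  dependence on the previous round and the MI has an interior minimum at
  the true carry-over. Non-negativity is enforced on the output images
  only.
* $\alpha$ is searched per detection channel independently (carry-over is a
  property of each channel's fluorophore/antibody stack), never for the
  re-stained reference channel, and on the full registered volume.

The returned $\alpha$ always attains the exact minimum of the reported MI
profile, ties resolving to the smallest candidate. On synthetic rounds the
recovery is within one to two grid steps (|error| ≤ 0.02) across
$\alpha \in [0.1, 1]$.

## Colocalization

Each channel volume is binarized by adaptive local thresholding — foreground
iff the voxel exceeds its local (31³ default, border-clamped) box mean times
$1 + (1 - \mathrm{sensitivity})$ — which absorbs per-channel SNR differences
through the sensitivity parameter (default 0.5). The formula is our
concretization of "adjusted sensitivity"; it is recorded in the docs because
the operation's name alone does not pin it down. Foreground is labeled by
26-connectivity (face, edge or corner adjacency; a small compiled BFS
kernel, cross-checked against a pure-R flood fill) and particles under 27
voxels (3³) are dropped.

The colocalization index of channels $A, B$ is the overlap volume as a
percentage of each: $100|A\cap B|/|A|$ and $100|A\cap B|/|B|$ — exact
integer arithmetic. The C×C matrix uses the row-as-reference convention
(entry $(i,j)$ = % of channel $i$'s volume overlapped by channel $j$),
declared in the object's metadata because the directional phrase is
ambiguous in common usage; both directions are always derivable from the
matrix. Group comparisons average matrices over ROIs, difference the group
means, and attach per-cell one-way ANOVA p-values (two groups ⇒ F with 1
and $n-2$ df, verified against the closed-form F CDF), starred at
0.05/0.01/0.001 with no multiple-testing correction by default
(a Benjamini–Hochberg option exists but is off, matching common practice
for these matrices).

## The synthetic generators

The generators are first-class, tested code; they stand in for raw
microscopy stacks and define the conditions every test runs under.

* `gen_expansion_pair()` renders Gaussian blobs (random peak intensity,
  slight anisotropy — enough texture to be matchable), maps them through a
  known similarity into a larger frame plus an optional smooth zero-mean
  warp (coarse random grid, cubic-spline upsampled, rescaled to a stated
  maximum displacement), renders a small z-stack and applies Poisson +
  Gaussian noise. Exact centre correspondences are the ground truth.
  `min_separation` emulates a dispersed particle suspension; the distortion
  and particle-area fixtures use it because blob crowding biases any
  centre-based localization, which is a property of the fixture, not of the
  measurement chain under test.
* `gen_round_series()` builds cumulative rounds obeying the recursive
  carry-over model exactly before offsets and noise, with an identically
  re-stained reference channel, a constant camera baseline (default 0.1)
  and stage offsets that translate content and back-fill with baseline
  (content never wraps; marker volumes are kept a margin away from the
  frame edge so offsets cannot push them out of view). In `"volumes"` mode
  the marker signals are solid 3D regions with exact pairwise overlap
  counts.
* `gen_label_volumes()` / `gen_coloc_volumes()` construct masks as
  consecutive index intervals along the raster order of a shared sub-box:
  each region is one connected component and every pairwise intersection is
  an exact interval intersection, so overlap truth is exact by
  construction.
* `gen_blinking_movie()` renders two-state Markov emitters (started at the
  stationary distribution) with Gaussian PSFs and Poisson sampling over a
  constant background.

Defaults follow the regimes the pipeline is meant for: three staining
cycles, four channels per round including the reference (nine markers plus
the nuclear stain — a ten-color panel), 50–100 frames per SOFI plane,
window lengths 5–30 for z-pairing. Noise levels and blob counts are not
reported by typical study descriptions and were fixed once at values a
practitioner would call realistic for spinning-disk confocal data
(read-noise s.d. ~0.5–1% of signal, a few hundred photons per intensity
unit).

What the generators do *not* emulate: optical sectioning and depth-dependent
blur, chromatic shifts between channels, autofluorescence structure,
photobleaching within a round, and gel-refraction artifacts. Passing tests
therefore demonstrate the correctness and calibration of the measurement
chain, not robustness to every real-world nuisance.

## Numerical choices and degenerate inputs

* Images are doubles in canonical `(channel, z, y, x)` order; coordinates
  are `(y, x)`, 0-based, pixel centres at integers; z-windows are half-open.
* TIFF samples are stored in [0,1] (16-bit losslessly for integer data,
  32-bit float otherwise, with the scale recorded); pixel sizes, channel
  names and the expansion factor live in a JSON sidecar. Missing pixel sizes
  default to 1 µm with a warning, never silently.
* Constant images: keypoint detection errors (nothing to match — the error
  message says to supply a transform manually); MI returns 0 with a
  degenerate flag; a constant movie yields an all-zero cumulant image with
  a warning, not an error.
* RANSAC with an inlier fraction under 25% attaches a low-confidence
  warning; zero inliers is an error. MI grid ties resolve to the smallest
  $\alpha$. Richardson–Lucy requires a PSF normalized to sum 1.
* Problem sizes in the test-suite: 256² unmixing rounds, 128² pre-expansion
  frames (up to 1024² post at scale 8), 16×96×96 end-to-end volumes,
  100-frame 64² movies. These match the regimes above while keeping the
  full suite and the acceptance script each within a few minutes on one
  core.

## Known limitations

* The keypoint detector targets punctate/blob-like fluorescence content; on
  filamentous or textureless scenes SIFT-class detectors would find more
  structure and ours will return few matches (and says so via the
  insufficient-keypoints error).
* Demons registration is plane-matched by default; genuinely 3D deformation
  between rounds would need the full-3D extension.
* Distortion analysis compares one pre-expansion plane against a matched
  projection (2D residuals), as is standard for these validations; axial
  distortion is not measured.
* The MI grid step (0.01) bounds the carry-over resolution; sub-grid
  refinement was deliberately left out so that the reported optimum is
  always an exactly verifiable grid argmin.
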