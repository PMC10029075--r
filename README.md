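# exmquant

Quantitative image analysis for expansion microscopy (ExM) experiments, for
microscopists who need to *validate* an expansion protocol and *process*
multi-round, multiplexed post-expansion data:

* **Distortion quantification** — scale-invariant keypoint matching between
  pre- and post-expansion images, similarity-only (rotation + translation +
  uniform scale) RANSAC, distortion vector fields, and RMS
  length-measurement-error curves in biological micrometres.
* **Expansion-factor estimation** by four routes: keypoint similarity scale,
  particle-area ratios (`sqrt(mean A_post / mean A_pre)`), mean length
  ratios, and whole-tissue size ratios, plus normalization of stacks to
  biological scale.
* **SOFI** — second-order cross-cumulant fluctuation imaging
  (`XC2(a, b) = <dF_a dF_b>_t` on a twice-denser virtual grid, which narrows
  the PSF by sqrt(2)), with subpixel drift/intensity correction and
  Richardson–Lucy deconvolution.
* **Multi-round registration** — rigid (scale-locked) consensus alignment of
  sequential staining rounds on the nuclear reference channel, refined by
  diffeomorphic demons; the reference-channel field transfers to all
  channels of the round.
* **Signal unmixing** for cumulative staining: round *i* observes
  `Image_i = ImageR_i + alpha * Image_{i-1}`; the carry-over `alpha` is found
  by enumerating a grid and minimizing the mutual information
  `I(Image_{i-1}; Image_i - alpha * Image_{i-1})`, then the true signal is
  recovered as `ImageR_i = clip(Image_i - alpha_opt * Image_{i-1}, 0)`.
* **3D colocalization** — adaptive local thresholding, 26-connected particle
  labeling, directional volume-overlap percentages, C×C matrices, group
  means, delta matrices and per-cell one-way ANOVA.
* **Synthetic data generators** with exact ground truth for every stage
  (expansion pairs with controlled warp, cumulative round series, label
  volumes with exact overlaps, blinking-emitter movies).

## Worked example

Simulate a pre/post pair at 4× expansion with a 2 px non-rigid warp, match
it, and quantify:

```r
library(exmquant)

pair <- gen_expansion_pair(n_objects = 30, scale = 4, rotation = 0.05,
                           translation = c(3, 2), warp_amplitude = 2,
                           seed = 14, n_z = 6, min_separation = 12)
proj    <- max_project(pair$post)
matches <- detect_and_match_keypoints(pair$pre, proj, sigma_range_b = c(4, 24))
fit     <- fit_similarity_ransac(matches, inlier_tol = 6, seed = 1)
fit$transform
#> SimilarityTransform: scale 3.99089, rotation 0.0492236 rad, translation (32.04, 5.932) px

expansion_factor(method = "keypoint", params = list(transform = fit$transform))
#> ExpansionEstimate: 3.991 (keypoint method)

field <- distortion_field(fit$matches, fit$transform, pixel_size_pre = 1)
field
#> DistortionField: 24 anchors, |r| mean 0.1645 um, max 0.3252 um
curve <- rms_error_curve(field, seed = 1)
pd <- percent_distortion(curve)
sprintf("percent distortion: %.2f%%", pd)
#> "percent distortion: 0.92%"
```

The recovered scale (3.991 vs the true 4) gives the expansion factor; the
residuals left after the best similarity fit are the distortion, here well
under 1% of the measured length — the regime a good expansion protocol
should reach.

Unmixing a three-round cumulative-staining series:

```r
rounds <- gen_round_series(n_rounds = 3, n_channels = 3,
                           alpha_per_round = c(0.3, 0.6),
                           shape = c(1, 192, 192), seed = 2)
unmix_series(rounds$series)
#> UnmixResult: 3 rounds, reference 'DAPI'
#> alpha_opt:
#>      r2  r3
#> ch1 0.3 0.6
#> ch2 0.3 0.6
```

Both injected carry-over coefficients are recovered exactly to the grid
resolution.

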