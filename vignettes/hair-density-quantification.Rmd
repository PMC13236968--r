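---
title: "Quantifying periocular hair density from facial photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying periocular hair density from facial photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(browquant)
```

## The measurement problem

Chemotherapy-induced madarosis — loss of eyebrow hair during cytotoxic
treatment — is usually graded by eye, with coarse ordinal scales. Ordinal
grading compresses real, continuous density change into a few categories, so
small or asymmetric changes are invisible and a one-step change in the scale
produces a large artificial jump in any derived percentage. `browquant`
implements an operator-independent alternative: the eyebrow is segmented in
standardized frontal photographs and density is measured as the count of
hair foreground pixels inside a fixed, baseline-anchored periocular region.
The quantity reported per timepoint $t$ is

$$\mathrm{retained}(t) = 100\,\frac{A(t)}{A(T1)}, \qquad
  \Delta(t) = 100\left(1 - \frac{A(t)}{A(T1)}\right),$$

where $A = \sum_{x,y} B(x,y)$ is the foreground pixel area of the optimized
binary hair mask $B$ in the baseline coordinate frame. This is a 2-D
projected hair-coverage measure, not a follicle count: it tracks visible
change in the image plane.

## Pipeline

Each capture passes through the following stages; every tunable is a field
of `pipeline_config()` and is echoed into the report for provenance.

1. **ROI extraction** (`extract_roi`). Facial landmarks are detected on a
   width-600 px resized copy of the image (`resize_for_detection`; a fixed
   index subset per eye is configuration, see `periocular_topology()`), and
   the smallest axis-aligned rectangle containing the periocular landmark
   cloud is expanded by a margin $m$ (default 10 px in the resized frame)
   and mapped back to full resolution. Mins are floored and maxes ceiled so
   no landmark is lost to rounding; boxes are half-open and 0-based.
2. **Photometric normalization** (`normalize_luminance`). The HSV value
   channel of each ROI is shifted by a global offset so its mean matches the
   baseline ROI's mean luminance $V_{ref}$, then clipped to $[0,255]$. Hue
   and saturation are untouched. Normalization happens on the unwarped crop,
   before registration, so the registration stage always sees
   brightness-matched inputs.
3. **Trimap generation** (`make_trimap`). The eyebrow landmark polygon is
   expanded vertically by $\delta = 0.30\,h$ (upper points up, lower points
   down), where $h$ is the vertical extent of the eyebrow landmark polygon;
   the convex hull of the expanded points is filled and dilated by an
   elliptical element of radius $0.10\,h$ (a package default; the source
   procedure fixes only the proportional-kernel philosophy, not this
   ratio). The result is the *unknown* region of a trimap. By default no
   definite-foreground core is marked — the entire hull is left to the
   matting backend to decide, the conservative choice — but
   `fg_core_ratio` can mark an eroded hull core as definite foreground.
   The trimap is generated once, on the baseline capture, and reused for
   every registered follow-up, so the same anatomical support region is
   evaluated longitudinally (`regenerate_trimaps = TRUE` switches to
   per-timepoint regeneration for ablation; the regenerated trimap is then
   warped into the baseline frame with `propagate_trimap`).
4. **Two-stage registration** (`register_two_stage`). A coarse homography
   $H_1$ is estimated from the matched periocular landmarks (normalized DLT)
   and the follow-up ROI is warped into the baseline grid. Residual local
   misalignment is then corrected by a fine homography $H_2$ estimated from
   local features — the bundled backend is a Harris corner detector with
   normalized-cross-correlation patch matching, a mutual-best and
   ambiguity-margin test (quasi-periodic hair strands otherwise alias to
   the wrong strand), and subpixel refinement of each match on the local
   correlation surface. $H_2$ is fitted robustly (consensus sampling,
   3 px inlier threshold, deterministic tie-breaks). The total mapping is
   $H_{total} = H_2 H_1$; coarse and fine RMSE are recorded, the fine one
   both on inliers and on all matches, since the two conventions differ.
   If fewer than 4 feature matches are found, $H_2$ falls back to the
   identity and the report is flagged. The registration also exports the
   warp's support mask; trimap pixels never observed in the follow-up crop
   are treated as background rather than as (black) image content, which
   would otherwise contaminate the intensity model below.
5. **Trimap-guided matting** (`segment_hair`). Backends are plugins
   (`function(roi, trimap) -> p in [0,1]`); every backend is forced to
   honor the trimap contract (background $\to 0$, foreground $\to 1$). The
   bundled `baseline` backend splits the unknown region's luminance values
   into two clusters (hair vs skin) by 2-class k-means with deterministic
   min/max initialization; pixels in the dark cluster get the linear ramp
   $p = \mathrm{clip}\!\left((\mu_{skin} - L)/(\mu_{skin} - \mu_{dark}),
   0, 1\right)$, so anti-aliased strand edges receive fractional opacity,
   and pixels in the skin cluster get $p = 0$. Gating by cluster
   assignment is essential: an ungated ramp gives every skin pixel darker
   than the cluster mean a small positive probability, which the
   high-sensitivity threshold below would count as hair. A trained matting
   network can be attached through the same plugin interface; its weights
   are not part of this package.
6. **Post-processing** (`postprocess_mask`). The probability map is stored
   as 8-bit grayscale and binarized at the high-sensitivity threshold
   $\tau = 1$ (strictly greater, on the 0–255 scale). Morphological opening
   (elliptical kernel, diameter $0.05\,h$) suppresses salt noise; dilation
   (diameter $0.07\,h$) consolidates fragmented strands. Kernel diameters
   are rounded to the nearest odd integer $\ge 1$ so the structuring
   element is centered. 8-connected component analysis labels the result
   (labels assigned in row-major order of each component's first pixel, for
   determinism); the largest component $C_{main}$ (ties to the lowest
   label) is always kept and a secondary component is retained only if its
   centroid lies strictly within $\tau_{dist} = 0.50\,h$ of
   $C_{main}$'s centroid *and* its area strictly exceeds
   $\tau_{area} = 0.01\,h^2$. All thresholds are ratios of $h$, keeping the
   filter scale-invariant across subjects; components touching the ROI
   border receive no special treatment.
7. **Quantification and metrology** (`run_pipeline`). The baseline area is
   the mean over the baseline captures, so the baseline timepoint averages
   100% while its replicates still show dispersion. Replicate captures in
   one session yield the intra-session standard deviation (sample, $n-1$),
   and the retained-percentage matrix (timepoint-by-eye rows stacked
   against capture columns by default; `icc_stack` controls the stacking)
   yields ICC(2,1) — two-way random effects, absolute agreement, single
   measurement — with $SEM = Std_{pooled}\sqrt{1 - ICC}$ and
   $MDC = SEM \times 1.96 \times \sqrt{2}$. The pooled Std is the root mean
   square of the per-row Stds. Combined-eye density sums the two eyes'
   pixel areas per capture before the ratio, a single physical quantity;
   per-eye series are reported alongside. `beta_comparison()` expresses
   ordinal BETA scores as percent of baseline (1 dp) for comparison with
   the continuous measure.

## The synthetic study generator

Patient photographs cannot be redistributed, so `scene_spec()` /
`render_session()` generate fully ground-truthed stand-ins: a skin-toned
field with a horizontal illumination gradient, eyes as dark ellipses
(replicates alternate open/closed eyelids, emulating the standard four-shot
acquisition), and each eyebrow as anti-aliased dark strokes with a Gaussian
cross-profile along a quadratic arc. Landmarks come from the generator's
geometric model — exactly, by construction — which isolates the pipeline
from any face detector. Timepoints differ by a known projective transform
(rotation up to 1.5°, translation up to 6 px, mild projective terms);
replicates add photometric jitter (global offset, sd 6 levels) and
sub-pixel translation. Hair loss is planted through per-timepoint retention
fractions applied to *nested* strand subsets (default trajectory
100/85/60/30%), so the ground truth is known both as a strand count and as
mask pixels.

Two generator choices matter for measurement validity and were fixed by
design, not tuned:

- Strands sit on a stratified two-row grid at a spacing that keeps
  neighbours 8-connected after the pipeline's proportional dilation. The
  retention filter presumes a consolidated main component —
  $\tau_{dist} = 0.50\,h$ is much smaller than a brow's width — so a brow
  that fragments into scattered islands would have lateral pieces
  amputated erratically.
- The nesting order is centre-outward: planted loss removes lateral
  strands first (the typical clinical pattern of eyebrow thinning), so
  every retained subset stays contiguous and connected.

What the generator does *not* emulate: photorealistic skin texture,
specular flash reflections, makeup or micro-pigmentation, non-frontal pose
beyond what a homography absorbs, landmark-detector noise (available via
`landmark_sd` but 0 by default), and hair-colour/skin-tone diversity. A
green test suite on these fixtures therefore demonstrates the pipeline's
internal correctness and metrological behaviour under controlled
conditions, not clinical validity on real photographs.

## Numerical choices

- Coordinates are 0-based pixel indices, $(x, y)$ with $y$ growing
  downward; boxes half-open; all rasters are 0–255 numeric arrays.
- Homographies are normalized to $h_{33} = 1$; estimation uses Hartley
  point normalization; consensus sampling breaks count ties by the
  lexicographically lowest inlier set, making the robust path
  deterministic under a fixed RNG seed (`pipeline_config(seed = ...)`).
- Warping is inverse-mapping: bilinear for intensities, nearest-neighbor
  for masks and trimaps (labels can never leave \{0, 128, 255\}); samples
  outside the source are zero-padded and excluded from the measurement
  support.
- The luminance offset is applied in floating point and rounded
  half-to-even once, at the end, to avoid cumulative bias.
- Degenerate inputs fail loudly: identical landmark clouds, zero eyebrow
  height, fewer than 4 correspondences, singular homographies, a zero
  baseline area. An empty component list is not an error — it yields an
  empty mask and a logged warning, since total hair loss is a valid
  clinical outcome.
- `intra_session_std` uses the sample ($n-1$) denominator; with a single
  capture per timepoint the Std fields are null and densities are still
  reported.

## Problem sizes and runtime

The bundled test-suite and acceptance scenes use a 720x540 px face with 20
strands per eyebrow, 4 timepoints and 4 replicate captures (32 eye-level
pipeline executions); one full session runs in well under a minute on a
single CPU. These sizes were chosen so the full study loop stays
interactive; all thresholds being ratios of $h$, results are
scale-invariant by construction and nothing in the method depends on this
particular image size.

## Known limitations

- The baseline intensity-split backend assumes hair is darker than skin;
  light-blond or grey brows would need the deep-matting plugin.
- The retention filter can amputate genuinely disconnected remnants that
  lie farther than $0.50\,h$ from the main component — at extreme loss the
  measure is conservative.
- Percent-of-baseline is undefined without a baseline ($A(T1) > 0$ is
  enforced), and everything downstream inherits the baseline session's
  segmentation quality.
- Intra-session repeatability is the only precision claim the package
  makes; inter-session factors (different days, lighting, operators,
  devices) are outside its scope.

## A worked micro-example

```{r}
# ICC(2,1) of a 3-subject, 2-capture matrix, and the derived SEM/MDC
m <- rbind(c(1, 2), c(3, 4), c(5, 6))
icc_2_1(m)
sem_mdc(std_pooled = 10, icc = icc_2_1(m))

# ordinal BETA scores as percent of baseline
beta_comparison(c(6, 3.8, 1.9, 1.5))
```

```{r, eval = FALSE}
# a complete synthetic study (about half a minute)
session <- render_session(scene_spec(seed = 1))
report <- run_pipeline(session, pipeline_config(seed = 2))
report
write_report(report, "report.json", csv = TRUE)
```
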