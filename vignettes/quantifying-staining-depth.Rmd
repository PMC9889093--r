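---
title: "Quantifying antibody staining depth in cleared tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying antibody staining depth in cleared tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clearquant)
```

## The problem

Tissue clearing makes millimetre-thick blocks of brain optically transparent,
but antibody labeling rarely survives the journey: fixation, hydrogel
embedding, delipidation and heat can each denature epitopes, and the antibody
itself is consumed by binding sites on its way into the tissue. The practical
consequence is that two protocols that look identical at the cut surface can
differ drastically a few hundred micrometres down. Choosing a protocol
therefore requires a *quantitative, depth-resolved* readout of staining
quality, applied identically across many candidate protocols and replicate
tissue sections.

`clearquant` implements that readout as a pipeline over 3D fluorescence
Z-stacks:

1. **Segment** each stack into stained and unstained voxels — either
   internally (percentile normalization → rolling-ball background
   subtraction → threshold) or by importing a mask produced by an external
   pixel classifier.
2. **Quantify** per plane: the fraction of segmented ("indexed") voxels, the
   mean intensity inside the mask (signal), the mean intensity outside
   (noise), and their ratio.
3. **Score**: normalize a chosen per-plane metric by the single maximum over
   all conditions that share a fluorophore, giving a staining-quality score
   in [0, 1] that is comparable across protocols; and reduce each stack to a
   *half-max depth* — the depth at which the staining metric first falls to
   half its maximum.
4. **Compare**: aggregate replicates per condition (mean ± SEM), and test
   every condition against the designated baseline protocol with a
   two-tailed t-test (`*` p < 0.05, `**` p < 0.01), separately per
   fluorophore. Sample identities can be blinded with seeded random codes
   before analysis and unblinded afterwards.

Because the pipeline's correctness cannot be established on real microscopy
data alone, the package ships a first-class synthetic-stack generator with
known ground truth; every stage is validated against it.

## The half-max depth estimator

For a per-plane series $m(z)$ (mean in-mask intensity by default), the
estimator:

1. finds the *start plane*: the metric is smoothed by a centred moving
   average (window 3 planes, truncated at the edges, undefined planes counted
   as zero) and the start is the first plane reaching 10% of the smoothed
   maximum. This keeps mounting-medium planes above the tissue surface from
   inflating depth.
2. takes the maximum of the raw series from the start plane on, skipping
   undefined planes;
3. finds the first pair of consecutive defined planes at or after the
   maximum where the series crosses half the maximum from above, and
   linearly interpolates the crossing depth;
4. reports the depth in µm relative to the start plane. A profile that never
   drops below half its maximum yields an undefined (`NA`) depth with the
   maximum still recorded — it is never silently coerced to the stack depth.

First-crossing-after-maximum with linear interpolation is deterministic and
conservative for noisy profiles; no multi-crossing heuristics are applied.
Empty-mask planes give *undefined* signal rather than zero, so a plane with
no detected staining cannot fake a crossing. Depth is voxel-indexed (0-based
plane index × plane spacing); anisotropy is handled solely through the plane
spacing, with no resampling.

Both the intensity metric and the area metric are computed and reported side
by side; intensity is the default reduction, while the area fraction is the
natural figure of merit when the antigen is uniformly distributed over depth
(see `figure_of_merit()`).

## Why the internal segmentation default is a fixed threshold

The internal route thresholds the very intensities that the depth profile is
later measured on. An *adaptive* threshold (Otsu) computed from the
whole-stack histogram lands near the middle of the foreground intensity
range — which, in an attenuated stack, is roughly the intensity at the
half-max depth itself. The mask then dies at almost exactly the depth the
intensity profile needs to cross, and the measured profile floors at the
threshold: half-max depths become undefined or collapse onto the threshold's
own cutoff. The area-fraction profile has the complementary problem under
sparse geometries: with few features per plane it is too lumpy for a
first-crossing rule.

The default is therefore a *fixed, permissive* threshold of 0.2 in
normalized units — a voxel is stained if, after rolling-ball background
subtraction, it exceeds background by 20% of the bright-staining intensity
range (about six standard deviations of the default noise). This keeps the
mask's reach well beyond the half-max crossing without tying the mask to the
depth distribution of intensity. Otsu remains available
(`threshold_mask(method = "otsu")`) and is validated against an exhaustive
between-class-variance search. Externally produced classifier masks, which
are intensity-independent by construction, are the preferred route for
intensity-based half-max on real data and are imported unchanged.

Other segmentation choices:

* **Rolling-ball background** is grayscale morphological opening with a flat
  disc element (radius default 5 feature radii in pixels, 8 px when the
  feature scale is unknown); it is anti-extensive and idempotent, and runs
  per-plane in 2D, as background and illumination vary by plane. The classic
  curved-ball (paraboloid) variant is available behind
  `method = "paraboloid"`.
* **Thresholding is strict** (`value > t`), giving deterministic boundary
  behaviour; probability maps are binarized the same way, so a map of all
  0.5 yields an empty mask at the default 0.5 cut.
* **Normalization percentiles** default to 0.1/99.9 to resist hot pixels,
  and are computed over the whole stack — per-plane normalization would
  erase the depth attenuation that is the signal of interest.

## The synthetic generator

The generator emulates what the pipeline will meet in practice: 0.5 mm-deep
stacks (default 128 × 128 × 100 voxels at 5 µm spacing) containing
sphere-like features (neuronal nuclei), tube-like features (vasculature) or
filament-like features (astrocytic processes), at a target in-feature voxel
fraction (default 2%, characteristic radius 15 µm). Placement is rejection
sampling with overlap allowed; a candidate that would overshoot the target
fraction by more than the current shortfall is rejected, keeping the
realised density within about ±20% of the target. A voxel belongs to a
feature iff its centre lies within the feature radius.

Staining intensity attenuates with depth according to one of three models:

* **sigmoid** — $f(z) = 1/(1 + e^{(z - d_{1/2})/w})$: a penetration front at
  $d_{1/2}$ with width $w$ (default 15 µm). The width default is deliberately
  small relative to the half-depths of interest (≥ 50 µm): depletion fronts
  are sharp, and a saturated surface matches the common observation that
  candidate protocols look alike at the cut face and differ only at depth.
  A wide front also biases any half-of-maximum estimator, which reads
  $d_{1/2} + w \ln((1-f_0/2)/(f_0/2))$ when the surface factor $f_0 < 1$.
* **exponential** — $f(z) = 2^{-z/d_{1/2}}$: halving per $d_{1/2}$.
* **pde** — the normalized bound-antibody profile of a one-dimensional
  reaction–diffusion model with depletion:
  $\partial_t c = D\,\partial_z^2 c - k\,c\,(B - b)$,
  $\partial_t b = k\,c\,(B - b)$, bath concentration fixed at the surface,
  zero flux at the far boundary. Solved by explicit finite differences; the
  diffusive stability bound $\Delta t \le \Delta z^2 / 2D$ is *enforced*,
  never silently corrected, and any negative concentration aborts with
  advice to increase the step count. In the strong-binding regime
  ($kB \gg D/\Delta z^2$) the front obeys the mass-balance scaling
  $z_f \approx \sqrt{2 D c_0 t / B}$, i.e. it doubles when incubation time
  quadruples — the classic signature of depletion-limited penetration, and a
  property the tests verify to ±15%.

Rendered intensity is
`amplitude × attenuation(depth) × truth + background + noise`, with optional
Gaussian read noise, signal-dependent (shot-like) noise, and an isotropic
Gaussian blur as a crude optical PSF. Defaults: amplitude 0.8, background
0.05, read noise SD 0.02, shot noise on, blur 2 µm. Blur is applied after
noise — a non-physical ordering chosen for simplicity and documented as
such. Penetration is one-sided (from plane 0) by default; `two_sided = TRUE`
takes the maximum of the profile and its mirror, for free-floating sections
stained from both faces.

What the generator does **not** emulate: realistic optics (light-sheet
stripes, refractive-index aberrations, depth-dependent PSF), spectral
crosstalk, photobleaching, non-uniform antigen distributions, or the texture
of real tissue backgrounds. Passing tests therefore demonstrate that the
*measurement machinery* is correct and well calibrated on stacks whose
ground truth is known — not that any particular real protocol will be ranked
correctly.

## Replicate comparison

Condition sets default to N = 3 replicates per condition, the typical
sample size for this kind of protocol screen. Replicate seeds derive
deterministically from one master seed, so a whole simulated experiment
regenerates bit-identically. When `shared_scene = TRUE` (default), replicate
*r* of every condition shares its geometry, so conditions differ only in
attenuation and noise.

Comparisons use Student's pooled-variance two-tailed t-test by default
(the equal-variance assumption is reasonable for replicates of a common
tissue source); Welch is available and recorded in the output. No
multiplicity adjustment is applied by default, matching the per-condition
star convention; a Bonferroni flag exists and is logged when used.
Conditions are never compared across fluorophores. SEM uses the sample SD
(n − 1) over √n, and a single replicate yields an undefined SEM rather than
zero.

## Numerical and I/O conventions

* Planes are 0-based (z = TIFF page index); depth in µm is derived only at
  reporting time.
* Multipage single-channel TIFF is the interchange format: stacks stored as
  32-bit float in [0, 1] (single precision round-trip), masks as 8-bit
  binary (exact round-trip). Plane spacing travels in the manifest, not in
  TIFF tags.
* The YAML manifest validates: exactly one baseline condition per
  fluorophore group, unique file paths, positive plane spacing; unknown keys
  warn rather than fail. Every default that was filled in is written to the
  run log, along with the seed and package version; the log contains no
  timestamps, so a seeded run is byte-reproducible.
* A failing sample is logged and excluded; the remaining samples complete
  and the failures are listed in the result.

## Validation problem sizes

The test-suite validates against brute-force oracles at small sizes (exact
per-voxel accumulation up to 16 × 16 × 8; exhaustive sliding-ball backgrounds
on 16 × 16 planes at radii 1–3; exhaustive Otsu over all 256 histogram cuts)
and against ground truth at study scale: half-max recovery and five-way
ranking use full 128 × 128 × 100 stacks at 5 µm spacing with default noise
and N = 3. The repeated-simulation statistics (null calibration and power of
the baseline t-test, 100 repetitions each) use a reduced 32 × 32 × 80
geometry at 6.25 µm spacing — the same 500 µm depth with smaller planes,
correspondingly finer and denser features (8 µm radius at 4% density, so
every depth range still contains features and profiles stay gap-free), and
threshold-only segmentation — chosen so that hundreds of full pipeline runs
remain quick while preserving the estimator's noise characteristics.

## Known limitations

* The attenuation models are stand-ins: no quantitative penetration model
  has been fitted to archived cleared-tissue images, so parameter realism is
  untested against real data.
* The intensity half-max on internally segmented masks is meaningful only
  while the mask extends beyond the half-max crossing; with very high
  thresholds it inherits the floor artifact described above. The package
  reports both metrics so the area-based reduction can be cross-checked.
* Whether depth should be measured one-sided or symmetrically for
  free-floating sections stained from both faces is a judgment call; the
  generator supports both, the quantifier measures from the detected start
  plane only.
* Object-level statistics (counts, morphology), colocalization and 3D
  rendering are out of scope.

## A worked example

```{r example, eval = FALSE}
library(clearquant)

conditions <- data.frame(
  condition_id = c("baseline", "delip2d", "delip3d"),
  d_half_um = c(150, 250, 90),
  baseline = c(TRUE, FALSE, FALSE)
)
set <- generate_condition_set(conditions, n_replicates = 3, seed = 42)

halfmax <- do.call(rbind, lapply(seq_len(nrow(set)), function(i) {
  stack <- set$stack[[i]]
  mask <- segment_stack(stack)
  prof <- plane_metrics(stack, mask)
  cbind(half_max_depth(prof), baseline = set$baseline[i])
}))

cmp <- compare_conditions(halfmax)
tidy(cmp)
autoplot(cmp)
```
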