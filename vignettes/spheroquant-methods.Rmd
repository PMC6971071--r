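---
title: "Methods: objective thresholding and invasion indices for spheroid assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: objective thresholding and invasion indices for spheroid assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroquant)
```

## The measurement problem

A spheroid invasion assay embeds a multicellular aggregate in an
extracellular-matrix gel and follows it by daily brightfield imaging. The
object is dark on a bright background, but not uniformly so: the center is
a tightly packed, nearly opaque **core**; around it lies a loosely
aggregated grey **intermediate** zone; the invading front is an **edge**
of thin projections and scattered cells with weak contrast against the
gel. Quantification therefore faces two coupled problems: where to put the
intensity threshold(s), and what summary number to report.

Cumulative parameters — total cell-covered area, maximum invasion length,
detached-cell counts — keep increasing as cells both proliferate and
invade, so they cannot distinguish a spheroid that grows from one that
disperses. The zone decomposition separates the two: proliferation
enlarges all zones roughly in proportion, while invasion converts
aggregated area into edge. The invasion indices

$$
\mathrm{index~A} = 100\,\frac{A_\mathrm{edge}}{A_\mathrm{all}},
\qquad
\mathrm{index~B} = 100\,\frac{A_\mathrm{edge}+A_\mathrm{intermediate}}{A_\mathrm{all}}
 = 100\,\frac{A_\mathrm{all}-A_\mathrm{core}}{A_\mathrm{all}}
$$

are intensive: under pure (isotropic) growth the numerator and denominator
scale together and the indices stay put; under invasion they rise. This is
the property the acceptance suite checks explicitly on synthetic series.

## Threshold detection from the profile derivative

`detect_thresholds()` operationalizes the objective threshold procedure:

1. **Profile.** A bar through the spheroid center, spanning the image,
   averaged over `bar_width` pixels perpendicular to it (default 10; the
   averaging suppresses single-row pixel noise by √10). The bar must start
   in clean background on the scanned side.
2. **Smoothing.** Centered moving average of `window = 20` pixels. At a
   typical low magnification 20 px corresponds to roughly the diameter of
   6–7 cells, enough to suppress cell-scale texture while keeping zone
   transitions sharp. At the profile ends the window truncates to the
   available samples rather than padding, so no out-of-image intensities
   are invented and constant regions stay exactly constant. For even
   windows the window at position *i* covers `[i - (w-1)%/%2, i + w%/%2]`.
3. **Derivative.** Central differences at interior points, one-sided at
   the two ends (exact for linear ramps; same output length).
4. **Downward peaks.** A downward peak is a local minimum of the
   derivative at least `min_prominence = 0.5` intensity units/pixel below
   zero. Scanning inward from the chosen side (left by default; estimates
   from the two sides of a centered spheroid agree closely, and fixing one
   side makes results comparable), the first three peaks before the
   profile's global minimum give, in order, `t_all`, `t_intermediate`,
   `t_core`. Two refinements make the peak location robust on sampled,
   noisy data:
   - *Clustering:* candidate minima closer together than half a window are
     ripple splits of one physical trough; the deepest (earliest on a
     depth tie) represents the cluster.
   - *Sub-pixel centroid:* the reported position is the depth-weighted
     centroid of the trough's half-depth region. An argmin alone jitters
     by a pixel or two on the flat bottom of a broad trough, which at a
     typical boundary slope of 3–4 intensity units/pixel would move the
     threshold by several units; the centroid of a symmetric trough is its
     center to well under a pixel.
5. **Threshold intensity.** The smoothed profile, linearly interpolated at
   the refined peak position. For a symmetric transition this is the
   midpoint intensity of the two adjacent zones.

Detection fails loudly — with the number of peaks found — rather than
guessing when fewer than the requested peaks qualify, and rejects cutoff
triples that are not strictly decreasing (a profile whose transitions are
not separable at the chosen window). Transitions closer together than
about 1.5 smoothing windows leave a structural saddle in the derivative
near the prominence cutoff and are the practical limit of the procedure;
the phantom defaults keep boundaries 40–45 px apart for the 20-px window.

For well-contrasted spheroids free in suspension a single threshold
suffices: `suspension_threshold()` takes the minimum intensity over the
outermost 10% of positions at each end of the bar (the surrounding medium)
minus a safety margin (default 5).

`threshold_set` objects carry a provenance record (peak positions, window,
side, prominence) and serialize to JSON so that one detected set can be
reapplied to a whole experiment.

## Segmentation and subareas

- **Foreground convention:** intensity ≤ cutoff. Ties go to the darker
  region, so a cutoff read at a transition point belongs to the zone it
  bounds.
- **Nesting by construction:** `mask_all` is particle-filtered; the darker
  binarizations are intersected with it. Subareas are set differences, so
  `A_edge + A_intermediate + A_core = A_all` holds exactly for every
  input, a property asserted on hundreds of random images and phantoms.
- **Particle filter:** 8-connected components (matching the diagonal
  behavior of common particle analyzers) below `min_area = 50` px² are
  removed at the "all" level only; filtering inner levels independently
  could break nesting. The right `min_area` depends on magnification and
  debris; it is a user parameter, and detached invading cells smaller than
  it will be discarded with the debris.
- **Perimeter:** crack length — the number of unit edges between
  foreground and background (or out-of-image) pixels. It is exactly
  defined, integer, and oracle-testable; since downstream use is the
  *relative* perimeter, any consistent convention gives the same ratios.
- 8-connected labeling and the topology-preserving thinning used for
  end-point counting are small compiled routines (two-pass union-find;
  Zhang–Suen) because no suitable 8-connectivity/thinning primitives were
  available in the package's R dependencies.

## Conventional parameters

- **Relative area / perimeter:** frame value divided by the reference
  frame's value (day 0 or untreated control).
- **Maximum invasion length:** max over cell-covered pixels of the
  Euclidean distance to the *reference* centroid, minus the reference
  equivalent radius `sqrt(A_ref/π)`, clamped at 0. Measuring radially from
  the reference centroid with an equivalent-radius edge is
  rotation-invariant and well defined for irregular spheroids, where "the
  edge of the initial spheroid" is otherwise ambiguous.
- **End-point voxels:** the mask is thinned to a 1-px skeleton and
  skeleton pixels with exactly one 8-neighbor are counted; each sprout
  contributes one. Thinning of large solid blobs can generate spurious
  interior branches, so tests assert lower bounds and monotonicity in the
  number of designed protrusions rather than exact counts, and the number
  is best read comparatively along a series.
- **Detached cells:** 8-connected components other than the single largest
  one, with area ≥ `min_size` (default 20 px²; the literature rarely
  states a cutoff, so it is exposed as a parameter).
- **Volume:** `(4/3)π r³` with `r = sqrt(A/π)` — a sphericity assumption
  appropriate for compact spheroids in suspension, increasingly nominal
  once invasion makes the outline stellate.
- **Roundness:** `4A/(π L²)` with `L` the major-axis length of the
  moments-equivalent ellipse (`L = 4\sqrt{\lambda_{max}}` from the pixel
  coordinate covariance), the convention of common image-analysis tools; a
  disk scores 1 (values are clamped into (0, 1] against discretization
  overshoot, and a single-pixel mask is defined as round). **Equivalent
  diameter:** `2\sqrt{A/π}`.

## The phantom generator

`generate_phantom()` emulates exactly the image structure the method
assumes: concentric zones at intensities (50, 110, 170) on a 230
background by default, blended by logistic transitions of width 8 px (so
the derivative has well-defined, symmetric troughs, mimicking the gradual
intensity falloff of real aggregates); thin radial spikes at edge
intensity for protrusions; detached disks beyond the body; additive
Gaussian pixel noise, clipped to [0, 255] and quantized. Ground truth
(masks with hard boundaries at the nominal radii, designed
transition-midpoint intensities, blob centers) comes from the noiseless
geometry. All randomness (angle jitter, blob placement, noise) is driven
by the spec's seed; identical specs give bit-identical images.

Default geometry: 384-px field with zone radii (40, 80, 125). The
boundary spacings of 40–45 px match the proportions seen in real day-3
invasion micrographs and are comfortably above the ~1.5-window separation
limit discussed above. The default detached radius of 5 px (~78 px²)
keeps blobs above both the default particle filter (50 px²) and the
detached-size cutoff (20 px²), so noiseless phantoms have exactly
countable detached cells. Protrusion spikes and blobs are kept clear of
the horizontal center line, where `run_timecourse()` draws its profile
bar — the synthetic counterpart of an experimenter placing the bar
through clean background, which the detection procedure presumes.

`generate_time_course()` holds background and zone intensities fixed
across frames, so one threshold set applies to the whole series — the
situation that makes batch processing of a real experiment valid.
**Growth** is a per-frame fractional increase applied multiplicatively to
all three zone radii: isotropic proliferation, which preserves zone-area
ratios and hence the indices — exactly the discrimination property the
indices claim. (Additive equal increments would instead thin the outer
annuli and drift the indices downward, conflating geometry with biology.)
**Invasion** is additive: more/longer protrusions and more detached blobs
per frame, leaving the designed core untouched.

What the phantoms deliberately do not model: optics (point-spread
function, defocus), illumination gradients or vignetting, cell texture,
and motility dynamics. Passing tests therefore demonstrate correctness of
the measurement chain on images satisfying the method's assumptions — not
robustness to uneven illumination, which real pipelines must handle
upstream (the package preserves raw intensities and leaves any
normalization between days to the user).

## Pipeline and reproducibility

`run_timecourse()` orders frames lexicographically by filename, detects
thresholds once on the reference frame (override or per-frame re-detection
available), segments every frame with the same set, and emits one CSV row
per frame with all metrics. Floating-point columns are written with fixed
6-decimal formatting, so identical inputs reproduce the CSV byte for byte.
A run log records every parameter and the detected thresholds.

Coordinates are 1-based (row, column) matrix indices; a pixel is the unit
cell, areas are pixel counts. With a µm/px calibration, lengths scale by
it, areas by its square, volumes by its cube.

Problem sizes in the test and acceptance suites — 384-px phantoms, grids
of 45 detection runs and 18 segmentations, 4-frame series, 100–400 random
masks against brute-force oracles — were chosen to exercise every code
path at full default geometry while keeping a complete run in the low
minutes on one core.

## Known limitations

- The derivative procedure needs three separable transitions; very
  invasive spheroids whose intermediate zone has dissolved, or bars placed
  through protrusions, fail detection (by design, with an error naming the
  number of peaks found).
- One threshold set per experiment presumes stable illumination and
  exposure across days.
- End-point counts inherit thinning artifacts on large solid bodies.
- The spherical volume and the moments-based roundness are descriptive
  conveniences for compact shapes, not measurements of 3-D structure.
- 2-D connected components stand in for the 3-D object counting used with
  image stacks; on single micrographs per frame the two coincide.
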