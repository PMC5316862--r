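---
title: "Quantifying in vitro cyst formation from brightfield z-stacks"
author: "cystometer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying in vitro cyst formation from brightfield z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystometer)
```

## The measurement problem

Primary renal epithelial cells from polycystic kidneys, plated as single
cells in 3D Matrigel, form hollow spheroids ("cysts") over about a week.
Drug effects on cystogenesis are read out as the number and total volume of
cysts per well. Each well is imaged in brightfield at a series of focal
planes down the z axis (by default 28 planes, 150 µm apart, 2448 × 1920 px
frames). Two properties of these images drive the design of the pipeline:

* a cyst is translucent, so in any plane near its equator it appears as a
  **dark ring** (the optical section of its wall) rather than a filled blob;
* a cyst is usually **larger than the plane spacing**, so the same cyst
  appears in several consecutive planes and naive per-plane counting
  overcounts.

The analysis therefore proceeds in three stages: per-plane segmentation of
ring-like objects, rule-based rejection of debris and artifacts, and
z-axis deduplication with spherical volume estimation.

## Per-plane segmentation

Each plane is processed by a fixed operator chain
(`segment_plane()`):

1. **Grayscale conversion** with the usual luminance weights
   (0.299, 0.587, 0.114), since source images are 24-bit colour TIFFs.
2. **Artifact masking** (`mask_artifacts()`): pixels under a user-supplied
   mask are replaced by the median intensity of the rest of the plane, so a
   scratch or dust spot can never seed foreground. How artifacts are
   *identified* is outside the package's scope; the mask is an input.
3. **Laplacian high-pass** (`laplacian_highpass()`): the discrete 3 × 3
   Laplacian (centre −4, edge neighbours +1). By default the **absolute**
   response is used so that both the dark-to-light and light-to-dark sides
   of a ring wall respond; a signed mode exists for diagnostics. Borders
   are handled by symmetric reflection, which avoids spurious responses at
   the frame edge. Kernel sizes above 3 switch to a Laplacian-of-Gaussian
   with σ = size/6 for noisier material.
4. **Adaptive threshold** (`adaptive_threshold()`): a pixel is foreground
   iff its response exceeds the mean response in the surrounding
   51 × 51 px window by more than the offset. The local mean makes the
   threshold robust to slow illumination gradients.
5. **Refinement** (`refine()`): dilation with a disc structuring element
   (radius 3 px), hole filling, erosion with the same element. Dilation
   closes small gaps in the detected wall; hole filling turns the closed
   ring into the cyst's full cross-section; erosion restores the outline.
   Hole filling is defined as "background components not connected to the
   image border become foreground", with background connectivity
   complementary to the foreground connectivity.
6. **Labeling** (`label_objects()`): connected components
   (8-connectivity by default), labels assigned in raster order.

### Choice of the threshold offset

The operator chain fixes *what* is computed; the offset decides *how much*
evidence an edge needs. On 8-bit images with additive sensor noise of
standard deviation σ, the 3 × 3 Laplacian amplifies noise by a factor
√20 ≈ 4.5, so the absolute response has a noise floor of roughly 3.6σ
(mean of the folded normal) with spread ≈ 4.5σ. An offset near the noise
floor floods the mask: in calibration runs at σ = 1 an offset of 2
produced a single merged foreground object covering the frame. The default
offset of **10** sits ≈ 2 standard deviations above the noise floor at
σ = 1 while remaining about half the measured response of a typical cyst
wall (15–25 units for a rim darkened by 50–70 % against the background).
Residual noise specks that survive thresholding are small and are removed
by the minimum-radius rule downstream; the failure mode that matters is
merging, not speckle. All parameters are exposed in
`segmentation_params()` and recorded in each well summary as a
fingerprint.

## Object statistics and exclusion rules

For every labeled object, `compute_features()` reports area, centroid, the
distribution of **centroid-to-boundary distances** (boundary = object
pixels with a background 4-neighbour), summarized as `mean_radius` and its
coefficient of variation, and the **eccentricity** of the
second-central-moments equivalent ellipse, √(1 − λ₂/λ₁). The
moments-ellipse convention is used because it maps a circle to 0 and keeps
the whole [0, 1) range usable against the 0.75 cut; whether the original
assay used this or the axis-ratio convention is not documented, so the
choice is stated here rather than asserted. The radius CV is defined over
the boundary-distance distribution because a *coefficient of variation of
the radius* requires a radius distribution, and boundary distances are the
natural one.

`filter_objects()` removes an object if any of four rules fires:

| rule | boundary behaviour |
|---|---|
| mean radius ≤ 15 px | 15.0 px is rejected |
| mean radius > 200 px | 200.0 px is kept |
| radius CV > 0.2 | 0.2 is kept |
| eccentricity > 0.75 | 0.75 is kept |

The four rules are checked in a fixed order only for reporting the
rejection reason; the keep/reject outcome is order-independent, and the
kept and rejected sets always partition the input.

## Z-axis deduplication and volume

`link_across_planes()` links two kept objects in **adjacent** planes when
their pixel footprints share at least one pixel; cysts are the connected
components of this graph. Footprint overlap was preferred over centroid
containment (also available, `mode = "centroid"`) because ring-derived
cross-sections can have noisy centroids while their footprints overlap
robustly. Objects two or more planes apart are never linked directly, so a
one-plane gap splits a cyst — deliberate, since a true cyst is convex in z
and cannot skip a plane it intersects. When one object overlaps several in
the next plane all of them merge (pure connected components, no splitting
heuristic).

Each cyst's volume is the sphere volume (4/3)πr³, with r the
`mean_radius` of the **largest-area** member (area, not radius, is used to
select the equatorial section because it is the "size" statistic and is
monotone in the chord for a sphere). Ties go to the lower plane index.
Volumes are converted to µm³ via `pixel_size³`. `summarize_well()` and
`summarize_groups()` aggregate counts and volumes per well and per
treatment group (mean, s.e.m. = sd/√n flagged NA for single-well groups,
and percent-of-control on mean counts). Hypothesis testing between groups
is left to standard tools (`t.test`, `aov`).

## The phantom generator

`generate_stack()` renders scenes with known ground truth so every claim
above is testable. A sphere of radius R centred at depth z₀ occupies
exactly the planes with |z − z₀| < R, with cross-section radius
√(R² − (z − z₀)²) — so a 60 µm sphere at a plane's depth appears only in
that plane (the neighbours are 150 µm away), while a 300 µm sphere spans
three planes. Appearance is contour-based: a mid-grey background (128), a
dark wall band 3 px wide (darkened by `rim_contrast`, default 0.7), a
lumen slightly brighter than background (160), Gaussian blur (σ = 1.5 px),
additive Gaussian noise (default σ = 1 grey level), 8-bit quantization.
Contour rendering was chosen over solid fills because a solid disc
presents a single intensity step whose Laplacian response is about half a
wall's double step — and because that is what brightfield actually shows.

`generate_distractor_suite()` supplies one violator per exclusion rule: a
10 px debris disc, a 210 px oversize blob, a 2:1 ellipse (eccentricity
0.866), a five-lobed shape (radius CV ≈ 0.28) and a disc crossing the
border (imaged as an open arc, rejected by the CV rule). Distractor kinds
are rendered as **planar** artifacts in the single plane nearest their
depth, not as spheres: a 210 px sphere's chord one plane away (≈ 185 px)
would fall inside the keep band and defeat the very rule the distractor
exists to exercise, and real debris (dust, bubbles, fibres) is effectively
planar at 150 µm spacing. The spherical occupancy contract applies to
`kind = "cyst"` objects only.

Synthetic test scenes place cyst centre depths **at plane depths**, so the
widest rendered cross-section equals the true radius and the recovery of
radius and volume measures the method rather than scene placement: a
centre mid-way between planes would shrink the widest chord of a 150 µm
sphere by 13 % and its estimated volume by 35 % before the pipeline ever
ran. `true_cross_section_radii()` reports the widest rendered chord per
cyst for scoring in either layout.

What the phantom does **not** emulate: physically accurate optics (no PSF
or refraction model — blur is a single Gaussian), fluorescence,
illumination gradients, well-to-well variation, touching or nested cysts,
and partial wall loss from focus drift. Passing recovery tests on the
phantom therefore demonstrates correctness of the operator chain and its
statistics, not robustness to every real-world imaging pathology.

## Companion assay statistics

* **Seed families** (`assign_seed_family()`): miRNAs sharing nucleotides
  2–8 of the mature sequence form one family. The family's **cumulative
  fold change** is the log2 ratio of summed member group means — the fold
  change of the family's pooled signal, which stays well-defined when
  members differ in abundance. The alternative reading (sum of per-member
  log2 fold changes) is implemented behind `method = "sum_log2"`; the
  pooled form is the default and is the interpretation this package
  commits to. Both a significant-members-only and an all-members variant
  are reported, along with each family's percentage of the total miRNA
  pool per group. Counts are assumed platform-normalized on input.
* **miPSA displacement** (`mipsa_displacement()`): the double-delta-Ct
  estimator, ΔCt = target − reference per condition, displacement =
  ΔCt(treated) − ΔCt(control), in log2 units; positive values mean loss of
  the target miRNA from the assayed polysome fraction. The estimator is
  exactly invariant to reference-wide Ct shifts.
* **ATP-linked OCR** (`atp_linked_ocr()`): mean basal OCR minus mean
  post-oligomycin OCR from a BOFA trace; a negative value is returned with
  a warning rather than clamped, as it usually flags a failed injection.

`planted_expression_model()` / `generate_expression_table()`,
`generate_mipsa_table()` and `generate_ocr_trace()` generate tables with
planted parameters for all three statistics; with dispersion or noise set
to zero the estimators recover the planted values exactly, which the test
suite asserts.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based (row, column), origin top-left, matching R
  matrix indexing; bounding boxes are inclusive. All radii and areas are
  in pixels until the explicit µm conversion.
* The adaptive-threshold local mean is computed by an integral image over
  a symmetrically reflected padding; on integer-valued images it is exact,
  and it agrees bit-for-bit with a per-pixel sliding-window reference.
* Labels are deterministic: 1..n in raster order of each component's first
  pixel, for any connectivity.
* Single-pixel objects: mean radius, radius CV and eccentricity all 0 by
  convention (they are removed by the minimum-radius rule regardless).
* An artifact mask covering the whole plane, a window larger than the
  image, zero control counts in a fold change, a missing gene × condition
  cell, and a missing BOFA phase are all hard errors, not silent NAs.
* Generators accept one integer seed, restore the caller's RNG state, and
  are bit-reproducible for equal seeds.

## Worked example

```{r example, eval = FALSE}
geom <- stack_geometry(n_planes = 28, width = 612, height = 480,
                       pixel_size = 1.5)
depths <- plane_depths(geom)
scene <- c(list(sphere_spec(300, 250, depths[3], radius = 60),
                sphere_spec(650, 500, depths[5], radius = 90)),
           generate_distractor_suite(geom, seed = 2))
sim <- generate_stack(geom, scene, seed = 2)
res <- quantify_stack(sim$stack, well_id = "demo")
res$well
#  2 cysts; distractors rejected with reasons in res$rejected$reject_reason
```

## Problem sizes used in the checks

The bundled tests and the acceptance script run on 612 × 480 px frames
(a 4× downscale of the nominal 2448 × 1920 acquisition) with the full 28
planes, scenes of 1–12 spheres of 25–60 px radius, and the five-distractor
suite; the expression model uses 2–4 families × 2–4 members × 3 + 3
samples. These sizes keep a full run in minutes while every object class
and code path is still exercised; nothing in the implementation depends on
frame size, and the defaults target the full acquisition geometry.

## Known limitations

* Cysts whose cross-sections touch in the same plane merge into one object
  (no watershed splitting); well-plated assays keep densities low enough
  that this is rare.
* The wall must be detected as a closed contour in at least one plane; a
  heavily broken contour fails hole filling and the fragments are
  (correctly, from the rules' point of view) rejected.
* Volume assumes sphericity; elongated cysts are either rejected by the
  eccentricity rule or mis-volumed.
* The original assay's artifact-identification procedure and its exact
  eccentricity convention are not documented; this package states its own
  choices and exposes them as parameters rather than claiming equivalence.
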