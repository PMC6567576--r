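---
title: "Mask propagation: augmenting images together with their annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mask propagation: augmenting images together with their annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maskaug)
```

## The problem

Deep models for bioimage analysis are data-hungry, and annotated bioimages
are expensive: acquisition is hard and labelling needs experts. Data
augmentation — generating new training examples by applying
label-compatible transformations to existing ones — is the standard remedy,
but most augmentation tooling only covers *classification*, where the label
survives any transform untouched. For localization, detection, semantic
segmentation and instance segmentation the annotation encodes **where**
objects are, so a flip or rotation silently invalidates it.

`maskaug` closes that gap. Its organising idea is simple: techniques split
into two categories.

* **Position-invariant** techniques (blurs, noise, gamma, histogram
  equalisation, colour jitters, ...) change pixel values but not object
  positions. The transformed image is paired with the *original* annotation,
  verbatim.
* **Position-variant** techniques (flip, rotation, translation, crop,
  rescale, shear, elastic deformation) move pixels. Here the annotation is
  converted to one or more raster masks, the masks are warped with the
  *exact same* geometric transform as the image, and the annotation is
  re-derived from the warped masks.

For a bounding box the round trip is: render the box as a black image with a
white rectangle, warp it, and take the tight box of the surviving white
region. For detection this happens per box; for instance segmentation per
instance mask; for semantic segmentation the label image itself is warped.
A box or instance that shrinks too much (or leaves the canvas) is dropped
by a configurable keep policy.

## The shared geometric plan

The correctness of the whole scheme rests on one object: the
`GeometricPlan`. `resolveGeometry()` materialises *all* randomness of a
position-variant technique — a rotation angle sampled from a range, the
crop window position, the elastic displacement field — into an inverse
coordinate map (for every output pixel, the continuous source coordinate it
draws from). `applyGeometric()` then replays that map on any same-shaped
raster:

* `smooth` (bilinear) interpolation for photographic images;
* `nearest` for every label or mask raster. Nearest-neighbour resampling
  can only copy values that already exist, so a warped label image can
  never contain an interpolated, meaningless label code. This choice is
  forced by the semantics of label rasters, not by aesthetics.

Because image and masks share one plan, the package can state — and its
test suite checks exhaustively on small rasters — that wherever a one-hot
pixel lands in a warped mask, the corresponding image pixel landed too.

Conventions: 0-based `(row, col)` coordinates, origin top-left; rotation
and shear about the image center; canvas size preserved (no expansion)
except for crop and rescale; vacated regions filled with 0. Bounding boxes
are 0-based and half-open internally; the VOC codec converts exactly to
VOC's 1-based inclusive dialect, and the YOLO codec round-trips to within
half a pixel (6-decimal fixed formatting).

## Multi-dimensional images

A z-stack or video is an ordered list of 2D frames. `augmentStack()`
resolves **one** plan per stack and applies it to every frame and every
frame's annotation. A single elastic displacement field therefore deforms
all focal planes coherently — warping frame 3 is bitwise identical to
warping frame 1 when their content is identical. Videos are handled as
frame folders or multi-page TIFFs; the package deliberately contains no
video codec.

## Generation modes and accounting

With `n` originals and `m` techniques:

* **linear** mode applies each technique once to each original: at most
  `n * m` generated images, and `nGenerated + nDiscarded = n * m` exactly.
* **power** mode chains stages: `D_0` are the originals and
  `D_i = D_(i-1) + technique_i(D_(i-1))`, so the new images number
  `(2^m - 1) * n` and their provenance chains are exactly the non-empty
  ordered subsequences of the technique list. One ambiguity had to be
  resolved here: a stage could in principle also re-feed its *own* outputs.
  We define the recurrence as above — each technique applied exactly once
  per stage to the previous stage's dataset — because it is the only
  reading that reproduces the `(2^m - 1) * n` total. A record discarded
  mid-pipeline forfeits its would-be descendants; those are counted as
  discarded so the accounting law still balances.

`combineDatasets()` unions runs over the same originals, counting shared
originals once and deduplicating generated records with identical
provenance — so an elastic-only run of 40 and a ten-technique run of 220
over the same 20 originals combine to 240.

Reproducibility: every (record, technique) application derives a child seed
by hashing the master seed, the source id, the provenance chain and the
technique tag. Runs are byte-identical given the same configuration and
master seed, independent of traversal order, including stochastic
techniques deep inside a power pipeline.

## Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| `min_keep_fraction` | fraction of original box area / instance pixel count | 0.3 | below a third of the object, the crop is more noise than signal; applied uniformly per run |
| rotation `angle` | degrees (scalar or range) | 90 | right angles are always label-safe; ranges sample once per application |
| translation `dx`, `dy` | pixels | 10, 10 | noticeable shift at typical patch sizes |
| crop `fraction` | linear fraction per side | 0.8 | keeps most context; `position = "random"` for stochastic crops |
| elastic `alpha`, `sigma` | px displacement scale, px smoothing | 8, 3 | mild tissue-like warp at 64-px scale |
| `gamma` | — | 1.5 | visible, invertible intensity curve |
| noise `sigma` | intensity levels | 10 | ~4 % of range |

The keep policy compares **areas** for boxes and **pixel counts** for
instances: areas are what detection losses see, while instance masks can be
arbitrarily non-convex, where pixel count is the honest measure. Both
choices, and the 0.3 default, are this package's decisions — the underlying
strategy only requires *some* minimum-percentage rule. Likewise detection
drops boxes individually and discards the image only when no box survives;
discarding a whole multi-object image because one box clipped out would
waste data.

Decisions on under-specified technique names: "lightning" is a global
linear gain/bias intensity adjustment; "brightness noising" is an additive
offset, "contrast noising" a scaling about mid-gray, "colour noising"
per-channel additive uniform noise; histogram equalisation is included
(applied to the luminance channel of colour images, with channels rescaled
proportionally) because colour-transform pipelines routinely use it
alongside gamma correction.

## What the synthetic generator emulates — and what it does not

`genScene()` renders flat-shaded rectangles and disks on a black background
and derives all four annotation views (boxes, semantic mask, instance
masks, class label) from the same geometry, so ground truth is exact and
mutually consistent by construction. By default shapes keep a border margin
of a quarter of the canvas side, so the default techniques displace nothing
off-canvas and the zero-discard count laws are testable exactly; truncation
cases for discard tests are built explicitly. `genDataset()` writes such
scenes in any supported input format.

What this does **not** emulate: real textures, anisotropic noise,
overlapping and touching objects, ambiguous boundaries. Passing tests
demonstrate that annotations are propagated *exactly as the geometry
dictates* — they say nothing about whether a given augmentation recipe
improves a particular model, which depends on real data and training.

## Numerical choices and degenerate inputs

* 8-bit intensities throughout; photometric outputs are rounded then
  clamped to [0, 255].
* Bilinear sampling at exact integer coordinates reproduces input values,
  so identity-parameter transforms (rotation 0°, translation (0,0),
  rescale ×1, shear 0°, elastic α = 0) are bitwise identities under
  nearest and within one intensity level under smooth interpolation.
* Out-of-canvas source coordinates yield 0 (black), for images and masks
  alike; an empty warped mask simply means "no annotation survives".
* Convolution-based filters (EBImage backends) see replicate-padded images
  so kernels larger than a tiny input remain defined.
* Degenerate requests fail loudly: zero-radius disks, boxes outside the
  canvas, position-invariant techniques asked for geometry, heterogeneous
  frame shapes in one stack.

## Problem sizes used in the checks

The test-suite and the acceptance script exercise the size accounting at
the case-study scales (1000 classification originals with 4+2 techniques;
100 detection originals with 3+3; 20 semantic originals with 1 and 10
techniques, the ten-technique list being three rotations, two translations,
two flips, one shear, gamma correction and histogram equalisation) on small
synthetic canvases, 16–24 px — the counts depend only on `n`, `m`, the mode
and the combination rule, never on canvas size. Exhaustive geometric
oracles run on canvases up to 12 × 12, where complete enumeration of boxes
and pixels is cheap.

## Known limitations

* Crop and rescale are the only shape-changing techniques; rotation does
  not expand the canvas (corners clip, as the keep policy expects).
* COCO polygons are handled by rasterising, warping and re-tracing;
  polygon vertices are not warped directly, and holes survive only via the
  RLE encoding.
* No HDF5 output, no in-memory training-framework generators, no video
  container decoding, and no GAN-based synthesis — the scope is classical,
  geometry-true augmentation with exact annotation bookkeeping.
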