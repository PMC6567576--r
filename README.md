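# maskaug — annotation-preserving image augmentation for bioimage datasets

Deep learning on bioimages is chronically data-limited, and annotating new
images needs experts. Data augmentation fixes the quantity problem for
*classification*, where any label-compatible transform leaves the label
alone — but for localization, detection, semantic segmentation and
instance segmentation the annotation encodes object **positions**, so a
flip or rotation invalidates it. Most augmentation tools therefore stop at
classification.

`maskaug` augments the **annotations together with the images**, for all
five problem kinds and for multi-dimensional data (z-stacks, videos as
frame collections), using standard annotation formats end to end.

## The core idea

Techniques are split into two categories:

* **position-invariant** (blurs, noises, gamma correction, histogram
  equalisation, HSV jitter, ...): pixel values change, positions do not —
  the original annotation is reused verbatim;
* **position-variant** (flip, rotation, translation, crop, rescale, shear,
  elastic deformation): the annotation is rendered as binary raster
  mask(s), every mask is warped with the *exact same* geometric plan as
  the image, and the annotation is re-derived from the warped masks.

For a bounding box `b` on an image `I`: draw `b` as a white rectangle on a
black canvas, apply the transform `T` to both, and take the tight box of
the white region of `T(mask)` to annotate `T(I)`. A transformed object
retaining less than a configurable fraction of its area (default 0.3) —
or leaving the canvas — causes the box/instance to be dropped. Label
rasters are always warped with nearest-neighbour interpolation, so no
interpolated label codes can appear.

With `n` originals and `m` techniques, **linear** mode generates at most
`n·m` images (each technique once per original) and **power** mode chains
stages, `D_i = D_(i-1) ∪ t_i(D_(i-1))`, generating `(2^m − 1)·n`. A label
map `f` can rewrite classes alongside a transform (left-facing ↔
right-facing under a flip).

Formats: folder-per-class (classification), PASCAL VOC XML
(localization/detection), YOLO text (detection), paired label-mask images
(semantic), COCO JSON (instance), paired multi-page TIFF stacks (stack
segmentation), folder-per-class frame-dirs/TIFFs (stack classification).

## Worked example

```r
library(maskaug)

# a small synthetic detection dataset in YOLO format, exactly annotated
cfg  <- genDataset("detection", 3, format = "yolo", seed = 7,
                   outDir = "demo-in", canvas = c(48L, 48L))
recs <- readDataset(cfg)
recs[[1]]
#> DatasetRecord "img0001" (detection), original
recordAnnotation(recs[[1]])[[1]]
#> BoundingBox [23, 32) x [26, 35) label="nucleus" area=81

# propagate a horizontal flip through the mask pipeline: on a 48-px canvas
# [23, 32) mirrors to [48-32, 48-23) = [16, 25); rows are untouched
res <- augmentLocalization(recordPayload(recs[[1]]),
                           recordAnnotation(recs[[1]])[[1]],
                           makeTechnique("flip", list(mode = "horizontal")))
res$box
#> BoundingBox [16, 25) x [26, 35) label="nucleus" area=81

# a full linear run: 3 originals x 3 techniques, nothing discarded
ec  <- engineConfig(cfg, list(makeTechnique("flip"),
                              makeTechnique("rotation", list(angle = c(-30, 30))),
                              makeTechnique("average-blur")),
                    generationMode = "linear", masterSeed = 42)
out <- runLinear(recs, ec)
out$report
#> RunReport: 3 originals, 9 generated, 0 discarded
#>     technique generated discarded
#>          flip         3         0
#>      rotation         3         0
#>  average-blur         3         0
```

The area is preserved under the flip, the box lands exactly where the
mirrored object sits, and the report obeys the linear count law
`generated + discarded = n·m = 9`.

The same run is available from the shell: write the six parameters
(dataset path, problem, input/output modes, generation mode, techniques)
into a JSON file and run

```sh
Rscript inst/scripts/maskaug augment --config config.json
Rscript inst/scripts/maskaug techniques     # list the registry
Rscript inst/scripts/maskaug validate --config config.json
```

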