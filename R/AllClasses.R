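## Central S4 classes. Raster payloads (images, label masks, binary masks) are
## plain integer arrays in (row, col) order with 8-bit intensities; the classes
## below carry the structured annotation and pipeline state around them.

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Technique: a configured augmentation operation
#'
#' A `Technique` pairs a registry name with resolved parameters, the
#' position-invariant / position-variant category recorded in the registry,
#' and an optional seed that fully determines any stochastic behaviour
#' (noise fields, sampled angles, erasing rectangles). Applying the same
#' seeded technique to the same image twice yields bitwise-identical output.
#'
#' @slot name registry identifier, e.g. `"flip"` or `"gaussian-blur"`.
#' @slot category `"position_invariant"` or `"position_variant"`.
#' @slot params named list of resolved parameter values.
#' @slot seed integer seed, or `NULL` for deterministic techniques.
#'
#' @seealso [makeTechnique()], [listTechniques()]
#' @export
setClass("Technique",
  representation(name = "character", category = "character",
                 params = "list", seed = "integerOrNULL"),
  validity = function(object) {
    if (length(object@name) != 1L) return("name must be a single string")
    if (!object@category %in% c("position_invariant", "position_variant"))
      return("category must be position_invariant or position_variant")
    TRUE
  })

#' GeometricPlan: a concrete, shared pixel-displacement plan
#'
#' All randomness of a position-variant technique (sampled angle, elastic
#' displacement field, crop window) is materialised once into an inverse
#' coordinate map: for every output pixel the continuous source coordinate it
#' draws from. Applying one plan to an image and to its annotation rasters
#' moves corresponding pixels identically, which is what lets annotations
#' follow images.
#'
#' @slot kind geometry kind (`"flip"`, `"rotation"`, `"translation"`,
#'   `"crop"`, `"rescale"`, `"shear"`, `"elastic"`).
#' @slot inShape,outShape integer `(H, W)` of the input and output canvas.
#' @slot srcRow,srcCol numeric `outH x outW` matrices of 0-based source
#'   coordinates for each output pixel.
#' @export
setClass("GeometricPlan",
  representation(kind = "character", inShape = "integer", outShape = "integer",
                 srcRow = "matrix", srcCol = "matrix"),
  validity = function(object) {
    if (!all(dim(object@srcRow) == object@outShape) ||
        !all(dim(object@srcCol) == object@outShape))
      return("srcRow/srcCol must have outShape dimensions")
    TRUE
  })

#' BoundingBox: a labeled axis-aligned rectangle
#'
#' Coordinates are 0-based and half-open: the box covers columns
#' `[xmin, xmax)` and rows `[ymin, ymax)`; the origin is the top-left corner.
#' Format codecs convert to and from the dialects of VOC (1-based inclusive)
#' and YOLO (normalised center/size).
#'
#' @slot xmin,ymin,xmax,ymax numeric pixel coordinates, `xmin < xmax`,
#'   `ymin < ymax`.
#' @slot label category string.
#' @export
setClass("BoundingBox",
  representation(xmin = "numeric", ymin = "numeric",
                 xmax = "numeric", ymax = "numeric", label = "character"),
  validity = function(object) {
    if (object@xmin < 0 || object@ymin < 0) return("box coordinates must be >= 0")
    if (object@xmax <= object@xmin) return("xmax must exceed xmin")
    if (object@ymax <= object@ymin) return("ymax must exceed ymin")
    TRUE
  })

#' SemanticMask: a per-pixel category labeling
#'
#' An integer label image of the same height and width as its image, where
#' entry `(i, j)` is the category code of pixel `(i, j)`, plus a palette
#' mapping codes to category names. Code 0 is background by convention.
#'
#' @slot labels integer `H x W` matrix of category codes.
#' @slot palette named character vector; names are codes as strings.
#' @export
setClass("SemanticMask",
  representation(labels = "matrix", palette = "character"),
  validity = function(object) {
    codes <- setdiff(unique(as.vector(object@labels)), 0L)
    missing <- setdiff(as.character(codes), names(object@palette))
    if (length(missing))
      return(paste("codes missing from palette:", paste(missing, collapse = ", ")))
    TRUE
  })

#' InstanceSet: per-object binary masks with class labels
#'
#' COCO-style instance annotation: each object carries its own binary mask on
#' the image canvas together with a category label, so objects of the same
#' class are distinguished from one another.
#'
#' @slot labels character vector, one category per instance.
#' @slot masks list of `H x W` integer 0/1 matrices, one per instance.
#' @export
setClass("InstanceSet",
  representation(labels = "character", masks = "list"),
  validity = function(object) {
    if (length(object@labels) != length(object@masks))
      return("labels and masks must have equal length")
    if (length(object@masks)) {
      shp <- dim(object@masks[[1]])
      for (m in object@masks) {
        if (!identical(dim(m), shp)) return("all masks must share one shape")
        if (sum(m) < 1) return("each mask needs at least one foreground pixel")
      }
    }
    TRUE
  })

#' LabelMap: the class-rewriting function f
#'
#' Some geometric techniques change the class of an object (people looking
#' left become people looking right under a flip). A `LabelMap` is the
#' category-to-category function applied to labels alongside a transform;
#' unmapped labels pass through unchanged, so the empty map is the identity.
#'
#' @slot map named character vector, `old -> new`.
#' @export
setClass("LabelMap", representation(map = "character"))

#' KeepPolicy: minimum surviving fraction before discarding
#'
#' After a geometric transform, a box or instance whose area (boxes) or
#' foreground pixel count (instances) falls below `minKeepFraction` of its
#' original value is dropped; an example with no surviving annotation is
#' discarded.
#'
#' @slot minKeepFraction numeric in (0, 1].
#' @export
setClass("KeepPolicy",
  representation(minKeepFraction = "numeric"),
  validity = function(object) {
    f <- object@minKeepFraction
    if (length(f) != 1 || is.na(f) || f <= 0 || f > 1)
      return("minKeepFraction must lie in (0, 1]")
    TRUE
  })

#' DatasetRecord: one annotated example
#'
#' The unit flowing through the engine: a stable identifier of the original
#' example, the raster payload (an image, or an ordered list of frames for
#' stack problems), the per-problem annotation, and the provenance — the
#' ordered list of technique names applied so far (empty for originals).
#'
#' @slot sourceId stable identifier of the original example.
#' @slot problem one of the supported problem kinds.
#' @slot payload an image array, or a list of frame arrays for stacks.
#' @slot annotation problem-specific annotation object.
#' @slot provenance character vector of technique names applied.
#' @export
setClass("DatasetRecord",
  representation(sourceId = "character", problem = "character",
                 payload = "ANY", annotation = "ANY", provenance = "character"),
  validity = function(object) {
    if (!object@problem %in% PROBLEMS)
      return(paste("unknown problem:", object@problem))
    TRUE
  })

#' IOConfig: dataset location and format selection
#'
#' @slot problem problem kind (see [supportedFormats()]).
#' @slot inputMode,outputMode format identifiers.
#' @slot inputPath,outputPath directories.
#' @slot options named list of dialect options (mask suffix, COCO encoding,
#'   strict mode, ...).
#' @export
setClass("IOConfig",
  representation(problem = "character", inputMode = "character",
                 outputMode = "character", inputPath = "character",
                 outputPath = "character", options = "list"))

#' EngineConfig: the six run parameters
#'
#' Gathers the dataset (via its [IOConfig-class]), the problem kind, the
#' input and output annotation modes, the generation mode and the ordered
#' technique list, plus the keep policy, the label map and the master seed.
#'
#' @slot io an [IOConfig-class].
#' @slot techniques ordered list of [Technique-class] objects (length m).
#' @slot generationMode `"linear"` or `"power"`.
#' @slot includeOriginals keep originals in the output dataset.
#' @slot keepPolicy a [KeepPolicy-class].
#' @slot labelMap a [LabelMap-class].
#' @slot masterSeed integer master seed.
#' @export
setClass("EngineConfig",
  representation(io = "IOConfig", techniques = "list",
                 generationMode = "character", includeOriginals = "logical",
                 keepPolicy = "KeepPolicy", labelMap = "LabelMap",
                 masterSeed = "integer"),
  validity = function(object) {
    if (length(object@techniques) < 1) return("at least one technique required")
    if (!object@generationMode %in% c("linear", "power"))
      return("generationMode must be linear or power")
    TRUE
  })

#' RunReport: production accounting for an augmentation run
#'
#' `nGenerated + nDiscarded` always equals the generation mode's theoretical
#' production count: `n * m` for linear mode and `(2^m - 1) * n` for power
#' mode (a record discarded mid-pipeline forfeits its would-be descendants,
#' which are counted as discarded).
#'
#' @slot nOriginals,nGenerated,nDiscarded integer counts.
#' @slot perTechnique data.frame with columns `technique`, `generated`,
#'   `discarded`.
#' @export
setClass("RunReport",
  representation(nOriginals = "integer", nGenerated = "integer",
                 nDiscarded = "integer", perTechnique = "data.frame"))

PROBLEMS <- c("classification", "localization", "detection", "semantic",
              "instance", "stack_classification", "stack_detection",
              "stack_segmentation")
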