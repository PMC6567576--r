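## Annotation propagation: lifting an image technique to annotated examples.
## Bounding boxes are propagated by rendering each box as a binary mask (a
## black image with a white rectangle), warping the mask with the exact plan
## applied to the image, and recomputing the tight box of the warped white
## region. Semantic masks and instance masks are warped directly with
## nearest-neighbour interpolation. Position-invariant techniques return the
## input annotation verbatim.

#' Render a bounding box as a binary mask
#'
#' @param box a [BoundingBox-class] (0-based, half-open).
#' @param shape integer `(H, W)` canvas.
#' @return An `H x W` integer 0/1 matrix, 1 exactly on the box rectangle.
#' @examples
#' sum(boxToMask(boundingBox(0, 0, 2, 2), c(4L, 4L)))  # 4
#' @export
boxToMask <- function(box, shape) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (box@xmax > W || box@ymax > H)
    stop("box extends outside the canvas", call. = FALSE)
  m <- matrix(0L, H, W)
  rows <- (floor(box@ymin) + 1L):ceiling(box@ymax)
  cols <- (floor(box@xmin) + 1L):ceiling(box@xmax)
  m[rows, cols] <- 1L
  m
}

#' Recover the tight bounding box of a binary mask
#'
#' Returns the minimal axis-aligned box containing all foreground pixels, or
#' `NULL` when the mask has no foreground (the object was pushed outside the
#' canvas).
#'
#' @param mask `H x W` 0/1 matrix.
#' @param label category string for the returned box.
#' @return A [BoundingBox-class] or `NULL`.
#' @export
maskToBox <- function(mask, label = "object") {
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) return(NULL)
  boundingBox(xmin = min(fg[, 2]) - 1, ymin = min(fg[, 1]) - 1,
              xmax = max(fg[, 2]), ymax = max(fg[, 1]), label = label)
}

# Shared plan for an annotated example; NULL for invariant techniques.
planFor <- function(technique, shape)
  if (isPositionVariant(technique)) resolveGeometry(technique, shape) else NULL

# Warp one box through the mask pipeline; NULL when it disappears or fails
# the keep policy.
propagateBox <- function(box, plan, shape, policy) {
  mask <- boxToMask(box, shape)
  warped <- applyGeometric(plan, mask, "nearest")
  newBox <- maskToBox(warped, box@label)
  if (is.null(newBox)) return(NULL)
  if (boxArea(newBox) < policy@minKeepFraction * boxArea(box)) return(NULL)
  newBox
}

#' Augment a localization example (one image, one box)
#'
#' Position-invariant techniques return the transformed image with the
#' original box. Position-variant techniques render the box as a mask, apply
#' one shared geometric plan to image (smooth) and mask (nearest), and
#' recompute the box from the warped mask; if the new box area falls below
#' `minKeepFraction` of the original (or the object leaves the canvas
#' entirely) the example is discarded and `NULL` is returned.
#'
#' @param image 8-bit image array.
#' @param box a [BoundingBox-class].
#' @param technique a [Technique-class].
#' @param policy a [KeepPolicy-class].
#' @param f a [LabelMap-class] applied to the box label.
#' @return `list(image=, box=)` or `NULL` if discarded.
#' @export
augmentLocalization <- function(image, box, technique,
                                policy = keepPolicy(), f = labelMap()) {
  if (!isPositionVariant(technique)) {
    newBox <- box; newBox@label <- applyLabelMap(f, box@label)
    return(list(image = applyPhotometric(technique, image), box = newBox))
  }
  plan <- resolveGeometry(technique, imShape(image))
  newBox <- propagateBox(box, plan, imShape(image), policy)
  if (is.null(newBox)) return(NULL)
  newBox@label <- applyLabelMap(f, newBox@label)
  list(image = applyGeometric(plan, image, "smooth"), box = newBox)
}

#' Augment a detection example (one image, many boxes)
#'
#' As [augmentLocalization()], but a mask is generated for every box and all
#' masks share the single geometric plan applied to the image. Boxes failing
#' the keep policy are dropped individually; the example is discarded only
#' when no box survives.
#'
#' @param image 8-bit image array.
#' @param boxes list of [BoundingBox-class] objects.
#' @inheritParams augmentLocalization
#' @return `list(image=, boxes=)` or `NULL` if discarded.
#' @export
augmentDetection <- function(image, boxes, technique,
                             policy = keepPolicy(), f = labelMap()) {
  if (length(boxes) == 0) return(NULL)
  if (!isPositionVariant(technique)) {
    boxes <- lapply(boxes, function(b) { b@label <- applyLabelMap(f, b@label); b })
    return(list(image = applyPhotometric(technique, image), boxes = boxes))
  }
  plan <- resolveGeometry(technique, imShape(image))
  kept <- list()
  for (b in boxes) {
    nb <- propagateBox(b, plan, imShape(image), policy)
    if (!is.null(nb)) {
      nb@label <- applyLabelMap(f, nb@label)
      kept[[length(kept) + 1L]] <- nb
    }
  }
  if (length(kept) == 0) return(NULL)
  list(image = applyGeometric(plan, image, "smooth"), boxes = kept)
}

#' Augment a semantic-segmentation example
#'
#' Applies the same transformation to the image and to the label image: one
#' shared plan, smooth interpolation on the image and nearest on the label
#' raster, so the output label codes are a subset of the input codes plus
#' background 0. Invariant techniques return the mask untouched.
#'
#' @param image 8-bit image array.
#' @param mask a [SemanticMask-class] of the same `H x W`.
#' @param technique a [Technique-class].
#' @param f a [LabelMap-class]; for semantic masks it remaps palette
#'   category names.
#' @return `list(image=, mask=)`.
#' @export
augmentSemantic <- function(image, mask, technique, f = labelMap()) {
  if (!all(imShape(image) == dim(mask@labels)))
    stop("image and mask shapes differ", call. = FALSE)
  palette <- mask@palette
  if (length(f@map)) {
    palette[] <- applyLabelMap(f, palette)
  }
  if (!isPositionVariant(technique))
    return(list(image = applyPhotometric(technique, image),
                mask = new("SemanticMask", labels = mask@labels, palette = palette)))
  plan <- resolveGeometry(technique, imShape(image))
  warped <- applyGeometric(plan, mask@labels, "nearest")
  storage.mode(warped) <- "integer"
  list(image = applyGeometric(plan, image, "smooth"),
       mask = new("SemanticMask", labels = warped, palette = palette))
}

#' Augment an instance-segmentation example
#'
#' A mask is generated for each instance; every instance mask is warped with
#' the single shared plan (nearest interpolation). Instances whose foreground
#' pixel count falls below `minKeepFraction` of the original count are
#' dropped; if all instances are dropped the example is discarded.
#'
#' @param image 8-bit image array.
#' @param instances an [InstanceSet-class].
#' @inheritParams augmentLocalization
#' @return `list(image=, instances=)` or `NULL` if discarded.
#' @export
augmentInstance <- function(image, instances, technique,
                            policy = keepPolicy(), f = labelMap()) {
  if (!isPositionVariant(technique)) {
    return(list(image = applyPhotometric(technique, image),
                instances = new("InstanceSet",
                                labels = applyLabelMap(f, instances@labels),
                                masks = instances@masks)))
  }
  plan <- resolveGeometry(technique, imShape(image))
  keptMasks <- list(); keptLabels <- character()
  for (i in seq_along(instances@masks)) {
    m <- instances@masks[[i]]
    warped <- applyGeometric(plan, m, "nearest")
    storage.mode(warped) <- "integer"
    if (sum(warped) >= policy@minKeepFraction * sum(m)) {
      keptMasks[[length(keptMasks) + 1L]] <- warped
      keptLabels <- c(keptLabels, applyLabelMap(f, instances@labels[i]))
    }
  }
  if (length(keptMasks) == 0) return(NULL)
  list(image = applyGeometric(plan, image, "smooth"),
       instances = new("InstanceSet", labels = keptLabels, masks = keptMasks))
}

#' Augment a classification example
#'
#' Returns the transformed image and `f(label)` — the label map covers the
#' cases where a geometric technique changes the class (e.g. objects facing
#' left become objects facing right under a flip).
#'
#' @param image 8-bit image array.
#' @param label category string.
#' @param technique a [Technique-class].
#' @param f a [LabelMap-class].
#' @return `list(image=, label=)`.
#' @export
augmentClassification <- function(image, label, technique, f = labelMap()) {
  list(image = applyTechnique(technique, image), label = applyLabelMap(f, label))
}

#' Augment a multi-dimensional example (z-stack or video)
#'
#' Decomposes the stack into its ordered 2D frames, applies the per-problem
#' procedure to every frame, and recombines. For position-variant techniques
#' ONE geometric plan is resolved per stack — a single sampled rotation
#' angle, one elastic displacement field — and applied to every frame and
#' every frame's annotation, preserving geometric consistency across frames.
#'
#' @param frames ordered list of same-shaped 8-bit frame arrays.
#' @param annotation problem-dependent: a single category string
#'   (`stack_classification`), a list of per-frame box lists
#'   (`stack_detection`), or a list of per-frame [SemanticMask-class]
#'   objects (`stack_segmentation`).
#' @param technique a [Technique-class].
#' @param problem one of `"stack_classification"`, `"stack_detection"`,
#'   `"stack_segmentation"`.
#' @param policy a [KeepPolicy-class] (detection only).
#' @param f a [LabelMap-class].
#' @return `list(frames=, annotation=)` or `NULL` if discarded
#'   (stack detection with no surviving box in any frame).
#' @export
augmentStack <- function(frames, annotation, technique,
                         problem = c("stack_classification", "stack_detection",
                                     "stack_segmentation"),
                         policy = keepPolicy(), f = labelMap()) {
  problem <- match.arg(problem)
  if (length(frames) == 0) stop("empty stack", call. = FALSE)
  shape <- imShape(frames[[1]])
  for (fr in frames)
    if (!all(imShape(fr) == shape))
      stop("all frames in a stack must share one shape", call. = FALSE)

  variant <- isPositionVariant(technique)
  plan <- if (variant) resolveGeometry(technique, shape) else NULL
  warpImage <- function(img) {
    if (variant) applyGeometric(plan, img, "smooth")
    else applyPhotometric(technique, img)
  }
  newFrames <- lapply(frames, warpImage)

  if (problem == "stack_classification") {
    return(list(frames = newFrames, annotation = applyLabelMap(f, annotation)))
  }
  if (problem == "stack_segmentation") {
    newMasks <- lapply(annotation, function(sm) {
      palette <- sm@palette
      if (length(f@map)) palette[] <- applyLabelMap(f, palette)
      if (!variant)
        return(new("SemanticMask", labels = sm@labels, palette = palette))
      warped <- applyGeometric(plan, sm@labels, "nearest")
      storage.mode(warped) <- "integer"
      new("SemanticMask", labels = warped, palette = palette)
    })
    return(list(frames = newFrames, annotation = newMasks))
  }
  # stack detection: propagate each frame's boxes through the shared plan
  newAnn <- lapply(annotation, function(boxes) {
    if (!variant)
      return(lapply(boxes, function(b) { b@label <- applyLabelMap(f, b@label); b }))
    kept <- list()
    for (b in boxes) {
      nb <- propagateBox(b, plan, shape, policy)
      if (!is.null(nb)) {
        nb@label <- applyLabelMap(f, nb@label)
        kept[[length(kept) + 1L]] <- nb
      }
    }
    kept
  })
  if (all(vapply(newAnn, length, 0L) == 0L)) return(NULL)
  list(frames = newFrames, annotation = newAnn)
}
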