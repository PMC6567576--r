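## Synthetic datasets with exactly known annotations. Scenes are flat-shaded
## rectangles and disks on a black background; the bounding boxes, semantic
## mask and instance masks are all derived from the same rendered geometry,
## so the four annotation views are mutually consistent by construction.
## By default shapes keep a safety margin from the canvas border so that
## moderate geometric techniques displace no object off-canvas and the
## zero-discard count laws are exactly testable; truncation cases for
## discard tests are produced by placing shapes with `margin = 0` or via
## an explicit ShapeSpec near the border.

#' Describe a shape for scene generation
#'
#' @param kind `"rectangle"` or `"disk"`.
#' @param center integer `(row, col)` center (0-based pixel coordinates).
#' @param size rectangle `(height, width)` in pixels, or disk radius.
#' @param label category string.
#' @param intensity fill intensity 1-255.
#' @return A shape-spec list.
#' @export
shapeSpec <- function(kind = c("rectangle", "disk"), center, size,
                      label = "object", intensity = 200) {
  kind <- match.arg(kind)
  if (kind == "disk" && (length(size) != 1 || size < 1))
    stop("disk radius must be a positive number", call. = FALSE)
  if (kind == "rectangle" && (length(size) != 2 || any(size < 1)))
    stop("rectangle size must be a positive (height, width)", call. = FALSE)
  if (intensity < 1 || intensity > 255)
    stop("intensity must lie in [1, 255]", call. = FALSE)
  list(kind = kind, center = as.numeric(center), size = as.numeric(size),
       label = label, intensity = as.integer(intensity))
}

shapeMembership <- function(spec, H, W) {
  r <- matrix(0:(H - 1), H, W); c <- matrix(0:(W - 1), H, W, byrow = TRUE)
  if (spec$kind == "rectangle") {
    # half-open span so a size-s rectangle covers exactly s pixels
    h2 <- spec$size[1] / 2; w2 <- spec$size[2] / 2
    (r - spec$center[1]) >= -h2 & (r - spec$center[1]) < h2 &
      (c - spec$center[2]) >= -w2 & (c - spec$center[2]) < w2
  } else {
    (r - spec$center[1])^2 + (c - spec$center[2])^2 <= spec$size^2
  }
}

#' Generate one synthetic annotated scene
#'
#' Renders the shapes on a black canvas and derives all four annotation
#' views from the same geometry: exact bounding boxes, a semantic mask
#' (codes assigned 1, 2, ... over the sorted label set), and per-shape
#' instance masks.
#'
#' @param shape integer `(H, W)` canvas.
#' @param shapes list of [shapeSpec()] entries.
#' @param allowTruncation allow shapes to extend past the canvas border
#'   (they are clipped); otherwise out-of-canvas shapes are an error.
#' @return `list(image =, boxes =, mask =, instances =)`.
#' @examples
#' sc <- genScene(c(32L, 32L), list(
#'   shapeSpec("rectangle", center = c(16, 16), size = c(10, 10))))
#' boxCoords(sc$boxes[[1]])
#' @export
genScene <- function(shape, shapes, allowTruncation = FALSE) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  img <- matrix(0L, H, W)
  masks <- list(); labels <- character(); boxes <- list()
  occupied <- matrix(FALSE, H, W)
  for (spec in shapes) {
    member <- shapeMembership(spec, H, W)
    if (!any(member))
      stop("shape lies entirely outside the canvas", call. = FALSE)
    if (!allowTruncation) {
      extent <- switch(spec$kind,
        rectangle = c(spec$center[1] - spec$size[1] / 2 >= 0,
                      spec$center[1] + spec$size[1] / 2 <= H,
                      spec$center[2] - spec$size[2] / 2 >= 0,
                      spec$center[2] + spec$size[2] / 2 <= W),
        disk = c(spec$center[1] - spec$size >= 0, spec$center[1] + spec$size <= H - 1,
                 spec$center[2] - spec$size >= 0, spec$center[2] + spec$size <= W - 1))
      if (!all(extent))
        stop("shape extends outside the canvas; set allowTruncation",
             call. = FALSE)
    }
    conflict <- occupied & member
    if (any(conflict))
      stop("overlapping shapes with conflicting labels; place shapes apart",
           call. = FALSE)
    occupied <- occupied | member
    img[member] <- spec$intensity
    m <- matrix(0L, H, W); m[member] <- 1L
    masks[[length(masks) + 1L]] <- m
    labels <- c(labels, spec$label)
    boxes[[length(boxes) + 1L]] <- maskToBox(m, spec$label)
  }
  codes <- stats::setNames(seq_along(sort(unique(labels))), sort(unique(labels)))
  semLabels <- matrix(0L, H, W)
  for (i in seq_along(masks))
    semLabels[masks[[i]] == 1L] <- codes[[labels[i]]]
  palette <- stats::setNames(names(codes), as.character(codes))
  list(image = img, boxes = boxes,
       mask = new("SemanticMask", labels = semLabels, palette = palette),
       instances = instanceSet(labels, masks))
}

#' Sample a random scene
#'
#' Shapes are placed disjointly with a safety `margin` from the border
#' (default a quarter of the smaller canvas side, large enough that the
#' default geometric techniques keep every object on canvas).
#'
#' @param shape integer `(H, W)` canvas.
#' @param nShapes number of shapes.
#' @param labels candidate category labels.
#' @param margin minimum distance from the canvas border in pixels.
#' @return As [genScene()].
#' @export
randomScene <- function(shape, nShapes = 2, labels = c("cell", "nucleus"),
                        margin = NULL) {
  H <- shape[1]; W <- shape[2]
  if (is.null(margin)) margin <- ceiling(0.25 * min(H, W))
  placed <- list()
  occupiedBoxes <- NULL
  for (i in seq_len(nShapes)) {
    for (try in 1:50) {
      kind <- sample(c("rectangle", "disk"), 1)
      maxSz <- max(4, floor(min(H, W) / 5))
      size <- if (kind == "disk") sample(2:max(2, floor(maxSz / 2)), 1)
              else c(sample(4:maxSz, 1), sample(4:maxSz, 1))
      half <- if (kind == "disk") c(size, size) else size / 2
      cy <- sample(seq(margin + half[1], H - 1 - margin - half[1]), 1)
      cx <- sample(seq(margin + half[2], W - 1 - margin - half[2]), 1)
      ext <- c(cy - half[1], cy + half[1], cx - half[2], cx + half[2])
      clash <- FALSE
      if (!is.null(occupiedBoxes))
        for (k in seq_len(nrow(occupiedBoxes))) {
          o <- occupiedBoxes[k, ]
          if (ext[1] <= o[2] + 1 && ext[2] >= o[1] - 1 &&
              ext[3] <= o[4] + 1 && ext[4] >= o[3] - 1) { clash <- TRUE; break }
        }
      if (!clash) {
        occupiedBoxes <- rbind(occupiedBoxes, ext)
        placed[[length(placed) + 1L]] <- shapeSpec(
          kind, center = c(cy, cx), size = size,
          label = sample(labels, 1), intensity = sample(120:255, 1))
        break
      }
    }
  }
  genScene(shape, placed)
}

#' Write a synthetic dataset to disk
#'
#' Generates `nImages` annotated examples (or stacks) and writes them in the
#' requested input format, returning the [IOConfig-class] that reads them
#' back. Generation is seed-deterministic.
#'
#' @param problem problem kind.
#' @param nImages number of examples (stacks for stack problems).
#' @param format format identifier; defaults to the problem's first
#'   supported format (see [supportedFormats()]).
#' @param seed integer seed.
#' @param outDir output directory.
#' @param canvas integer `(H, W)` canvas (default 64x64).
#' @param nFrames frames per stack for stack problems (default 5).
#' @param classes class labels for classification problems.
#' @return An [IOConfig-class] pointing at the written dataset.
#' @export
genDataset <- function(problem, nImages, format = NULL, seed = 1,
                       outDir = tempfile("maskaug-fixture-"),
                       canvas = c(64L, 64L), nFrames = 5L,
                       classes = c("classA", "classB")) {
  if (is.null(format)) format <- FORMAT_MATRIX[[problem]][1]
  checkFormatPair(problem, format)
  records <- withSeed(seed, genRecords(problem, nImages, canvas, nFrames, classes))
  cfg <- ioConfig(problem, inputMode = format, outputMode = format,
                  inputPath = outDir, outputPath = outDir)
  writeDataset(records, cfg)
  cfg
}

#' Generate synthetic records in memory
#'
#' Like [genDataset()] but returns the records directly without touching
#' disk; also covers `stack_detection`, which has no on-disk format.
#'
#' @inheritParams genDataset
#' @return List of [DatasetRecord-class] objects.
#' @export
genExamples <- function(problem, nImages, seed = 1, canvas = c(64L, 64L),
                        nFrames = 5L, classes = c("classA", "classB")) {
  withSeed(seed, genRecords(problem, nImages, canvas, nFrames, classes))
}

genRecords <- function(problem, nImages, canvas, nFrames, classes) {
  lapply(seq_len(nImages), function(i) {
    sid <- sprintf("img%04d", i)
    if (problem %in% c("classification", "stack_classification")) {
      cl <- classes[(i - 1L) %% length(classes) + 1L]
      sc <- randomScene(canvas, nShapes = 1 + (i %% 2))
      if (problem == "classification")
        return(datasetRecord(sid, problem, sc$image, cl))
      frames <- lapply(seq_len(nFrames), function(k)
        clamp8(sc$image * (0.8 + 0.04 * k)))
      return(datasetRecord(sid, problem, frames, cl))
    }
    if (problem == "stack_segmentation") {
      sc <- randomScene(canvas, nShapes = 2)
      frames <- lapply(seq_len(nFrames), function(k)
        clamp8(sc$image * (0.8 + 0.04 * k)))
      masks <- rep(list(sc$mask), nFrames)
      return(datasetRecord(sid, problem, frames, masks))
    }
    if (problem == "stack_detection") {
      sc <- randomScene(canvas, nShapes = 2)
      frames <- lapply(seq_len(nFrames), function(k)
        clamp8(sc$image * (0.8 + 0.04 * k)))
      return(datasetRecord(sid, problem, frames, rep(list(sc$boxes), nFrames)))
    }
    sc <- randomScene(canvas, nShapes = if (problem == "localization") 1 else 2)
    ann <- switch(problem,
      localization = sc$boxes[[1]],
      detection = sc$boxes,
      semantic = sc$mask,
      instance = sc$instances)
    datasetRecord(sid, problem, sc$image, ann)
  })
}
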