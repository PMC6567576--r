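## User-facing constructors, accessors and show() methods.

#' Create a bounding box
#'
#' @param xmin,ymin,xmax,ymax 0-based half-open pixel coordinates.
#' @param label category string.
#' @return A [BoundingBox-class].
#' @examples
#' b <- boundingBox(0, 0, 10, 5, "cell")
#' boxArea(b)  # 50
#' @export
boundingBox <- function(xmin, ymin, xmax, ymax, label = "object") {
  new("BoundingBox", xmin = as.numeric(xmin), ymin = as.numeric(ymin),
      xmax = as.numeric(xmax), ymax = as.numeric(ymax), label = label)
}

#' Box area in pixels
#' @param box a [BoundingBox-class].
#' @export
boxArea <- function(box) (box@xmax - box@xmin) * (box@ymax - box@ymin)

#' Box label accessor
#' @param box a [BoundingBox-class].
#' @export
boxLabel <- function(box) box@label

#' Box coordinates as a named numeric vector
#' @param box a [BoundingBox-class].
#' @export
boxCoords <- function(box)
  c(xmin = box@xmin, ymin = box@ymin, xmax = box@xmax, ymax = box@ymax)

#' Create a semantic mask
#'
#' @param labels integer `H x W` matrix of category codes (0 = background).
#' @param palette named character vector mapping codes (as strings) to
#'   category names; defaults to naming each code after itself.
#' @return A [SemanticMask-class].
#' @export
semanticMask <- function(labels, palette = NULL) {
  storage.mode(labels) <- "integer"
  if (is.null(palette)) {
    codes <- sort(setdiff(unique(as.vector(labels)), 0L))
    palette <- stats::setNames(as.character(codes), as.character(codes))
  }
  new("SemanticMask", labels = labels, palette = palette)
}

#' Semantic mask label matrix accessor
#' @param mask a [SemanticMask-class].
#' @export
maskLabels <- function(mask) mask@labels

#' Semantic mask palette accessor
#' @param mask a [SemanticMask-class].
#' @export
maskPalette <- function(mask) mask@palette

#' Create an instance set
#'
#' @param labels character vector of per-instance categories.
#' @param masks list of `H x W` 0/1 matrices, one per instance.
#' @return An [InstanceSet-class].
#' @export
instanceSet <- function(labels = character(), masks = list()) {
  masks <- lapply(masks, function(m) { storage.mode(m) <- "integer"; m })
  new("InstanceSet", labels = labels, masks = masks)
}

#' Number of instances
#' @param x an [InstanceSet-class].
#' @export
nInstances <- function(x) length(x@masks)

#' Instance masks accessor
#' @param x an [InstanceSet-class].
#' @export
instanceMasks <- function(x) x@masks

#' Instance labels accessor
#' @param x an [InstanceSet-class].
#' @export
instanceLabels <- function(x) x@labels

#' Create a label map
#'
#' @param map named character vector `old -> new`; empty for identity.
#' @return A [LabelMap-class].
#' @examples
#' f <- labelMap(c(left = "right", right = "left"))
#' applyLabelMap(f, "left")  # "right"
#' @export
labelMap <- function(map = character()) new("LabelMap", map = map)

#' Apply a label map to one or more labels
#'
#' Labels absent from the map pass through unchanged (identity default).
#' @param f a [LabelMap-class].
#' @param labels character vector.
#' @export
applyLabelMap <- function(f, labels) {
  hit <- labels %in% names(f@map)
  labels[hit] <- unname(f@map[labels[hit]])
  labels
}

#' Create a keep policy
#'
#' @param minKeepFraction minimum fraction of original box area (boxes) or
#'   foreground pixel count (instances) a transformed object must retain to
#'   be kept. Default 0.3.
#' @return A [KeepPolicy-class].
#' @export
keepPolicy <- function(minKeepFraction = 0.3)
  new("KeepPolicy", minKeepFraction = minKeepFraction)

#' Create a dataset record
#'
#' @param sourceId stable identifier of the original example.
#' @param problem problem kind.
#' @param payload image array, or list of frames for stack problems.
#' @param annotation problem-specific annotation.
#' @param provenance technique names applied so far (empty for originals).
#' @return A [DatasetRecord-class].
#' @export
datasetRecord <- function(sourceId, problem, payload, annotation,
                          provenance = character()) {
  new("DatasetRecord", sourceId = sourceId, problem = problem,
      payload = payload, annotation = annotation, provenance = provenance)
}

#' Record accessors
#' @param record a [DatasetRecord-class].
#' @export
recordId <- function(record) record@sourceId

#' @rdname recordId
#' @export
recordPayload <- function(record) record@payload

#' @rdname recordId
#' @export
recordAnnotation <- function(record) record@annotation

#' @rdname recordId
#' @export
recordProvenance <- function(record) record@provenance

#' @rdname recordId
#' @export
isOriginal <- function(record) length(record@provenance) == 0L

#' Create an IO configuration
#'
#' @param problem problem kind.
#' @param inputMode,outputMode format identifiers (see [supportedFormats()]).
#' @param inputPath,outputPath dataset directories.
#' @param options named list of dialect options. Recognised: `maskSuffix`
#'   (default `"_mask"`), `cocoEncoding` (`"rle"` or `"polygon"`),
#'   `strict` (fail on unreadable files, default `TRUE`), `classFile`
#'   (explicit YOLO class list), `imageExt` (default `"png"`).
#' @return An [IOConfig-class].
#' @export
ioConfig <- function(problem, inputMode, outputMode = inputMode,
                     inputPath = "", outputPath = "", options = list()) {
  checkFormatPair(problem, inputMode)
  checkFormatPair(problem, outputMode)
  defaults <- list(maskSuffix = "_mask", cocoEncoding = "rle", strict = TRUE,
                   classFile = NULL, imageExt = "png")
  for (nm in names(options)) defaults[[nm]] <- options[[nm]]
  new("IOConfig", problem = problem, inputMode = inputMode,
      outputMode = outputMode, inputPath = inputPath,
      outputPath = outputPath, options = defaults)
}

#' Create an engine configuration
#'
#' @param io an [IOConfig-class].
#' @param techniques list of [Technique-class] objects, in application order.
#' @param generationMode `"linear"` (each technique applied once to every
#'   original, at most `n * m` generated) or `"power"` (pipeline stages,
#'   `(2^m - 1) * n` generated).
#' @param includeOriginals keep the originals in the output (default TRUE).
#' @param keepPolicy a [KeepPolicy-class].
#' @param labelMap a [LabelMap-class].
#' @param masterSeed integer master seed for all stochastic techniques.
#' @return An [EngineConfig-class].
#' @export
engineConfig <- function(io, techniques, generationMode = "linear",
                         includeOriginals = TRUE, keepPolicy = NULL,
                         labelMap = NULL, masterSeed = 0L) {
  if (is.null(keepPolicy)) keepPolicy <- new("KeepPolicy", minKeepFraction = 0.3)
  if (is.null(labelMap)) labelMap <- new("LabelMap", map = character())
  new("EngineConfig", io = io, techniques = techniques,
      generationMode = generationMode, includeOriginals = includeOriginals,
      keepPolicy = keepPolicy, labelMap = labelMap,
      masterSeed = as.integer(masterSeed))
}

#' Report accessors
#' @param report a [RunReport-class].
#' @export
nGenerated <- function(report) report@nGenerated

#' @rdname nGenerated
#' @export
nDiscarded <- function(report) report@nDiscarded

#' @rdname nGenerated
#' @export
nOriginals <- function(report) report@nOriginals

setMethod("show", "Technique", function(object) {
  cat(sprintf("Technique \"%s\" (%s)\n", object@name,
              sub("position_", "position ", object@category)))
  if (length(object@params)) {
    p <- vapply(object@params, function(v) paste(format(v), collapse = ","), "")
    cat("  params:", paste(names(p), p, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(object@seed)) cat("  seed:", object@seed, "\n")
})

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox [%g, %g) x [%g, %g) label=\"%s\" area=%g\n",
              object@xmin, object@xmax, object@ymin, object@ymax,
              object@label, boxArea(object)))
})

setMethod("show", "SemanticMask", function(object) {
  cat(sprintf("SemanticMask %dx%d, %d categories\n",
              nrow(object@labels), ncol(object@labels),
              length(setdiff(unique(as.vector(object@labels)), 0L))))
})

setMethod("show", "InstanceSet", function(object) {
  cat(sprintf("InstanceSet with %d instance(s): %s\n", nInstances(object),
              paste(object@labels, collapse = ", ")))
})

setMethod("show", "DatasetRecord", function(object) {
  prov <- if (isOriginal(object)) "original"
          else paste(object@provenance, collapse = " > ")
  cat(sprintf("DatasetRecord \"%s\" (%s), %s\n", object@sourceId,
              object@problem, prov))
})

setMethod("show", "GeometricPlan", function(object) {
  cat(sprintf("GeometricPlan kind=%s %dx%d -> %dx%d\n", object@kind,
              object@inShape[1], object@inShape[2],
              object@outShape[1], object@outShape[2]))
})

setMethod("show", "RunReport", function(object) {
  cat(sprintf("RunReport: %d originals, %d generated, %d discarded\n",
              object@nOriginals, object@nGenerated, object@nDiscarded))
  if (nrow(object@perTechnique)) {
    print(object@perTechnique, row.names = FALSE)
  }
})
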