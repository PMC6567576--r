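## YOLO text dialect: one sibling .txt per image, one line per box of the
## form "<class_id> <cx> <cy> <w> <h>" with center and size normalised by the
## image width and height, fixed 6-decimal formatting. Class ids come from a
## classes.txt file (one label per line, 0-based ids); when absent, ids are
## assigned lexicographically over the labels present in the dataset.

#' Encode a box as a YOLO annotation line
#'
#' @param box a [BoundingBox-class].
#' @param shape integer `(H, W)` of the image.
#' @param classIds named integer vector mapping label to 0-based class id.
#' @return A single YOLO line string.
#' @examples
#' boxToYolo(boundingBox(0, 0, 64, 64), c(64L, 64L), c(object = 0L))
#' @export
boxToYolo <- function(box, shape, classIds) {
  H <- shape[1]; W <- shape[2]
  if (!box@label %in% names(classIds))
    stop("label \"", box@label, "\" missing from the class registry",
         call. = FALSE)
  sprintf("%d %.6f %.6f %.6f %.6f", classIds[[box@label]],
          (box@xmin + box@xmax) / 2 / W, (box@ymin + box@ymax) / 2 / H,
          (box@xmax - box@xmin) / W, (box@ymax - box@ymin) / H)
}

#' Decode a YOLO annotation line
#'
#' The inverse codec recovers the box to within half-pixel rounding; the
#' returned coordinates are rounded to whole pixels.
#'
#' @param line YOLO line string.
#' @param shape integer `(H, W)` of the image.
#' @param classLabels character vector of labels indexed by 0-based class id.
#' @return A [BoundingBox-class].
#' @export
yoloToBox <- function(line, shape, classLabels) {
  parts <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(parts) != 5)
    stop("malformed YOLO line (expected 5 fields): ", line, call. = FALSE)
  vals <- as.numeric(parts[2:5])
  if (anyNA(vals) || any(vals < 0) || any(vals > 1))
    stop("YOLO fields must be normalised to [0, 1]: ", line, call. = FALSE)
  id <- as.integer(parts[1])
  if (id < 0 || id >= length(classLabels))
    stop("YOLO class id ", id, " outside the class registry", call. = FALSE)
  H <- shape[1]; W <- shape[2]
  xmin <- round((vals[1] - vals[3] / 2) * W)
  xmax <- round((vals[1] + vals[3] / 2) * W)
  ymin <- round((vals[2] - vals[4] / 2) * H)
  ymax <- round((vals[2] + vals[4] / 2) * H)
  # guard against degenerate rounding of sub-pixel boxes
  if (xmax <= xmin) xmax <- xmin + 1
  if (ymax <= ymin) ymax <- ymin + 1
  boundingBox(max(0, xmin), max(0, ymin), min(W, xmax), min(H, ymax),
              label = classLabels[id + 1L])
}

readClassFile <- function(path) {
  labs <- readLines(path, warn = FALSE)
  labs[nzchar(trimws(labs))]
}

writeClassFile <- function(labels, path) {
  writeLines(labels, path)
  invisible(path)
}

# Stable class registry: explicit class file wins, otherwise lexicographic.
classRegistryFor <- function(records, classFile = NULL) {
  if (!is.null(classFile) && file.exists(classFile)) {
    labs <- readClassFile(classFile)
  } else {
    labs <- sort(unique(unlist(lapply(records, function(r)
      vapply(r@annotation, boxLabel, "")))))
  }
  stats::setNames(seq_along(labs) - 1L, labs)
}
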