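## COCO JSON dialect for instance segmentation. Instance masks are encoded
## either as uncompressed RLE (exact round-trip; column-major counts starting
## with the background run, as in the COCO API) or as traced outer-contour
## polygons. Areas and bounding boxes are recomputed from the masks; ids are
## dense and stable.

#' Encode a binary mask as uncompressed COCO RLE
#'
#' @param mask `H x W` 0/1 matrix.
#' @return List with `size = c(H, W)` and integer `counts` (column-major
#'   runs, first count is background).
#' @export
maskToRle <- function(mask) {
  v <- as.integer(as.vector(mask) != 0)  # column-major, COCO order
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1] == 1L) counts <- c(0L, counts)
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(counts))
}

#' Decode uncompressed COCO RLE to a binary mask
#'
#' @param rle list with `size` and `counts` as produced by [maskToRle()].
#' @return Integer `H x W` 0/1 matrix.
#' @export
rleToMask <- function(rle) {
  size <- as.integer(unlist(rle$size))
  counts <- as.integer(unlist(rle$counts))
  if (sum(counts) != prod(size))
    stop("RLE counts do not cover the mask size", call. = FALSE)
  vals <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  matrix(vals, size[1], size[2])
}

#' Trace the outer contours of a binary mask as COCO polygons
#'
#' Uses connected-component labelling and contour following; each component
#' yields one polygon ring of pixel-center `x, y` coordinates (0-based,
#' interleaved as in COCO `segmentation` arrays).
#'
#' @param mask `H x W` 0/1 matrix.
#' @return List of numeric vectors `c(x1, y1, x2, y2, ...)`.
#' @export
maskToPolygons <- function(mask) {
  lab <- EBImage::bwlabel(t(mask))  # EBImage orientation: dim1 = x
  if (max(lab) == 0) return(list())
  oc <- EBImage::ocontour(lab)
  lapply(oc, function(pts) as.numeric(t(pts)))  # (x, y) interleaved, 0-based
}

#' Rasterize COCO polygons to a binary mask
#'
#' Even-odd ray-casting over pixel centers, with the polygon boundary pixels
#' included in the foreground.
#'
#' @param polygons list of interleaved `x, y` coordinate vectors.
#' @param shape integer `(H, W)` canvas.
#' @return Integer `H x W` 0/1 matrix.
#' @export
polygonsToMask <- function(polygons, shape) {
  H <- shape[1]; W <- shape[2]
  out <- matrix(0L, H, W)
  for (poly in polygons) {
    xs <- poly[seq(1, length(poly), 2)]
    ys <- poly[seq(2, length(poly), 2)]
    n <- length(xs)
    if (n < 3) {
      ri <- clamp(round(ys), 0, H - 1) + 1
      ci <- clamp(round(xs), 0, W - 1) + 1
      out[cbind(ri, ci)] <- 1L
      next
    }
    px <- matrix(0:(W - 1), H, W, byrow = TRUE)
    py <- matrix(0:(H - 1), H, W)
    inside <- matrix(FALSE, H, W)
    j <- n
    for (i in seq_len(n)) {
      cond <- ((ys[i] > py) != (ys[j] > py)) &
        (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- xor(inside, cond)
      j <- i
    }
    out[inside] <- 1L
    # boundary pixels (vertices lie on pixel centers from the tracer)
    ri <- clamp(round(ys), 0, H - 1) + 1
    ci <- clamp(round(xs), 0, W - 1) + 1
    out[cbind(ri, ci)] <- 1L
  }
  out
}

# Serialize instance records to a COCO JSON structure.
cocoBuild <- function(records, encoding = "rle", imageExt = "png") {
  categories <- sort(unique(unlist(lapply(records, function(r)
    r@annotation@labels))))
  catIds <- stats::setNames(seq_along(categories), categories)
  images <- list(); annotations <- list()
  annId <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    shp <- imShape(rec@payload)
    images[[i]] <- list(id = i, file_name = paste0(recordFileStem(rec), ".", imageExt),
                        width = shp[2], height = shp[1])
    ins <- rec@annotation
    for (k in seq_len(nInstances(ins))) {
      m <- ins@masks[[k]]
      box <- maskToBox(m)
      annId <- annId + 1L
      seg <- if (encoding == "rle") maskToRle(m) else maskToPolygons(m)
      annotations[[annId]] <- list(
        id = annId, image_id = i,
        category_id = unname(catIds[[ins@labels[k]]]),
        segmentation = seg,
        iscrowd = if (encoding == "rle") 1L else 0L,
        area = sum(m),
        bbox = c(box@xmin, box@ymin, box@xmax - box@xmin, box@ymax - box@ymin))
    }
  }
  list(images = images, annotations = annotations,
       categories = lapply(categories, function(nm)
         list(id = unname(catIds[[nm]]), name = nm)))
}

cocoParse <- function(coco, imageDir) {
  catNames <- stats::setNames(
    vapply(coco$categories, function(c) c$name, ""),
    vapply(coco$categories, function(c) as.character(c$id), ""))
  imgById <- stats::setNames(coco$images,
    vapply(coco$images, function(im) as.character(im$id), ""))
  for (a in coco$annotations)
    if (is.null(imgById[[as.character(a$image_id)]]))
      stop("annotation ", a$id, " references missing image id ", a$image_id,
           call. = FALSE)
  byImage <- split(coco$annotations,
    vapply(coco$annotations, function(a) as.character(a$image_id), ""))
  records <- list()
  for (im in coco$images) {
    path <- file.path(imageDir, im$file_name)
    if (!file.exists(path))
      stop("COCO image file missing: ", path, call. = FALSE)
    img <- readImageFile(path)
    shp <- imShape(img)
    anns <- byImage[[as.character(im$id)]]
    labels <- character(); masks <- list()
    for (a in anns) {
      seg <- a$segmentation
      m <- if (!is.null(seg$counts)) rleToMask(seg)
           else polygonsToMask(seg, shp)
      if (sum(m) == 0) next
      masks[[length(masks) + 1L]] <- m
      labels <- c(labels, catNames[[as.character(a$category_id)]])
    }
    records[[length(records) + 1L]] <- datasetRecord(
      sourceId = tools::file_path_sans_ext(im$file_name),
      problem = "instance", payload = img,
      annotation = instanceSet(labels, masks))
  }
  records
}
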