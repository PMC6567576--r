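## Position-variant geometry. Every geometric technique is materialised into
## a GeometricPlan: an inverse coordinate map giving, for each output pixel,
## the continuous 0-based source coordinate it draws from. The same plan is
## applied to the image (bilinear) and to every annotation raster (nearest
## neighbour), which guarantees that annotations follow the image exactly.

# Smooth a double-valued random field with a gaussian kernel (for elastic
# displacement fields). Replicate-padded so small fields work.
gaussSmoothField <- function(m, sigma) {
  p <- 2 * ceiling(3 * sigma) + 1
  mp <- padReplicate(m, p)
  out <- EBImage::gblur(t(mp), sigma = sigma)
  t(as.array(out))[(p + 1):(p + nrow(m)), (p + 1):(p + ncol(m)), drop = FALSE]
}

#' Resolve a position-variant technique into a concrete geometric plan
#'
#' Materialises all randomness of the technique (a rotation angle sampled
#' from a range, the crop window position, the elastic displacement field)
#' exactly once, so the identical pixel movement can be applied to an image
#' and to each of its annotation rasters. Repeated calls with the same seeded
#' technique and shape return equal plans.
#'
#' Conventions: coordinates are 0-based `(row, col)` with the origin at the
#' top-left; rotation and shear are taken about the image center; the canvas
#' size is preserved except for `crop` and `rescale`; regions vacated by the
#' transform are filled with 0.
#'
#' @param technique a position-variant [Technique-class].
#' @param shape integer `(H, W)` of the raster the plan will be applied to.
#' @return A [GeometricPlan-class].
#' @examples
#' plan <- resolveGeometry(makeTechnique("flip"), c(4L, 6L))
#' @export
resolveGeometry <- function(technique, shape) {
  if (!isPositionVariant(technique))
    stop("resolveGeometry requires a position-variant technique; \"",
         technique@name, "\" is position-invariant and needs no geometry",
         call. = FALSE)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  stopifnot(H >= 1, W >= 1)
  p <- technique@params
  outH <- H; outW <- W
  cy <- (H - 1) / 2; cx <- (W - 1) / 2

  # grids of output coordinates (0-based), row index varies down the matrix
  grid <- function(h, w) list(r = matrix(0:(h - 1), h, w),
                              c = matrix(0:(w - 1), h, w, byrow = TRUE))

  kind <- switch(technique@name,
    "flip" = "flip", "rotation" = "rotation", "translation" = "translation",
    "crop" = "crop", "rescale" = "rescale", "shear" = "shear",
    "elastic-deformation" = "elastic",
    stop("technique \"", technique@name, "\" has no geometric implementation",
         call. = FALSE))

  if (kind == "flip") {
    g <- grid(H, W)
    srcRow <- if (p$mode %in% c("vertical", "both")) (H - 1) - g$r else g$r
    srcCol <- if (p$mode %in% c("horizontal", "both")) (W - 1) - g$c else g$c
  } else if (kind == "rotation") {
    angle <- if (length(p$angle) == 2)
      withSeed(technique@seed, runif(1, p$angle[1], p$angle[2])) else p$angle
    th <- angle * pi / 180
    g <- grid(H, W)
    dx <- g$c - cx; dy <- g$r - cy
    srcCol <- cx + cos(th) * dx + sin(th) * dy
    srcRow <- cy - sin(th) * dx + cos(th) * dy
  } else if (kind == "translation") {
    g <- grid(H, W)
    srcRow <- g$r - p$dy
    srcCol <- g$c - p$dx
  } else if (kind == "shear") {
    th <- p$angle * pi / 180
    g <- grid(H, W)
    srcRow <- g$r
    srcCol <- g$c - tan(th) * (g$r - cy)
  } else if (kind == "crop") {
    outH <- max(1L, as.integer(round(H * p$fraction)))
    outW <- max(1L, as.integer(round(W * p$fraction)))
    if (p$position == "center") {
      r0 <- (H - outH) %/% 2L; c0 <- (W - outW) %/% 2L
    } else {
      off <- withSeed(technique@seed,
                      c(sample.int(H - outH + 1L, 1L), sample.int(W - outW + 1L, 1L)))
      r0 <- off[1] - 1L; c0 <- off[2] - 1L
    }
    g <- grid(outH, outW)
    srcRow <- g$r + r0
    srcCol <- g$c + c0
  } else if (kind == "rescale") {
    outH <- max(1L, as.integer(round(H * p$factor)))
    outW <- max(1L, as.integer(round(W * p$factor)))
    g <- grid(outH, outW)
    srcRow <- g$r * (H / outH)
    srcCol <- g$c * (W / outW)
  } else if (kind == "elastic") {
    g <- grid(H, W)
    if (p$alpha == 0) {
      srcRow <- g$r + 0; srcCol <- g$c + 0
    } else {
      fields <- withSeed(technique@seed, list(
        dr = matrix(runif(H * W, -1, 1), H, W),
        dc = matrix(runif(H * W, -1, 1), H, W)))
      srcRow <- g$r + gaussSmoothField(fields$dr, p$sigma) * p$alpha
      srcCol <- g$c + gaussSmoothField(fields$dc, p$sigma) * p$alpha
    }
  }

  new("GeometricPlan", kind = kind, inShape = c(H, W),
      outShape = c(outH, outW),
      srcRow = matrix(as.numeric(srcRow), outH, outW),
      srcCol = matrix(as.numeric(srcCol), outH, outW))
}

# Gather one channel through the plan. Nearest introduces no new intensity
# values (required for label rasters); bilinear may interpolate. Out-of-canvas
# source coordinates yield 0.
resampleChannel <- function(plan, m, interpolation) {
  H <- plan@inShape[1]; W <- plan@inShape[2]
  sr <- plan@srcRow; sc <- plan@srcCol
  if (interpolation == "nearest") {
    ri <- round(sr); ci <- round(sc)
    inside <- ri >= 0 & ri < H & ci >= 0 & ci < W
    out <- matrix(0, plan@outShape[1], plan@outShape[2])
    idx <- ri[inside] + 1 + ci[inside] * H
    out[inside] <- m[idx]
    out
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    gather <- function(ri, ci) {
      inside <- ri >= 0 & ri < H & ci >= 0 & ci < W
      v <- matrix(0, plan@outShape[1], plan@outShape[2])
      v[inside] <- m[ri[inside] + 1 + ci[inside] * H]
      v
    }
    gather(r0, c0) * (1 - fr) * (1 - fc) +
      gather(r0 + 1, c0) * fr * (1 - fc) +
      gather(r0, c0 + 1) * (1 - fr) * fc +
      gather(r0 + 1, c0 + 1) * fr * fc
  }
}

#' Apply a geometric plan to an image or annotation raster
#'
#' Moves pixels according to the plan's inverse coordinate map. Use
#' `interpolation = "smooth"` (bilinear) for photographic images and
#' `"nearest"` for any label or binary mask raster: nearest-neighbour
#' resampling introduces no intensity values absent from the input, so label
#' images cannot gain interpolated labels. Out-of-canvas regions are filled
#' with 0.
#'
#' @param plan a [GeometricPlan-class] resolved for the raster's shape.
#' @param image 8-bit image array (`H x W` or `H x W x C`).
#' @param interpolation `"smooth"` or `"nearest"`.
#' @return The transformed raster with the plan's output shape.
#' @examples
#' img <- matrix(0L, 5, 5); img[2, 3] <- 255L
#' plan <- resolveGeometry(makeTechnique("flip"), dim(img))
#' applyGeometric(plan, img, "nearest")[2, 3]  # moved to column 3 -> 5-3+1
#' @export
applyGeometric <- function(plan, image, interpolation = c("smooth", "nearest")) {
  interpolation <- match.arg(interpolation)
  checkImage(image)
  if (!all(imShape(image) == plan@inShape))
    stop("plan was resolved for shape ", paste(plan@inShape, collapse = "x"),
         " but image is ", paste(imShape(image), collapse = "x"), call. = FALSE)
  out <- perChannelResample(plan, image, interpolation)
  clamp8(out)
}

perChannelResample <- function(plan, image, interpolation) {
  if (length(dim(image)) == 2)
    return(resampleChannel(plan, image, interpolation))
  C <- dim(image)[3]
  out <- array(0, c(plan@outShape, C))
  for (ch in seq_len(C))
    out[, , ch] <- resampleChannel(plan, image[, , ch], interpolation)
  out
}

#' Apply a technique to a bare image
#'
#' Dispatches to [applyPhotometric()] for position-invariant techniques and
#' to [resolveGeometry()] + [applyGeometric()] (smooth interpolation) for
#' position-variant ones. This is the classification-problem transform; for
#' annotated problems use the `augment*` family, which shares the geometric
#' plan between the image and its annotation.
#'
#' @param technique a [Technique-class].
#' @param image 8-bit image array.
#' @return The transformed image.
#' @export
applyTechnique <- function(technique, image) {
  if (isPositionVariant(technique)) {
    plan <- resolveGeometry(technique, imShape(image))
    applyGeometric(plan, image, "smooth")
  } else {
    applyPhotometric(technique, image)
  }
}
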