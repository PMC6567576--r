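## Position-invariant techniques: blurs, noises, intensity and colour
## adjustments. These alter pixel values but never positions, so the engine
## reuses the input annotation verbatim for all of them. Convolution-based
## filters go through EBImage; images are padded by edge replication first
## because EBImage's filters require the kernel to fit inside the image.

padReplicate <- function(m, p) {
  r <- clamp(seq_len(nrow(m) + 2 * p) - p, 1, nrow(m))
  c <- clamp(seq_len(ncol(m) + 2 * p) - p, 1, ncol(m))
  m[r, c, drop = FALSE]
}

# 2D convolution with replicate padding; kern is a small odd-sized matrix.
convolve2 <- function(m, kern) {
  p <- max(dim(kern))
  mp <- padReplicate(m / 255, p)
  out <- EBImage::filter2(t(mp), t(kern), boundary = "circular")
  out <- t(as.array(out))[(p + 1):(p + nrow(m)), (p + 1):(p + ncol(m)), drop = FALSE]
  clamp8(out * 255)
}

gaussianBlur8 <- function(m, sigma) {
  p <- 2 * ceiling(3 * sigma) + 1
  mp <- padReplicate(m / 255, p)
  out <- EBImage::gblur(t(mp), sigma = sigma)
  out <- t(as.array(out))[(p + 1):(p + nrow(m)), (p + 1):(p + ncol(m)), drop = FALSE]
  clamp8(out * 255)
}

medianBlur8 <- function(m, k) {
  r <- (k - 1) / 2
  if (r < 1) return(m)
  p <- k
  mp <- padReplicate(m, p)
  out <- EBImage::medianFilter(t(mp) / 255, size = r)
  out <- t(as.array(out))[(p + 1):(p + nrow(m)), (p + 1):(p + ncol(m)), drop = FALSE]
  clamp8(out * 255)
}

# Bilateral filter: range-weighted gaussian smoothing. Written out directly
# as a sum over window offsets (vectorised over pixels).
bilateral8 <- function(m, d, sigmaColor, sigmaSpace) {
  r <- (d - 1) / 2
  if (r < 1) return(m)
  mp <- padReplicate(m, r)
  H <- nrow(m); W <- ncol(m)
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  center <- matrix(as.numeric(m), H, W)
  for (dr in -r:r) for (dc in -r:r) {
    shifted <- mp[(1 + r + dr):(H + r + dr), (1 + r + dc):(W + r + dc), drop = FALSE]
    w <- exp(-(dr^2 + dc^2) / (2 * sigmaSpace^2)) *
      exp(-(shifted - center)^2 / (2 * sigmaColor^2))
    num <- num + w * shifted
    den <- den + w
  }
  clamp8(num / den)
}

# Classic integer histogram equalisation via the cumulative distribution.
equalizeGray8 <- function(m) {
  n <- length(m)
  h <- tabulate(as.vector(m) + 1L, nbins = 256L)
  cdf <- cumsum(h)
  cdfMin <- cdf[which(cdf > 0)[1]]
  if (n == cdfMin) return(m)  # constant image
  lut <- clamp8((cdf - cdfMin) / (n - cdfMin) * 255)
  matrix(lut[as.vector(m) + 1L], nrow(m), ncol(m))
}

rgbToHsvMat <- function(img) {
  grDevices::rgb2hsv(r = as.vector(img[, , 1]), g = as.vector(img[, , 2]),
                     b = as.vector(img[, , 3]), maxColorValue = 255)
}

hsvToRgbImg <- function(hsv, H, W) {
  cols <- grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])
  rgb <- grDevices::col2rgb(cols)
  out <- array(0L, c(H, W, 3))
  out[, , 1] <- matrix(rgb[1, ], H, W)
  out[, , 2] <- matrix(rgb[2, ], H, W)
  out[, , 3] <- matrix(rgb[3, ], H, W)
  storage.mode(out) <- "integer"
  out
}

hsvJitter <- function(img, channel, delta) {
  if (imChannels(img) == 1) {
    # grayscale: hue/saturation carry no information; value scales intensity
    if (channel == "v") return(clamp8(img * (1 + delta))) else return(img)
  }
  hsv <- rgbToHsvMat(img)
  if (channel == "h") hsv[1, ] <- (hsv[1, ] + delta) %% 1
  if (channel == "s") hsv[2, ] <- clamp(hsv[2, ] * (1 + delta), 0, 1)
  if (channel == "v") hsv[3, ] <- clamp(hsv[3, ] * (1 + delta), 0, 1)
  hsvToRgbImg(hsv, nrow(img), ncol(img))
}

luminance <- function(img) {
  if (imChannels(img) == 1) return(img)
  clamp8(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

#' Apply a position-invariant technique to an image
#'
#' Covers blurs (average, gaussian, median, bilateral), noises (gaussian,
#' salt-and-pepper, colour noise, dropout), intensity operations (gamma
#' correction, histogram equalisation, min-max normalisation, brightness,
#' contrast, lightning), HSV jitters, sharpening, channel shift, colour-space
#' change and random erasing. The output always has the same height and
#' width (and channel count) as the input; the engine therefore reuses the
#' input annotation verbatim.
#'
#' @param technique a position-invariant [Technique-class].
#' @param image 8-bit image array (`H x W` or `H x W x 3`).
#' @return The transformed image, same shape as the input.
#' @examples
#' img <- matrix(100L, 8, 8)
#' identical(applyPhotometric(makeTechnique("gamma-correction",
#'                                          list(gamma = 1)), img), img)
#' @export
applyPhotometric <- function(technique, image) {
  if (isPositionVariant(technique))
    stop("applyPhotometric requires a position-invariant technique; \"",
         technique@name, "\" is position-variant", call. = FALSE)
  checkImage(image)
  storage.mode(image) <- "integer"
  p <- technique@params
  H <- nrow(image); W <- ncol(image); C <- imChannels(image)
  out <- switch(technique@name,
    "average-blur" = {
      k <- p$k
      perChannel(image, function(m) convolve2(m, matrix(1 / k^2, k, k)))
    },
    "gaussian-blur" = perChannel(image, function(m) gaussianBlur8(m, p$sigma)),
    "median-blur" = perChannel(image, function(m) medianBlur8(m, p$k)),
    "bilateral-blur" = perChannel(image, function(m)
      bilateral8(m, p$d, p$sigmaColor, p$sigmaSpace)),
    "sharpen" = {
      a <- p$amount
      kern <- matrix(c(0, -a, 0, -a, 1 + 4 * a, -a, 0, -a, 0), 3, 3)
      perChannel(image, function(m) convolve2(m, kern))
    },
    "brightness" = clamp8(image + p$delta),
    "contrast" = clamp8((image - 127.5) * p$factor + 127.5),
    "lightning" = clamp8(image * p$gain + p$bias),
    "gamma-correction" = {
      lut <- clamp8(255 * (0:255 / 255)^p$gamma)
      out <- array(lut[image + 1L], dim(image)); storage.mode(out) <- "integer"; out
    },
    "normalization" = {
      rng <- range(image)
      if (rng[1] == rng[2]) image
      else clamp8((image - rng[1]) / (rng[2] - rng[1]) * 255)
    },
    "equalize-histogram" = {
      if (C == 1) equalizeGray8(image)
      else {
        # equalise the luminance channel, rescale RGB proportionally
        y <- luminance(image)
        yEq <- equalizeGray8(y)
        ratio <- (as.numeric(yEq) + 1) / (as.numeric(y) + 1)
        perChannel(image, function(m) clamp8(m * ratio))
      }
    },
    "gaussian-noise" = withSeed(technique@seed,
      clamp8(image + rnorm(length(image), 0, p$sigma))),
    "color-noise" = withSeed(technique@seed,
      clamp8(image + runif(length(image), -p$amplitude, p$amplitude))),
    "salt-and-pepper" = withSeed(technique@seed, {
      hit <- runif(H * W) < p$p
      val <- ifelse(runif(H * W) < 0.5, 0L, 255L)
      out <- image
      if (C == 1) out[hit] <- val[hit]
      else for (ch in 1:C) { plane <- out[, , ch]; plane[hit] <- val[hit]; out[, , ch] <- plane }
      out
    }),
    "dropout" = withSeed(technique@seed, {
      hit <- runif(H * W) < p$p
      out <- image
      if (C == 1) out[hit] <- 0L
      else for (ch in 1:C) { plane <- out[, , ch]; plane[hit] <- 0L; out[, , ch] <- plane }
      out
    }),
    "random-erasing" = withSeed(technique@seed, {
      area <- p$areaFraction * H * W
      aspect <- runif(1, 0.5, 2)
      eh <- max(1L, min(H, as.integer(round(sqrt(area * aspect)))))
      ew <- max(1L, min(W, as.integer(round(sqrt(area / aspect)))))
      r0 <- sample.int(H - eh + 1L, 1L)
      c0 <- sample.int(W - ew + 1L, 1L)
      fill <- if (p$fill == "zero") 0L else
        as.integer(sample.int(256L, eh * ew * C, replace = TRUE) - 1L)
      out <- image
      if (C == 1) out[r0:(r0 + eh - 1L), c0:(c0 + ew - 1L)] <- fill
      else out[r0:(r0 + eh - 1L), c0:(c0 + ew - 1L), ] <- fill
      out
    }),
    "hue-jitter" = hsvJitter(image, "h", p$delta),
    "saturation-jitter" = hsvJitter(image, "s", p$delta),
    "value-jitter" = hsvJitter(image, "v", p$delta),
    "channel-shift" = {
      if (C == 1) clamp8(image + p$shift)
      else {
        offs <- c(p$shift, 0, -p$shift)
        out <- image
        for (ch in 1:3) out[, , ch] <- clamp8(image[, , ch] + offs[ch])
        out
      }
    },
    "change-color-space" = {
      if (p$to == "gray") {
        y <- luminance(image)
        if (C == 1) y else { out <- image; for (ch in 1:3) out[, , ch] <- y; out }
      } else {
        if (C == 1) image
        else {
          hsv <- rgbToHsvMat(image)
          out <- image
          for (ch in 1:3) out[, , ch] <- clamp8(matrix(hsv[ch, ] * 255, H, W))
          out
        }
      }
    },
    stop("technique \"", technique@name, "\" has no photometric implementation",
         call. = FALSE)
  )
  storage.mode(out) <- "integer"
  out
}
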