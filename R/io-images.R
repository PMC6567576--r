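## Raster file IO. PNG and TIFF are read/written natively in (row, col)
## orientation through the png and tiff packages; other formats (JPEG) fall
## back to EBImage's readers. Label masks are read without intensity scaling:
## an 8-bit code image round-trips exactly.

dropAlpha <- function(a) {
  if (length(dim(a)) == 3 && dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
  if (length(dim(a)) == 3 && dim(a)[3] == 1) a <- a[, , 1]
  if (length(dim(a)) == 3 && dim(a)[3] == 2) a <- a[, , 1]  # gray+alpha
  a
}

#' Read a raster image file as an 8-bit array
#'
#' @param path image file (PNG, TIFF or JPEG).
#' @return Integer array `H x W` or `H x W x 3`, intensities 0-255.
#' @export
readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    {
      eb <- EBImage::readImage(path)
      return(clamp8(dropAlpha(fromEB(as.array(eb)))))
    })
  clamp8(dropAlpha(a) * 255)
}

#' Write an 8-bit array to a PNG file
#'
#' @param image integer array `H x W` or `H x W x 3`, 0-255.
#' @param path destination `.png` path.
#' @export
writeImageFile <- function(image, path) {
  checkImage(image)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read a multi-page TIFF as a list of frames
#'
#' @param path `.tif` file.
#' @param asLabels read pages as label rasters (integer codes, no scaling
#'   semantics beyond the 8-bit mapping).
#' @return List of integer `H x W` (or `H x W x 3`) arrays.
#' @export
readStackFile <- function(path, asLabels = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(a) clamp8(dropAlpha(a) * 255))
}

#' Write a list of frames to a multi-page TIFF
#'
#' @param frames list of integer arrays, 0-255, one shape.
#' @param path destination `.tif` path.
#' @export
writeStackFile <- function(frames, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(lapply(frames, function(f) f / 255), path)
  invisible(path)
}

listImageFiles <- function(dir) {
  f <- list.files(dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                  ignore.case = TRUE, full.names = TRUE)
  sort(f)
}
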