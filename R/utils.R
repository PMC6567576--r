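## Internal helpers shared across modules.

#' @import methods
#' @importFrom stats runif rnorm
#' @importFrom utils head tail
NULL

#' Clamp numeric values into an interval
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round and clamp to the 8-bit intensity range
#' @noRd
clamp8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

#' FNV-1a hash of a string, folded into a non-negative 31-bit integer.
#'
#' Used to derive per-(record, technique) child seeds from the master seed so
#' that runs are reproducible and independent of traversal order.
#' @noRd
fnv1a31 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b)) + 2^30
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}

#' Derive a deterministic child seed
#' @noRd
childSeed <- function(masterSeed, sourceId, provenance, techniqueName) {
  fnv1a31(paste(masterSeed, sourceId, paste(provenance, collapse = ">"),
                techniqueName, sep = "|"))
}

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Validate an 8-bit image array
#'
#' Images are integer arrays of dimension `H x W` (grayscale) or `H x W x 3`
#' (colour), row = y (top to bottom), column = x (left to right), intensities
#' in `[0, 255]`.
#' @noRd
checkImage <- function(img, what = "image") {
  if (!is.array(img) && !is.matrix(img))
    stop(what, " must be a matrix or array", call. = FALSE)
  nd <- length(dim(img))
  if (nd == 3 && !dim(img)[3] %in% c(1L, 3L))
    stop(what, " must have 1 or 3 channels", call. = FALSE)
  if (nd != 2 && nd != 3)
    stop(what, " must be 2- or 3-dimensional", call. = FALSE)
  if (any(dim(img)[1:2] < 1)) stop(what, " must be at least 1x1", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(what, " intensities must lie in [0, 255]", call. = FALSE)
  invisible(TRUE)
}

#' Image height/width
#' @noRd
imShape <- function(img) dim(img)[1:2]

#' Number of channels (1 for matrices)
#' @noRd
imChannels <- function(img) if (length(dim(img)) == 3) dim(img)[3] else 1L

#' Apply a per-channel function, preserving dimensionality
#' @noRd
perChannel <- function(img, fun) {
  if (length(dim(img)) == 2) return(fun(img))
  out <- img
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- fun(img[, , ch])
  out
}

#' Convert internal (row, col) integer image to EBImage's (x, y) double image
#' @noRd
toEB <- function(img) {
  if (length(dim(img)) == 2) t(img) / 255 else aperm(img, c(2, 1, 3)) / 255
}

#' Convert an EBImage-oriented array back to the internal 8-bit layout
#' @noRd
fromEB <- function(x) {
  x <- as.array(x)
  out <- if (length(dim(x)) == 2) t(x) else aperm(x, c(2, 1, 3))
  clamp8(out * 255)
}
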