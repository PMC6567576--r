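# Shared helpers: deterministic random rasters and tiny annotated examples.

randomImage <- function(h, w, channels = 1, seed = 1) {
  withr::with_seed(seed, {
    if (channels == 1) {
      m <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
    } else {
      m <- array(sample(0:255, h * w * channels, replace = TRUE), c(h, w, channels))
    }
    storage.mode(m) <- "integer"
    m
  })
}

# All valid integer boxes on a small canvas (0-based half-open).
allBoxes <- function(H, W) {
  out <- list()
  for (x1 in 0:(W - 1)) for (x2 in (x1 + 1):W)
    for (y1 in 0:(H - 1)) for (y2 in (y1 + 1):H)
      out[[length(out) + 1L]] <- boundingBox(x1, y1, x2, y2)
  out
}

# Tiny two-blob scene used across propagation tests.
twoBlobScene <- function() {
  genScene(c(20L, 20L), list(
    shapeSpec("rectangle", center = c(10, 10), size = c(4, 4), label = "a",
              intensity = 200),
    shapeSpec("rectangle", center = c(3, 3), size = c(3, 3), label = "b",
              intensity = 120)))
}

expectedPositionVariant <- c("crop", "elastic-deformation", "flip", "rescale",
                             "rotation", "shear", "translation")
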