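## Technique registry: every augmentation technique the engine knows, its
## position-invariant / position-variant category, and its parameter schema.
## Categories follow the standard split: invariant techniques alter pixel
## values but not object positions (annotations pass through verbatim);
## variant techniques move pixels and require annotation propagation.

# paramSpec entries: list(default, check) where check(value) returns TRUE or
# an error message string.
.posNum <- function(what) function(v)
  if (is.numeric(v) && length(v) == 1 && v > 0) TRUE else
    paste(what, "must be a positive number")
.oddKernel <- function(v)
  if (is.numeric(v) && length(v) == 1 && v >= 1 && v %% 2 == 1) TRUE else
    "kernel size must be a positive odd integer"
.fraction <- function(what) function(v)
  if (is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1) TRUE else
    paste(what, "must lie in [0, 1]")
.anyNum <- function(what) function(v)
  if (is.numeric(v) && length(v) == 1 && is.finite(v)) TRUE else
    paste(what, "must be a finite number")
.numOrRange <- function(what) function(v)
  if (is.numeric(v) && length(v) %in% c(1, 2) && all(is.finite(v))) TRUE else
    paste(what, "must be a number or a (min, max) range")
.choice <- function(what, choices) function(v)
  if (is.character(v) && length(v) == 1 && v %in% choices) TRUE else
    paste0(what, " must be one of: ", paste(choices, collapse = ", "))

TECHNIQUE_REGISTRY <- list(
  ## --- position invariant -------------------------------------------------
  `average-blur`      = list(category = "position_invariant", stochastic = FALSE,
    params = list(k = list(3, .oddKernel))),
  `bilateral-blur`    = list(category = "position_invariant", stochastic = FALSE,
    params = list(d = list(5, .oddKernel),
                  sigmaColor = list(30, .posNum("sigmaColor")),
                  sigmaSpace = list(2, .posNum("sigmaSpace")))),
  brightness          = list(category = "position_invariant", stochastic = FALSE,
    params = list(delta = list(30, .anyNum("delta")))),
  `color-noise`       = list(category = "position_invariant", stochastic = TRUE,
    params = list(amplitude = list(20, .posNum("amplitude")))),
  contrast            = list(category = "position_invariant", stochastic = FALSE,
    params = list(factor = list(1.3, .posNum("factor")))),
  dropout             = list(category = "position_invariant", stochastic = TRUE,
    params = list(p = list(0.05, .fraction("p")))),
  `gamma-correction`  = list(category = "position_invariant", stochastic = FALSE,
    params = list(gamma = list(1.5, .posNum("gamma")))),
  `gaussian-blur`     = list(category = "position_invariant", stochastic = FALSE,
    params = list(sigma = list(1, .posNum("sigma")))),
  `gaussian-noise`    = list(category = "position_invariant", stochastic = TRUE,
    params = list(sigma = list(10, .posNum("sigma")))),
  `hue-jitter`        = list(category = "position_invariant", stochastic = FALSE,
    params = list(delta = list(0.05, .anyNum("delta")))),
  `median-blur`       = list(category = "position_invariant", stochastic = FALSE,
    params = list(k = list(3, .oddKernel))),
  normalization       = list(category = "position_invariant", stochastic = FALSE,
    params = list()),
  `random-erasing`    = list(category = "position_invariant", stochastic = TRUE,
    params = list(areaFraction = list(0.05, .fraction("areaFraction")),
                  fill = list("noise", .choice("fill", c("noise", "zero"))))),
  `salt-and-pepper`   = list(category = "position_invariant", stochastic = TRUE,
    params = list(p = list(0.05, .fraction("p")))),
  `saturation-jitter` = list(category = "position_invariant", stochastic = FALSE,
    params = list(delta = list(0.2, .anyNum("delta")))),
  sharpen             = list(category = "position_invariant", stochastic = FALSE,
    params = list(amount = list(1, .posNum("amount")))),
  `value-jitter`      = list(category = "position_invariant", stochastic = FALSE,
    params = list(delta = list(0.2, .anyNum("delta")))),
  `channel-shift`     = list(category = "position_invariant", stochastic = FALSE,
    params = list(shift = list(20, .anyNum("shift")))),
  lightning           = list(category = "position_invariant", stochastic = FALSE,
    params = list(gain = list(1.2, .posNum("gain")),
                  bias = list(10, .anyNum("bias")))),
  `change-color-space` = list(category = "position_invariant", stochastic = FALSE,
    params = list(to = list("gray", .choice("to", c("gray", "hsv"))))),
  `equalize-histogram` = list(category = "position_invariant", stochastic = FALSE,
    params = list()),
  ## --- position variant ---------------------------------------------------
  crop                = list(category = "position_variant", stochastic = TRUE,
    params = list(fraction = list(0.8, .fraction("fraction")),
                  position = list("center", .choice("position", c("center", "random"))))),
  `elastic-deformation` = list(category = "position_variant", stochastic = TRUE,
    params = list(alpha = list(8, .anyNum("alpha")),
                  sigma = list(3, .posNum("sigma")))),
  flip                = list(category = "position_variant", stochastic = FALSE,
    params = list(mode = list("horizontal",
                  .choice("mode", c("horizontal", "vertical", "both"))))),
  rescale             = list(category = "position_variant", stochastic = FALSE,
    params = list(factor = list(1.2, .posNum("factor")))),
  rotation            = list(category = "position_variant", stochastic = TRUE,
    params = list(angle = list(90, .numOrRange("angle")))),
  shear               = list(category = "position_variant", stochastic = FALSE,
    params = list(angle = list(10, .anyNum("angle")))),
  translation         = list(category = "position_variant", stochastic = FALSE,
    params = list(dx = list(10, .anyNum("dx")), dy = list(10, .anyNum("dy"))))
)

#' List the technique registry
#'
#' @return A data.frame with columns `name`, `category` and `stochastic` for
#'   every registered augmentation technique.
#' @examples
#' head(listTechniques())
#' @export
listTechniques <- function() {
  data.frame(
    name = names(TECHNIQUE_REGISTRY),
    category = vapply(TECHNIQUE_REGISTRY, `[[`, "", "category"),
    stochastic = vapply(TECHNIQUE_REGISTRY, `[[`, NA, "stochastic"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Create a configured augmentation technique
#'
#' Looks up `name` in the registry, validates and completes `params` with the
#' registry defaults, and records the technique's category. Stochastic
#' techniques (noise, random erasing, sampled rotation angles, elastic
#' displacement fields, random crops) draw all randomness from `seed`, so the
#' same seeded technique applied to the same image twice is bitwise identical.
#'
#' @param name registry identifier; see [listTechniques()].
#' @param params named list of parameter overrides.
#' @param seed integer seed for stochastic techniques, or `NULL`.
#' @return A [Technique-class].
#' @examples
#' makeTechnique("flip", list(mode = "vertical"))
#' makeTechnique("gaussian-noise", list(sigma = 5), seed = 7)
#' @export
makeTechnique <- function(name, params = list(), seed = NULL) {
  if (!name %in% names(TECHNIQUE_REGISTRY))
    stop("unknown technique \"", name, "\"; valid names: ",
         paste(names(TECHNIQUE_REGISTRY), collapse = ", "), call. = FALSE)
  entry <- TECHNIQUE_REGISTRY[[name]]
  unknown <- setdiff(names(params), names(entry$params))
  if (length(unknown))
    stop("unknown parameter(s) for ", name, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  resolved <- lapply(entry$params, `[[`, 1)
  for (nm in names(params)) {
    ok <- entry$params[[nm]][[2]](params[[nm]])
    if (!isTRUE(ok)) stop("invalid parameter ", nm, " for ", name, ": ", ok,
                          call. = FALSE)
    resolved[[nm]] <- params[[nm]]
  }
  new("Technique", name = name, category = entry$category, params = resolved,
      seed = if (is.null(seed)) NULL else as.integer(seed))
}

#' Is a technique position-variant?
#' @param technique a [Technique-class].
#' @export
isPositionVariant <- function(technique)
  technique@category == "position_variant"

#' Replace the seed of a technique
#' @param technique a [Technique-class].
#' @param seed integer seed.
#' @return The technique with its seed set.
#' @export
setTechniqueSeed <- function(technique, seed) {
  technique@seed <- as.integer(seed)
  technique
}
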