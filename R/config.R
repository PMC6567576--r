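## JSON run configuration. The schema mirrors the six run parameters: the
## dataset path, the problem kind, the input and output annotation modes,
## the generation mode and the technique list, plus keep policy, label map
## and master seed.

CONFIG_KEYS <- c("schema_version", "problem", "input_mode", "input_path",
                 "output_mode", "output_path", "generation_mode",
                 "include_originals", "min_keep_fraction", "label_map",
                 "master_seed", "techniques", "options")

#' Load and validate a JSON run configuration
#'
#' Required keys: `problem`, `input_mode`, `input_path`, `output_mode`,
#' `output_path`, `generation_mode`, `techniques`. Defaults: identity label
#' map, `include_originals = true`, `min_keep_fraction = 0.3`,
#' `master_seed = 0`. Unknown keys and unknown techniques are rejected with
#' a message naming the offender.
#'
#' @param path JSON file path, or a JSON string.
#' @return An [EngineConfig-class].
#' @examples
#' cfgJson <- '{
#'   "problem": "detection", "input_mode": "yolo", "input_path": "in",
#'   "output_mode": "yolo", "output_path": "out",
#'   "generation_mode": "linear",
#'   "techniques": [
#'     {"name": "flip", "params": {"mode": "vertical"}},
#'     {"name": "rotation", "params": {"angle": [-30, 30]}},
#'     {"name": "average-blur"}
#'   ]
#' }'
#' cfg <- loadConfig(cfgJson)
#' @export
loadConfig <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  required <- c("problem", "input_mode", "input_path", "output_mode",
                "output_path", "generation_mode", "techniques")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required configuration field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!raw$generation_mode %in% c("linear", "power"))
    stop("generation_mode must be \"linear\" or \"power\"", call. = FALSE)
  if (length(raw$techniques) < 1)
    stop("techniques must list at least one technique", call. = FALSE)

  techniques <- lapply(seq_along(raw$techniques), function(i) {
    t <- raw$techniques[[i]]
    if (is.null(t$name))
      stop("techniques[", i, "] is missing \"name\"", call. = FALSE)
    params <- if (is.null(t$params)) list() else
      lapply(t$params, function(v) if (is.list(v)) unlist(v) else v)
    tryCatch(makeTechnique(t$name, params),
             error = function(e)
               stop("techniques[", i, "]: ", conditionMessage(e), call. = FALSE))
  })
  lm <- if (is.null(raw$label_map)) labelMap() else
    labelMap(vapply(raw$label_map, as.character, ""))
  kp <- keepPolicy(if (is.null(raw$min_keep_fraction)) 0.3
                   else raw$min_keep_fraction)
  opts <- if (is.null(raw$options)) list() else raw$options
  io <- ioConfig(problem = raw$problem, inputMode = raw$input_mode,
                 outputMode = raw$output_mode, inputPath = raw$input_path,
                 outputPath = raw$output_path, options = opts)
  engineConfig(io = io, techniques = techniques,
               generationMode = raw$generation_mode,
               includeOriginals = if (is.null(raw$include_originals)) TRUE
                                  else isTRUE(raw$include_originals),
               keepPolicy = kp, labelMap = lm,
               masterSeed = if (is.null(raw$master_seed)) 0L
                            else as.integer(raw$master_seed))
}

#' Serialize an engine configuration back to JSON
#'
#' `loadConfig(serializeConfig(loadConfig(x)))` equals `loadConfig(x)`.
#'
#' @param cfg an [EngineConfig-class].
#' @param path optional file to write to.
#' @return The JSON string, invisibly when writing to a file.
#' @export
serializeConfig <- function(cfg, path = NULL) {
  obj <- list(
    schema_version = 1L,
    problem = cfg@io@problem,
    input_mode = cfg@io@inputMode,
    input_path = cfg@io@inputPath,
    output_mode = cfg@io@outputMode,
    output_path = cfg@io@outputPath,
    generation_mode = cfg@generationMode,
    include_originals = cfg@includeOriginals,
    min_keep_fraction = cfg@keepPolicy@minKeepFraction,
    master_seed = cfg@masterSeed,
    techniques = lapply(cfg@techniques, function(t)
      list(name = t@name, params = t@params)))
  if (length(cfg@labelMap@map)) obj$label_map <- as.list(cfg@labelMap@map)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}
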