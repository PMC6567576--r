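## Dataset reading and writing in the supported (problem, format) matrix.
## Generated filenames embed the source id and the provenance chain so
## outputs are collision-free and traceable back to their original.

FORMAT_MATRIX <- list(
  classification       = "folder",
  localization         = "voc",
  detection            = c("voc", "yolo"),
  semantic             = "masks",
  instance             = "coco",
  stack_classification = "folder",
  stack_segmentation   = "tiff-pairs"
)

#' Supported (problem, format) pairs
#'
#' @return Data.frame with columns `problem` and `format`.
#' @export
supportedFormats <- function() {
  do.call(rbind, lapply(names(FORMAT_MATRIX), function(p)
    data.frame(problem = p, format = FORMAT_MATRIX[[p]],
               stringsAsFactors = FALSE)))
}

checkFormatPair <- function(problem, mode) {
  if (!problem %in% PROBLEMS)
    stop("unknown problem \"", problem, "\"; supported: ",
         paste(PROBLEMS, collapse = ", "), call. = FALSE)
  ok <- FORMAT_MATRIX[[problem]]
  if (is.null(ok) || !mode %in% ok) {
    sf <- supportedFormats()
    stop("unsupported (problem, format) pair (", problem, ", ", mode,
         "); supported pairs: ",
         paste(sprintf("(%s, %s)", sf$problem, sf$format), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# File stem for a record: sourceId for originals, sourceId__t1+t2 otherwise.
recordFileStem <- function(record) {
  if (isOriginal(record)) record@sourceId
  else paste0(record@sourceId, "__", paste(record@provenance, collapse = "+"))
}

ioFail <- function(cfg, msg) {
  if (isTRUE(cfg@options$strict)) stop(msg, call. = FALSE)
  warning(msg, call. = FALSE)
  NULL
}

#' Read a dataset into records
#'
#' Reads every annotated example under `inputPath` in the configured input
#' format and returns one [DatasetRecord-class] per example. In strict mode
#' (default) an unreadable or unpaired file is an error; otherwise it is
#' reported as a warning and skipped. An empty directory yields an empty
#' list.
#'
#' @param cfg an [IOConfig-class].
#' @return List of [DatasetRecord-class] objects.
#' @export
readDataset <- function(cfg) {
  if (!dir.exists(cfg@inputPath))
    stop("input path does not exist: ", cfg@inputPath, call. = FALSE)
  switch(paste(cfg@problem, cfg@inputMode, sep = "/"),
    "classification/folder" = readClassificationFolder(cfg),
    "localization/voc" = readVocDataset(cfg, single = TRUE),
    "detection/voc" = readVocDataset(cfg, single = FALSE),
    "detection/yolo" = readYoloDataset(cfg),
    "semantic/masks" = readSemanticFolder(cfg),
    "instance/coco" = readCocoDataset(cfg),
    "stack_classification/folder" = readStackClassificationFolder(cfg),
    "stack_segmentation/tiff-pairs" = readStackPairs(cfg),
    stop("unsupported (problem, format) pair", call. = FALSE))
}

#' Write records to disk
#'
#' Writes the records in the configured output format. Generated filenames
#' embed the source id plus the provenance chain (`id__flip+rotation.png`).
#' A `manifest.json` with the counts is written alongside.
#'
#' @param records list of [DatasetRecord-class] objects.
#' @param cfg an [IOConfig-class].
#' @param report optional [RunReport-class]; its discard count is included
#'   in the manifest.
#' @return The manifest, invisibly: a list with `originals`, `generated`,
#'   `discarded` counts.
#' @export
writeDataset <- function(records, cfg, report = NULL) {
  for (r in records)
    if (r@problem != cfg@problem)
      stop("record problem ", r@problem, " does not match config ",
           cfg@problem, call. = FALSE)
  dir.create(cfg@outputPath, recursive = TRUE, showWarnings = FALSE)
  switch(paste(cfg@problem, cfg@outputMode, sep = "/"),
    "classification/folder" = writeClassificationFolder(records, cfg),
    "localization/voc" = writeVocDataset(records, cfg),
    "detection/voc" = writeVocDataset(records, cfg),
    "detection/yolo" = writeYoloDataset(records, cfg),
    "semantic/masks" = writeSemanticFolder(records, cfg),
    "instance/coco" = writeCocoDataset(records, cfg),
    "stack_classification/folder" = writeStackClassificationFolder(records, cfg),
    "stack_segmentation/tiff-pairs" = writeStackPairs(records, cfg),
    stop("unsupported (problem, format) pair", call. = FALSE))
  manifest <- list(
    problem = cfg@problem,
    originals = sum(vapply(records, isOriginal, NA)),
    generated = sum(!vapply(records, isOriginal, NA)),
    discarded = if (is.null(report)) 0L else report@nDiscarded)
  jsonlite::write_json(manifest, file.path(cfg@outputPath, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

## --- classification: folder per class --------------------------------------

readClassificationFolder <- function(cfg) {
  classes <- sort(list.dirs(cfg@inputPath, recursive = FALSE, full.names = FALSE))
  records <- list()
  for (cl in classes) {
    for (fp in listImageFiles(file.path(cfg@inputPath, cl))) {
      img <- tryCatch(readImageFile(fp), error = function(e)
        ioFail(cfg, paste0("unreadable image ", fp, ": ", conditionMessage(e))))
      if (is.null(img)) next
      records[[length(records) + 1L]] <- datasetRecord(
        sourceId = paste(cl, tools::file_path_sans_ext(basename(fp)), sep = "-"),
        problem = "classification", payload = img, annotation = cl)
    }
  }
  records
}

writeClassificationFolder <- function(records, cfg) {
  for (r in records)
    writeImageFile(r@payload,
      file.path(cfg@outputPath, r@annotation, paste0(recordFileStem(r), ".png")))
}

## --- localization / detection: VOC ----------------------------------------

readVocDataset <- function(cfg, single) {
  records <- list()
  for (fp in listImageFiles(cfg@inputPath)) {
    xml <- file.path(cfg@inputPath, paste0(tools::file_path_sans_ext(basename(fp)), ".xml"))
    if (!file.exists(xml)) {
      ioFail(cfg, paste("missing VOC annotation for", fp))
      next
    }
    boxes <- tryCatch(readVocXml(xml), error = function(e)
      ioFail(cfg, conditionMessage(e)))
    if (is.null(boxes)) next
    img <- readImageFile(fp)
    sid <- tools::file_path_sans_ext(basename(fp))
    if (single) {
      if (length(boxes) != 1) {
        ioFail(cfg, paste0("localization requires exactly one object; ", xml,
                           " has ", length(boxes)))
        next
      }
      ann <- boxes[[1]]
    } else ann <- boxes
    records[[length(records) + 1L]] <- datasetRecord(
      sourceId = sid, problem = cfg@problem, payload = img, annotation = ann)
  }
  records
}

writeVocDataset <- function(records, cfg) {
  for (r in records) {
    stem <- recordFileStem(r)
    imgFile <- file.path(cfg@outputPath, paste0(stem, ".png"))
    writeImageFile(r@payload, imgFile)
    boxes <- if (cfg@problem == "localization") list(r@annotation) else r@annotation
    writeVocXml(boxes, imgFile, imShape(r@payload), imChannels(r@payload),
                file.path(cfg@outputPath, paste0(stem, ".xml")))
  }
}

## --- detection: YOLO --------------------------------------------------------

readYoloDataset <- function(cfg) {
  classFile <- cfg@options$classFile
  if (is.null(classFile)) classFile <- file.path(cfg@inputPath, "classes.txt")
  if (!file.exists(classFile))
    stop("YOLO class file not found: ", classFile, call. = FALSE)
  classLabels <- readClassFile(classFile)
  records <- list()
  for (fp in listImageFiles(cfg@inputPath)) {
    txt <- file.path(cfg@inputPath, paste0(tools::file_path_sans_ext(basename(fp)), ".txt"))
    if (!file.exists(txt)) {
      ioFail(cfg, paste("missing YOLO annotation for", fp))
      next
    }
    img <- readImageFile(fp)
    lines <- readLines(txt, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    boxes <- tryCatch(lapply(lines, yoloToBox, shape = imShape(img),
                             classLabels = classLabels),
                      error = function(e) ioFail(cfg, paste0(txt, ": ", conditionMessage(e))))
    if (is.null(boxes)) next
    records[[length(records) + 1L]] <- datasetRecord(
      sourceId = tools::file_path_sans_ext(basename(fp)),
      problem = "detection", payload = img, annotation = boxes)
  }
  records
}

writeYoloDataset <- function(records, cfg) {
  classIds <- classRegistryFor(records, cfg@options$classFile)
  writeClassFile(names(classIds), file.path(cfg@outputPath, "classes.txt"))
  for (r in records) {
    stem <- recordFileStem(r)
    writeImageFile(r@payload, file.path(cfg@outputPath, paste0(stem, ".png")))
    lines <- vapply(r@annotation, boxToYolo, "", shape = imShape(r@payload),
                    classIds = classIds)
    writeLines(lines, file.path(cfg@outputPath, paste0(stem, ".txt")))
  }
}

## --- semantic: paired label masks ------------------------------------------

readSemanticFolder <- function(cfg) {
  suffix <- cfg@options$maskSuffix
  files <- listImageFiles(cfg@inputPath)
  stems <- tools::file_path_sans_ext(basename(files))
  isMask <- endsWith(stems, suffix)
  records <- list()
  for (i in which(!isMask)) {
    maskIdx <- which(stems == paste0(stems[i], suffix))
    if (length(maskIdx) == 0) {
      ioFail(cfg, paste("missing mask for", files[i]))
      next
    }
    img <- readImageFile(files[i])
    lab <- readImageFile(files[maskIdx[1]])
    if (length(dim(lab)) == 3) lab <- lab[, , 1]
    if (!all(imShape(img) == dim(lab))) {
      ioFail(cfg, paste("image/mask shape mismatch for", files[i]))
      next
    }
    records[[length(records) + 1L]] <- datasetRecord(
      sourceId = stems[i], problem = "semantic", payload = img,
      annotation = semanticMask(lab))
  }
  records
}

writeSemanticFolder <- function(records, cfg) {
  suffix <- cfg@options$maskSuffix
  for (r in records) {
    stem <- recordFileStem(r)
    writeImageFile(r@payload, file.path(cfg@outputPath, paste0(stem, ".png")))
    writeImageFile(r@annotation@labels,
                   file.path(cfg@outputPath, paste0(stem, suffix, ".png")))
  }
}

## --- instance: COCO ---------------------------------------------------------

readCocoDataset <- function(cfg) {
  jsonFile <- file.path(cfg@inputPath, "annotations.json")
  if (!file.exists(jsonFile))
    stop("COCO annotations.json not found in ", cfg@inputPath, call. = FALSE)
  coco <- jsonlite::fromJSON(jsonFile, simplifyVector = FALSE)
  cocoParse(coco, cfg@inputPath)
}

writeCocoDataset <- function(records, cfg) {
  for (r in records)
    writeImageFile(r@payload,
                   file.path(cfg@outputPath, paste0(recordFileStem(r), ".png")))
  # stems double as file names, so build the JSON against augmented records
  recs <- lapply(records, function(r) {
    r@sourceId <- recordFileStem(r); r@provenance <- character(); r
  })
  coco <- cocoBuild(recs, encoding = cfg@options$cocoEncoding)
  jsonlite::write_json(coco, file.path(cfg@outputPath, "annotations.json"),
                       auto_unbox = TRUE, digits = NA)
}

## --- stacks ------------------------------------------------------------------

readFramesFrom <- function(path) {
  if (dir.exists(path)) {
    lapply(listImageFiles(path), readImageFile)
  } else {
    readStackFile(path)
  }
}

readStackClassificationFolder <- function(cfg) {
  classes <- sort(list.dirs(cfg@inputPath, recursive = FALSE, full.names = FALSE))
  records <- list()
  for (cl in classes) {
    dirPath <- file.path(cfg@inputPath, cl)
    videos <- c(sort(list.dirs(dirPath, recursive = FALSE)),
                sort(list.files(dirPath, pattern = "\\.(tif|tiff)$",
                                ignore.case = TRUE, full.names = TRUE)))
    for (v in videos) {
      frames <- readFramesFrom(v)
      if (length(frames) == 0) next
      records[[length(records) + 1L]] <- datasetRecord(
        sourceId = paste(cl, tools::file_path_sans_ext(basename(v)), sep = "-"),
        problem = "stack_classification", payload = frames, annotation = cl)
    }
  }
  records
}

writeStackClassificationFolder <- function(records, cfg) {
  for (r in records) {
    stackDir <- file.path(cfg@outputPath, r@annotation, recordFileStem(r))
    dir.create(stackDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(r@payload))
      writeImageFile(r@payload[[i]],
                     file.path(stackDir, sprintf("frame_%04d.png", i)))
  }
}

readStackPairs <- function(cfg) {
  suffix <- cfg@options$maskSuffix
  files <- sort(list.files(cfg@inputPath, pattern = "\\.(tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  stems <- tools::file_path_sans_ext(basename(files))
  isMask <- endsWith(stems, suffix)
  records <- list()
  for (i in which(!isMask)) {
    maskIdx <- which(stems == paste0(stems[i], suffix))
    if (length(maskIdx) == 0) {
      ioFail(cfg, paste("missing mask stack for", files[i]))
      next
    }
    frames <- readStackFile(files[i])
    maskFrames <- readStackFile(files[maskIdx[1]], asLabels = TRUE)
    if (length(frames) != length(maskFrames))
      stop("frame-count mismatch between ", files[i], " (", length(frames),
           ") and ", files[maskIdx[1]], " (", length(maskFrames), ")",
           call. = FALSE)
    masks <- lapply(maskFrames, function(m) {
      if (length(dim(m)) == 3) m <- m[, , 1]
      semanticMask(m)
    })
    records[[length(records) + 1L]] <- datasetRecord(
      sourceId = stems[i], problem = "stack_segmentation", payload = frames,
      annotation = masks)
  }
  records
}

writeStackPairs <- function(records, cfg) {
  suffix <- cfg@options$maskSuffix
  for (r in records) {
    stem <- recordFileStem(r)
    writeStackFile(r@payload, file.path(cfg@outputPath, paste0(stem, ".tif")))
    writeStackFile(lapply(r@annotation, function(sm) sm@labels),
                   file.path(cfg@outputPath, paste0(stem, suffix, ".tif")))
  }
}
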