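## Run orchestration: linear and power generation modes, dataset
## combination, and the full read -> augment -> write pipeline.
##
## Child seeds: every (record, technique) application gets its own seed,
## derived by hashing the master seed, the record's source id, its
## provenance chain and the technique name. Runs are therefore reproducible
## and independent of traversal order, including stochastic techniques in
## power mode.

#' Apply one technique to one record
#'
#' Dispatches to the problem-specific propagation routine, threading the
#' keep policy and the label map. The child seed for stochastic techniques
#' is derived from `masterSeed` and the record identity.
#'
#' @param record a [DatasetRecord-class].
#' @param technique a [Technique-class].
#' @param policy a [KeepPolicy-class].
#' @param f a [LabelMap-class].
#' @param masterSeed integer master seed.
#' @param tag provenance tag for the technique; defaults to its name. The
#'   engine disambiguates duplicate names in one run (`rotation`,
#'   `rotation.2`, ...) so provenance chains and generated filenames stay
#'   collision-free.
#' @return The augmented [DatasetRecord-class] (provenance extended by the
#'   technique tag), or `NULL` if the example was discarded.
#' @export
augmentRecord <- function(record, technique, policy = keepPolicy(),
                          f = labelMap(), masterSeed = 0L,
                          tag = technique@name) {
  technique <- setTechniqueSeed(technique,
    childSeed(masterSeed, record@sourceId, record@provenance, tag))
  res <- switch(record@problem,
    classification = augmentClassification(record@payload, record@annotation,
                                           technique, f),
    localization = {
      r <- augmentLocalization(record@payload, record@annotation, technique,
                               policy, f)
      if (is.null(r)) NULL else list(payload = r$image, annotation = r$box)
    },
    detection = {
      r <- augmentDetection(record@payload, record@annotation, technique,
                            policy, f)
      if (is.null(r)) NULL else list(payload = r$image, annotation = r$boxes)
    },
    semantic = {
      r <- augmentSemantic(record@payload, record@annotation, technique, f)
      list(payload = r$image, annotation = r$mask)
    },
    instance = {
      r <- augmentInstance(record@payload, record@annotation, technique,
                           policy, f)
      if (is.null(r)) NULL else list(payload = r$image, annotation = r$instances)
    },
    {
      # stack problems
      r <- augmentStack(record@payload, record@annotation, technique,
                        problem = record@problem, policy = policy, f = f)
      if (is.null(r)) NULL else list(payload = r$frames, annotation = r$annotation)
    })
  if (is.null(res)) return(NULL)
  if (record@problem == "classification")
    res <- list(payload = res$image, annotation = res$label)
  datasetRecord(sourceId = record@sourceId, problem = record@problem,
                payload = res$payload, annotation = res$annotation,
                provenance = c(record@provenance, tag))
}

# Unique provenance tags for a technique list: duplicate names get an
# occurrence suffix (rotation, rotation.2, rotation.3).
techniqueTags <- function(techniques) {
  nms <- vapply(techniques, function(t) t@name, "")
  tags <- nms
  for (nm in unique(nms[duplicated(nms)])) {
    idx <- which(nms == nm)
    tags[idx[-1]] <- paste0(nm, ".", seq_along(idx)[-1])
  }
  tags
}

emptyBreakdown <- function(techniques) {
  data.frame(technique = techniqueTags(techniques),
             generated = 0L, discarded = 0L, stringsAsFactors = FALSE)
}

#' Linear generation mode
#'
#' Each of the `m` configured techniques is applied once to each of the `n`
#' originals, producing at most `n * m` generated records; the count law
#' `nGenerated + nDiscarded = n * m` always holds. When
#' `includeOriginals` is set (the default) the originals are part of the
#' returned dataset.
#'
#' @param records list of original [DatasetRecord-class] objects.
#' @param cfg an [EngineConfig-class] with `generationMode = "linear"`.
#' @return `list(records = , report = )` with a [RunReport-class].
#' @export
runLinear <- function(records, cfg) {
  if (cfg@generationMode != "linear")
    stop("runLinear requires generationMode = \"linear\"", call. = FALSE)
  breakdown <- emptyBreakdown(cfg@techniques)
  tags <- techniqueTags(cfg@techniques)
  out <- if (cfg@includeOriginals) records else list()
  for (ti in seq_along(cfg@techniques)) {
    tech <- cfg@techniques[[ti]]
    for (rec in records) {
      newRec <- augmentRecord(rec, tech, cfg@keepPolicy, cfg@labelMap,
                              cfg@masterSeed, tag = tags[ti])
      if (is.null(newRec)) {
        breakdown$discarded[ti] <- breakdown$discarded[ti] + 1L
      } else {
        breakdown$generated[ti] <- breakdown$generated[ti] + 1L
        out[[length(out) + 1L]] <- newRec
      }
    }
  }
  report <- new("RunReport", nOriginals = length(records),
                nGenerated = sum(breakdown$generated),
                nDiscarded = sum(breakdown$discarded),
                perTechnique = breakdown)
  list(records = out, report = report)
}

#' Power generation mode
#'
#' Pipeline semantics: with `D_0` the originals, stage `i` applies technique
#' `i` to every record of `D_(i-1)` and adds the survivors, so
#' `D_i = D_(i-1) + technique_i(D_(i-1))`. With no discards the new records
#' number `(2^m - 1) * n`, and their provenance strings are exactly the
#' non-empty ordered subsequences of the technique list. A record discarded
#' at stage `i` does not propagate to later stages; its would-be descendants
#' are counted as discarded so that
#' `nGenerated + nDiscarded = (2^m - 1) * n` always holds.
#'
#' @param records list of original [DatasetRecord-class] objects.
#' @param cfg an [EngineConfig-class] with `generationMode = "power"`.
#' @return `list(records = , report = )` with a [RunReport-class].
#' @export
runPower <- function(records, cfg) {
  if (cfg@generationMode != "power")
    stop("runPower requires generationMode = \"power\"", call. = FALSE)
  m <- length(cfg@techniques)
  breakdown <- emptyBreakdown(cfg@techniques)
  tags <- techniqueTags(cfg@techniques)
  current <- records
  generatedAll <- list()
  for (ti in seq_len(m)) {
    tech <- cfg@techniques[[ti]]
    stageNew <- list()
    for (rec in current) {
      newRec <- augmentRecord(rec, tech, cfg@keepPolicy, cfg@labelMap,
                              cfg@masterSeed, tag = tags[ti])
      if (is.null(newRec)) {
        breakdown$discarded[ti] <- breakdown$discarded[ti] + 1L
      } else {
        breakdown$generated[ti] <- breakdown$generated[ti] + 1L
        stageNew[[length(stageNew) + 1L]] <- newRec
      }
    }
    current <- c(current, stageNew)
    generatedAll <- c(generatedAll, stageNew)
  }
  nGen <- length(generatedAll)
  theoretical <- (2^m - 1) * length(records)
  out <- if (cfg@includeOriginals) c(records, generatedAll) else generatedAll
  report <- new("RunReport", nOriginals = length(records),
                nGenerated = as.integer(nGen),
                nDiscarded = as.integer(theoretical - nGen),
                perTechnique = breakdown)
  list(records = out, report = report)
}

#' Combine augmentation runs over a shared original dataset
#'
#' Takes the union of several output record lists that derive from the same
#' originals: originals (empty provenance) are deduplicated by source id and
#' included once; all generated records are kept. Combining a 5000-record
#' and a 3000-record run over the same 1000 originals therefore yields 7000
#' records.
#'
#' @param runs list of record lists (each as returned in
#'   `runLinear(...)$records`).
#' @return Combined list of [DatasetRecord-class] objects.
#' @export
combineDatasets <- function(runs) {
  if (length(runs) == 0) return(list())
  origIds <- lapply(runs, function(recs)
    sort(unique(vapply(Filter(isOriginal, recs), recordId, ""))))
  for (ids in origIds[-1])
    if (!identical(ids, origIds[[1]]))
      stop("runs do not share the same original dataset", call. = FALSE)
  seenOrig <- character()
  seenGen <- character()
  out <- list()
  for (recs in runs) {
    for (r in recs) {
      key <- recordFileStem(r)
      if (isOriginal(r)) {
        if (r@sourceId %in% seenOrig) next
        seenOrig <- c(seenOrig, r@sourceId)
      } else {
        if (key %in% seenGen) next
        seenGen <- c(seenGen, key)
      }
      out[[length(out) + 1L]] <- r
    }
  }
  out
}

#' Run a full augmentation job
#'
#' Reads the dataset described by the configuration's [IOConfig-class],
#' runs the configured generation mode, and writes the output dataset and
#' manifest.
#'
#' @param cfg an [EngineConfig-class].
#' @return `list(records = , report = , manifest = )`, invisibly.
#' @export
augmentDataset <- function(cfg) {
  records <- readDataset(cfg@io)
  res <- if (cfg@generationMode == "linear") runLinear(records, cfg)
         else runPower(records, cfg)
  manifest <- writeDataset(res$records, cfg@io, res$report)
  invisible(list(records = res$records, report = res$report,
                 manifest = manifest))
}
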