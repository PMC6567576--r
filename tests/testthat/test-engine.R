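# Generation modes, count laws, combination, configuration and the CLI.

safeTechniques <- function(k = 3) {
  # identity-safe: never discard when objects stay clear of the border
  list(makeTechnique("flip"),
       makeTechnique("rotation", list(angle = 90)),
       makeTechnique("gamma-correction"),
       makeTechnique("brightness"))[seq_len(k)]
}

test_that("linear mode produces n x m generated records when nothing is
           discarded", {
  recs <- genExamples("classification", 5, seed = 1, canvas = c(24L, 24L))
  cfg <- engineConfig(ioConfig("classification", "folder"),
                      safeTechniques(4), "linear", masterSeed = 2)
  res <- runLinear(recs, cfg)
  expect_equal(nGenerated(res$report), 20)
  expect_equal(nDiscarded(res$report), 0)
  expect_length(res$records, 25)  # originals kept by default
  cfg@includeOriginals <- FALSE
  expect_length(runLinear(recs, cfg)$records, 20)
})

test_that("power mode follows the pipeline recurrence and its count formula", {
  recs <- genExamples("classification", 10, seed = 2, canvas = c(24L, 24L))
  cfg <- engineConfig(ioConfig("classification", "folder"),
                      safeTechniques(3), "power", masterSeed = 3)
  res <- runPower(recs, cfg)
  expect_equal(nGenerated(res$report), 70)  # (2^3 - 1) * 10
  expect_length(res$records, 80)
  # provenance chains are exactly the non-empty ordered subsequences of the
  # technique list (brute-force enumeration for m = 3)
  tags <- vapply(safeTechniques(3), function(t) t@name, "")
  subseqs <- unlist(lapply(1:7, function(bits) {
    paste(tags[as.logical(bitwAnd(bits, c(1, 2, 4)))], collapse = "+")
  }))
  provs <- vapply(Filter(function(r) !isOriginal(r), res$records),
                  function(r) paste(recordProvenance(r), collapse = "+"), "")
  expect_setequal(unique(provs), subseqs)
  expect_equal(as.vector(table(provs)), rep(10L, 7))
})

test_that("power mode with m = 1 coincides with linear mode", {
  recs <- genExamples("semantic", 4, seed = 3, canvas = c(24L, 24L))
  io <- ioConfig("semantic", "masks")
  lin <- runLinear(recs, engineConfig(io, safeTechniques(1), "linear",
                                      masterSeed = 7))
  pow <- runPower(recs, engineConfig(io, safeTechniques(1), "power",
                                     masterSeed = 7))
  expect_equal(nGenerated(lin$report), nGenerated(pow$report))
  expect_equal(length(lin$records), length(pow$records))
  expect_identical(recordPayload(lin$records[[5]]), recordPayload(pow$records[[5]]))
})

test_that("count laws hold under discards for randomized small runs", {
  # translation-heavy technique lists push objects off borderless canvases,
  # so discards actually occur; the accounting laws must still hold
  pool <- list(makeTechnique("translation", list(dx = 18, dy = 0)),
               makeTechnique("translation", list(dx = 0, dy = 15)),
               makeTechnique("flip"),
               makeTechnique("crop", list(fraction = 0.45)))
  withr::with_seed(99, {
    for (rep in 1:5) {
      n <- sample(3:8, 1); m <- sample(1:4, 1)
      recs <- genExamples("detection", n, seed = rep, canvas = c(24L, 24L))
      # place some objects near the border to make discards likely
      techniques <- pool[sample(4, m)]
      io <- ioConfig("detection", "voc")
      lin <- runLinear(recs, engineConfig(io, techniques, "linear",
                                          masterSeed = rep))
      expect_equal(nGenerated(lin$report) + nDiscarded(lin$report), n * m)
      pow <- runPower(recs, engineConfig(io, techniques, "power",
                                         masterSeed = rep))
      expect_equal(nGenerated(pow$report) + nDiscarded(pow$report),
                   (2^m - 1) * n)
    }
  })
})

test_that("combining runs deduplicates shared originals and keeps all
           generated records", {
  recs <- genExamples("classification", 20, seed = 4, canvas = c(24L, 24L))
  io <- ioConfig("classification", "folder")
  runA <- runLinear(recs, engineConfig(io, list(
    makeTechnique("elastic-deformation")), "linear", masterSeed = 5))
  runB <- runLinear(recs, engineConfig(io, list(
    makeTechnique("rotation", list(angle = 45)),
    makeTechnique("rotation", list(angle = 90)),
    makeTechnique("rotation", list(angle = 135)),
    makeTechnique("translation", list(dx = 3, dy = 0)),
    makeTechnique("translation", list(dx = 0, dy = 3)),
    makeTechnique("flip"),
    makeTechnique("flip", list(mode = "vertical")),
    makeTechnique("shear", list(angle = 8)),
    makeTechnique("gamma-correction"),
    makeTechnique("equalize-histogram")), "linear", masterSeed = 5))
  expect_length(runA$records, 40)
  expect_length(runB$records, 220)
  comb <- combineDatasets(list(runA$records, runB$records))
  expect_length(comb, 240)  # shared originals counted once
  # idempotence: combining a run with itself changes nothing
  expect_length(combineDatasets(list(runA$records, runA$records)), 40)
  # mismatched original sets are an error
  other <- genExamples("classification", 3, seed = 9, canvas = c(24L, 24L))
  expect_error(combineDatasets(list(runA$records, other)), "same original")
})

test_that("duplicate technique names get distinct provenance tags", {
  recs <- genExamples("classification", 2, seed = 6, canvas = c(24L, 24L))
  cfg <- engineConfig(ioConfig("classification", "folder"), list(
    makeTechnique("rotation", list(angle = 30)),
    makeTechnique("rotation", list(angle = 60))), "linear", masterSeed = 1)
  res <- runLinear(recs, cfg)
  provs <- vapply(Filter(function(r) !isOriginal(r), res$records),
                  function(r) recordProvenance(r), "")
  expect_setequal(unique(provs), c("rotation", "rotation.2"))
})

test_that("identical configuration and master seed give byte-identical
           outputs", {
  src <- withr::local_tempdir()
  genDataset("detection", 3, format = "yolo", seed = 8, outDir = src,
             canvas = c(32L, 32L))
  runTo <- function(outDir) {
    cfgJson <- sprintf('{
      "problem": "detection", "input_mode": "yolo", "input_path": "%s",
      "output_mode": "yolo", "output_path": "%s",
      "generation_mode": "linear", "master_seed": 31,
      "techniques": [
        {"name": "gaussian-noise", "params": {"sigma": 12}},
        {"name": "rotation", "params": {"angle": [-25, 25]}},
        {"name": "elastic-deformation", "params": {"alpha": 4, "sigma": 2}}
      ]}', src, outDir)
    augmentDataset(loadConfig(cfgJson))
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  runTo(d1); runTo(d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(h1, h2)
})

test_that("configuration loading validates fields, keys and techniques", {
  base <- '{
    "problem": "detection", "input_mode": "yolo", "input_path": "in",
    "output_mode": "yolo", "output_path": "out",
    "generation_mode": "linear",
    "techniques": [{"name": "flip", "params": {"mode": "vertical"}},
                   {"name": "rotation", "params": {"angle": [-30, 30]}},
                   {"name": "average-blur"}]}'
  cfg <- loadConfig(base)
  expect_length(cfg@techniques, 3)
  expect_equal(cfg@generationMode, "linear")
  expect_equal(cfg@keepPolicy@minKeepFraction, 0.3)  # default
  expect_true(cfg@includeOriginals)                   # default
  # serialize -> load is stable
  cfg2 <- loadConfig(serializeConfig(cfg))
  expect_equal(serializeConfig(cfg2), serializeConfig(cfg))
  expect_error(loadConfig(sub("generation_mode", "generation_mod", base)),
               "generation_mod")
  expect_error(loadConfig(sub('"flip"', '"flop"', base)), "flop")
  noMode <- '{
    "problem": "detection", "input_mode": "yolo", "input_path": "in",
    "output_mode": "yolo", "output_path": "out",
    "techniques": [{"name": "flip"}]}'
  expect_error(loadConfig(noMode), "generation_mode")
})

test_that("the CLI lists techniques, validates configs and runs jobs", {
  expect_equal(suppressMessages(cliMain(character())), 1L)
  out <- capture.output(code <- cliMain("techniques"))
  expect_equal(code, 0L)
  expect_true(any(grepl("elastic-deformation", out)))
  expect_true(any(grepl("position variant", out)))

  src <- withr::local_tempdir(); dst <- withr::local_tempdir()
  genDataset("detection", 2, format = "yolo", seed = 10, outDir = src,
             canvas = c(24L, 24L))
  cfgFile <- file.path(withr::local_tempdir(), "cfg.json")
  writeLines(sprintf('{
    "problem": "detection", "input_mode": "yolo", "input_path": "%s",
    "output_mode": "yolo", "output_path": "%s",
    "generation_mode": "linear", "master_seed": 4,
    "techniques": [{"name": "flip", "params": {"mode": "vertical"}},
                   {"name": "average-blur"}]}', src, dst), cfgFile)
  expect_equal(suppressMessages(cliMain(c("validate", "--config", cfgFile))), 0L)
  out <- capture.output(
    code <- suppressMessages(cliMain(c("augment", "--config", cfgFile))))
  expect_equal(code, 0L)
  # report consistent with a direct library call: 2 originals x 2 techniques
  expect_true(any(grepl('"generated": 4', out)))
  expect_length(list.files(dst, pattern = "__"), 8)  # 4 images + 4 txt
  expect_equal(suppressMessages(cliMain(c("validate", "--config",
                                          "/nonexistent.json"))), 1L)
  expect_equal(suppressMessages(cliMain("frobnicate")), 1L)
})
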