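# Augmentation techniques: registry contracts, photometric behaviour,
# geometric plans and their exact pixel-index semantics.

test_that("registry rejects unknown techniques and invalid parameters", {
  expect_error(makeTechnique("no-such-thing"), "valid names")
  expect_error(makeTechnique("average-blur", list(k = -3)), "odd")
  expect_error(makeTechnique("flip", list(mode = "diagonal")), "one of")
  expect_error(makeTechnique("gaussian-blur", list(radius = 2)), "unknown parameter")
})

test_that("every technique carries the expected category and respects the
           photometric/geometric split", {
  tab <- listTechniques()
  expect_setequal(tab$name[tab$category == "position_variant"],
                  expectedPositionVariant)
  img <- randomImage(16, 16, seed = 3)
  for (nm in tab$name) {
    tech <- makeTechnique(nm, seed = 5)
    if (isPositionVariant(tech)) {
      expect_error(applyPhotometric(tech, img), "position-variant")
      expect_s4_class(resolveGeometry(tech, dim(img)), "GeometricPlan")
    } else {
      expect_error(resolveGeometry(tech, dim(img)), "position-invariant")
      out <- applyPhotometric(tech, img)
      expect_identical(dim(out)[1:2], dim(img)[1:2])
      expect_true(min(out) >= 0 && max(out) <= 255)
    }
  }
})

test_that("photometric techniques preserve shape on colour images too", {
  img <- randomImage(14, 11, channels = 3, seed = 9)
  for (nm in listTechniques()$name[!listTechniques()$name %in%
                                   expectedPositionVariant]) {
    out <- applyPhotometric(makeTechnique(nm, seed = 2), img)
    expect_identical(dim(out), dim(img))
  }
})

test_that("identity-parameter techniques reproduce the input bitwise", {
  img <- randomImage(9, 13, seed = 4)
  expect_identical(applyPhotometric(makeTechnique("gamma-correction",
                                                  list(gamma = 1)), img), img)
  # median blur of a constant image is the constant image
  const <- matrix(77L, 10, 10)
  expect_identical(applyPhotometric(makeTechnique("median-blur", list(k = 3)),
                                    const), const)
  idSpecs <- list(
    list("rotation", list(angle = 0)),
    list("translation", list(dx = 0, dy = 0)),
    list("rescale", list(factor = 1)),
    list("shear", list(angle = 0)),
    list("elastic-deformation", list(alpha = 0)))
  for (s in idSpecs) {
    plan <- resolveGeometry(makeTechnique(s[[1]], s[[2]]), dim(img))
    expect_identical(applyGeometric(plan, img, "nearest"), img)
    expect_lte(max(abs(applyGeometric(plan, img, "smooth") - img)), 1)
  }
})

test_that("flips are involutions, bitwise, in every mode", {
  img <- randomImage(7, 12, seed = 6)
  for (mode in c("horizontal", "vertical", "both")) {
    plan <- resolveGeometry(makeTechnique("flip", list(mode = mode)), dim(img))
    once <- applyGeometric(plan, img, "nearest")
    expect_identical(applyGeometric(plan, once, "nearest"), img)
    expect_false(mode != "both" && identical(once, img))
  }
})

test_that("seeded techniques are replayable bitwise", {
  img <- randomImage(20, 20, channels = 3, seed = 8)
  stochastic <- listTechniques()$name[listTechniques()$stochastic]
  for (nm in stochastic) {
    tech <- makeTechnique(nm, seed = 7)
    if (isPositionVariant(tech)) {
      p1 <- resolveGeometry(tech, dim(img)[1:2])
      p2 <- resolveGeometry(tech, dim(img)[1:2])
      expect_identical(p1@srcRow, p2@srcRow)
      expect_identical(p1@srcCol, p2@srcCol)
    } else {
      expect_identical(applyPhotometric(tech, img), applyPhotometric(tech, img))
    }
  }
  # different seeds actually differ (noise is not degenerate)
  n1 <- applyPhotometric(makeTechnique("gaussian-noise", seed = 1), img)
  n2 <- applyPhotometric(makeTechnique("gaussian-noise", seed = 2), img)
  expect_false(identical(n1, n2))
})

test_that("90-degree rotation matches the brute-force index permutation", {
  # oracle: on an n x n canvas the implemented rotation sends source pixel
  # (a, b) to (b, n - 1 - a); verified pixel-by-pixel with one-hot images
  n <- 5
  tech <- makeTechnique("rotation", list(angle = 90))
  plan <- resolveGeometry(tech, c(n, n))
  for (a in 0:(n - 1)) for (b in 0:(n - 1)) {
    hot <- matrix(0L, n, n); hot[a + 1, b + 1] <- 255L
    out <- applyGeometric(plan, hot, "nearest")
    expected <- matrix(0L, n, n); expected[b + 1, n - a] <- 255L
    expect_identical(out, expected)
  }
})

test_that("geometric plans move image pixels and one-hot masks identically", {
  # geometry/annotation coherence, exhaustively on a small raster
  H <- 6L; W <- 8L
  plans <- list(
    resolveGeometry(makeTechnique("flip", list(mode = "both")), c(H, W)),
    resolveGeometry(makeTechnique("translation", list(dx = 2, dy = -1)), c(H, W)),
    resolveGeometry(makeTechnique("rotation", list(angle = 37), seed = 1), c(H, W)),
    resolveGeometry(makeTechnique("shear", list(angle = 15)), c(H, W)),
    resolveGeometry(makeTechnique("elastic-deformation",
                                  list(alpha = 2, sigma = 2), seed = 3), c(H, W)))
  img <- randomImage(H, W, seed = 11) + 1L  # strictly positive intensities
  for (plan in plans) {
    warpedImg <- applyGeometric(plan, img, "nearest")
    for (r in 0:(H - 1)) for (c in 0:(W - 1)) {
      hot <- matrix(0L, H, W); hot[r + 1, c + 1] <- 1L
      warpedHot <- applyGeometric(plan, hot, "nearest")
      at <- which(warpedHot == 1L)
      # wherever the one-hot pixel lands, the image pixel landed too
      if (length(at)) expect_true(all(warpedImg[at] == img[r + 1, c + 1]))
    }
  }
})

test_that("nearest interpolation introduces no new intensity values", {
  img <- matrix(sample(c(0L, 40L, 200L), 100, replace = TRUE), 10, 10)
  for (spec in list(list("rotation", list(angle = 33)),
                    list("rescale", list(factor = 1.7)),
                    list("elastic-deformation", list(alpha = 3, sigma = 2)))) {
    plan <- resolveGeometry(makeTechnique(spec[[1]], spec[[2]], seed = 4),
                            dim(img))
    out <- applyGeometric(plan, img, "nearest")
    expect_true(all(out %in% c(0L, 40L, 200L)))
  }
})

test_that("salt-and-pepper alters a binomially plausible fraction of pixels", {
  img <- matrix(128L, 100, 100)
  out <- applyPhotometric(makeTechnique("salt-and-pepper", list(p = 0.1),
                                        seed = 5), img)
  altered <- sum(out != img)
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.1)
  expect_gte(altered, bounds[1])
  expect_lte(altered, bounds[2])
  expect_true(all(out[out != img] %in% c(0L, 255L)))
})

test_that("crop and rescale change the canvas as configured", {
  img <- randomImage(40, 60, seed = 2)
  planC <- resolveGeometry(makeTechnique("crop", list(fraction = 0.5)), dim(img))
  expect_identical(planC@outShape, c(20L, 30L))
  cropped <- applyGeometric(planC, img, "nearest")
  expect_identical(cropped, img[11:30, 16:45])  # central window, exact copy
  planR <- resolveGeometry(makeTechnique("rescale", list(factor = 1.5)), dim(img))
  expect_identical(planR@outShape, c(60L, 90L))
  expect_error(applyGeometric(planC, randomImage(10, 10)), "shape")
})
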