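# Annotation propagation: box/mask conversions, the mask pipeline against
# closed-form oracles, keep-policy discards, and stack coherence.

test_that("boxToMask renders exactly the half-open rectangle", {
  expect_equal(sum(boxToMask(boundingBox(0, 0, 2, 2), c(4L, 4L))), 4)
  expect_true(all(boxToMask(boundingBox(0, 0, 5, 7), c(7L, 5L)) == 1L))
  # enumerate rectangle membership for all 25 pixels of a 5x5 canvas
  m <- boxToMask(boundingBox(1, 1, 2, 3), c(5L, 5L))
  for (r in 0:4) for (c in 0:4)
    expect_identical(m[r + 1, c + 1],
                     as.integer(r >= 1 && r < 3 && c >= 1 && c < 2))
  expect_error(boxToMask(boundingBox(0, 0, 6, 2), c(5L, 5L)), "canvas")
})

test_that("maskToBox is the inverse of boxToMask and handles empties", {
  expect_null(maskToBox(matrix(0L, 6, 6)))
  for (b in allBoxes(4, 5)) {
    rec <- maskToBox(boxToMask(b, c(4L, 5L)))
    expect_equal(boxCoords(rec), boxCoords(b))
  }
  # filled disk of radius 3 at (10,10): brute-force min/max over foreground
  m <- matrix(0L, 20, 20)
  for (r in 0:19) for (c in 0:19)
    if ((r - 10)^2 + (c - 10)^2 <= 9) m[r + 1, c + 1] <- 1L
  expect_equal(unname(boxCoords(maskToBox(m))), c(7, 7, 14, 14))
})

test_that("mask pipeline equals closed-form boxes for flips and translations
           exhaustively on small canvases", {
  policy <- keepPolicy(1e-6)  # isolate geometry from the keep policy
  for (canvas in list(c(5L, 7L), c(8L, 8L), c(12L, 10L))) {
    H <- canvas[1]; W <- canvas[2]
    img <- randomImage(H, W, seed = H * W)
    for (b in allBoxes(H, W)) {
      # horizontal flip: (x1, y1, x2, y2) -> (W - x2, y1, W - x1, y2)
      r <- augmentLocalization(img, b, makeTechnique("flip"), policy)
      expect_equal(unname(boxCoords(r$box)),
                   c(W - b@xmax, b@ymin, W - b@xmin, b@ymax))
      # vertical flip mirrors rows
      r <- augmentLocalization(img, b,
                               makeTechnique("flip", list(mode = "vertical")),
                               policy)
      expect_equal(unname(boxCoords(r$box)),
                   c(b@xmin, H - b@ymax, b@xmax, H - b@ymin))
      # integer translation: shifted box clipped to the canvas
      dx <- 2; dy <- -1
      r <- augmentLocalization(img, b,
                               makeTechnique("translation",
                                             list(dx = dx, dy = dy)), policy)
      xlo <- max(0, b@xmin + dx); xhi <- min(W, b@xmax + dx)
      ylo <- max(0, b@ymin + dy); yhi <- min(H, b@ymax + dy)
      if (xhi <= xlo || yhi <= ylo) {
        expect_null(r)
      } else {
        expect_equal(unname(boxCoords(r$box)), c(xlo, ylo, xhi, yhi))
      }
    }
  }
})

test_that("translation pushing the box off-canvas discards the example", {
  img <- randomImage(10, 10, seed = 1)
  b <- boundingBox(1, 1, 4, 4)
  expect_null(augmentLocalization(img, b,
    makeTechnique("translation", list(dx = 20, dy = 0))))
})

test_that("position-invariant techniques leave every annotation type
           bitwise unchanged", {
  sc <- twoBlobScene()
  invariants <- listTechniques()$name[!listTechniques()$name %in%
                                      expectedPositionVariant]
  for (nm in invariants) {
    tech <- makeTechnique(nm, seed = 3)
    r <- augmentLocalization(sc$image, sc$boxes[[1]], tech)
    expect_identical(boxCoords(r$box), boxCoords(sc$boxes[[1]]))
    r <- augmentDetection(sc$image, sc$boxes, tech)
    expect_identical(lapply(r$boxes, boxCoords), lapply(sc$boxes, boxCoords))
    r <- augmentSemantic(sc$image, sc$mask, tech)
    expect_identical(maskLabels(r$mask), maskLabels(sc$mask))
    r <- augmentInstance(sc$image, sc$instances, tech)
    expect_identical(instanceMasks(r$instances), instanceMasks(sc$instances))
  }
})

test_that("detection drops boxes individually and discards only when none
           survive", {
  sc <- twoBlobScene()
  # translate so blob b (near origin) leaves the canvas but blob a stays
  tech <- makeTechnique("translation", list(dx = -6, dy = -6))
  r <- augmentDetection(sc$image, sc$boxes, tech, keepPolicy(0.9))
  expect_equal(length(r$boxes), 1)
  expect_equal(boxLabel(r$boxes[[1]]), "a")
  # a translation that removes everything discards the example
  expect_null(augmentDetection(sc$image, sc$boxes,
                               makeTechnique("translation", list(dx = 25, dy = 0))))
  expect_null(augmentDetection(sc$image, list(), makeTechnique("flip")))
})

test_that("raising the keep threshold never increases survivors", {
  sc <- twoBlobScene()
  tech <- makeTechnique("translation", list(dx = -4, dy = 0))
  survivors <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0), function(f) {
    r <- augmentDetection(sc$image, sc$boxes, tech, keepPolicy(f))
    if (is.null(r)) 0L else length(r$boxes)
  }, 0L)
  expect_true(all(diff(survivors) <= 0))
})

test_that("semantic warps conserve the label-code set and follow the image", {
  sc <- twoBlobScene()
  codes <- unique(as.vector(maskLabels(sc$mask)))
  for (spec in list(list("translation", list(dx = 3, dy = 0)),
                    list("rotation", list(angle = 90)),
                    list("rotation", list(angle = 28)),
                    list("elastic-deformation", list(alpha = 3, sigma = 2)))) {
    tech <- makeTechnique(spec[[1]], spec[[2]], seed = 2)
    r <- augmentSemantic(sc$image, sc$mask, tech)
    expect_true(all(unique(as.vector(maskLabels(r$mask))) %in% c(codes, 0L)))
  }
  # 90-degree rotation: mask follows the exact index permutation of the image
  r <- augmentSemantic(sc$image, sc$mask, makeTechnique("rotation", list(angle = 90)))
  n <- 20
  expected <- matrix(0L, n, n)
  for (a in 0:(n - 1)) for (b in 0:(n - 1))
    expected[b + 1, n - a] <- maskLabels(sc$mask)[a + 1, b + 1]
  expect_identical(maskLabels(r$mask), expected)
  expect_error(augmentSemantic(sc$image, semanticMask(matrix(0L, 5, 5)),
                               makeTechnique("flip")), "shape")
})

test_that("instance propagation preserves counts under flips and drops
           cropped-out instances", {
  sc <- twoBlobScene()
  r <- augmentInstance(sc$image, sc$instances,
                       makeTechnique("flip", list(mode = "vertical")))
  expect_equal(nInstances(r$instances), nInstances(sc$instances))
  expect_equal(vapply(instanceMasks(r$instances), sum, 0),
               vapply(instanceMasks(sc$instances), sum, 0))
  # central crop keeps the central blob only
  r <- augmentInstance(sc$image, sc$instances,
                       makeTechnique("crop", list(fraction = 0.4)))
  expect_equal(nInstances(r$instances), 1)
  expect_equal(instanceLabels(r$instances), "a")
  # invariant techniques keep masks bitwise
  r <- augmentInstance(sc$image, sc$instances, makeTechnique("brightness"))
  expect_identical(instanceMasks(r$instances), instanceMasks(sc$instances))
})

test_that("classification propagation applies the label function f", {
  img <- randomImage(8, 8, seed = 1)
  r <- augmentClassification(img, "left", makeTechnique("rotation", list(angle = 90)))
  expect_equal(r$label, "left")  # identity f
  f <- labelMap(c(left = "right", right = "left"))
  r <- augmentClassification(img, "left", makeTechnique("flip"), f)
  expect_equal(r$label, "right")
  r <- augmentClassification(img, "up", makeTechnique("flip"), f)
  expect_equal(r$label, "up")  # outside the map: identity
})

test_that("stack augmentation shares one geometric plan across frames", {
  frames <- lapply(1:5, function(i) randomImage(16, 16, seed = i))
  r <- augmentStack(frames, "classA", makeTechnique("rotation", list(angle = 90)),
                    "stack_classification")
  expect_equal(length(r$frames), 5)
  # frame order preserved; each frame equals the direct per-frame warp
  plan <- resolveGeometry(makeTechnique("rotation", list(angle = 90)), c(16L, 16L))
  for (i in 1:5)
    expect_identical(r$frames[[i]], applyGeometric(plan, frames[[i]], "smooth"))
  # one elastic displacement field for the whole stack: warping a shared
  # calibration raster through each frame slot gives identical results
  calib <- randomImage(16, 16, seed = 99)
  tech <- makeTechnique("elastic-deformation", list(alpha = 4, sigma = 2), seed = 5)
  r <- augmentStack(rep(list(calib), 3), "classA", tech, "stack_classification")
  expect_identical(r$frames[[1]], r$frames[[2]])
  expect_identical(r$frames[[2]], r$frames[[3]])
  planE <- resolveGeometry(tech, c(16L, 16L))
  expect_identical(r$frames[[1]], applyGeometric(planE, calib, "smooth"))
  expect_error(augmentStack(list(randomImage(4, 4), randomImage(5, 5)), "x",
                            makeTechnique("flip"), "stack_classification"),
               "share one shape")
})

test_that("stack segmentation and detection propagate frame annotations
           consistently", {
  sc <- twoBlobScene()
  frames <- rep(list(sc$image), 3)
  masks <- rep(list(sc$mask), 3)
  r <- augmentStack(frames, masks, makeTechnique("flip"), "stack_segmentation")
  single <- augmentSemantic(sc$image, sc$mask, makeTechnique("flip"))
  for (i in 1:3) {
    expect_identical(r$frames[[i]], single$image)
    expect_identical(maskLabels(r$annotation[[i]]), maskLabels(single$mask))
  }
  rd <- augmentStack(frames, rep(list(sc$boxes), 3), makeTechnique("flip"),
                     "stack_detection")
  singleD <- augmentDetection(sc$image, sc$boxes, makeTechnique("flip"))
  for (i in 1:3)
    expect_identical(lapply(rd$annotation[[i]], boxCoords),
                     lapply(singleD$boxes, boxCoords))
})
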