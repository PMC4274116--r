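test_that("feature bank has 16 documented channels on the frame grid", {
  mv <- wrappedScene(1)
  st <- computePixelStatistics(mv[[1]])
  expect_equal(dim(st), c(128, 128, 16))
  expect_identical(dimnames(st)[[3]], unwrapChannelNames())
  expect_true(all(is.finite(st)))
})

test_that("constant frames give zero edge/texture response", {
  f <- PhaseFrame(matrix(7, 32, 32), intensity = matrix(3, 32, 32))
  st <- computePixelStatistics(f)
  for (ch in c("sobel_x", "sobel_y", "sobel_mag", "laplacian",
               "local_range_3", "median3_residual", "morph_gradient",
               "intensity_sobel_mag"))
    expect_true(all(st[, , ch] == 0), label = ch)
  ## variance-based channels are zero up to floating-point cancellation
  for (ch in c("phase_quality", "local_sd_3", "local_sd_7"))
    expect_lt(max(st[, , ch]), 1e-6)
  expect_true(all(st[, , "wrap_proximity"] == 530 - 7))
})

test_that("edge-magnitude channels peak along a step edge", {
  o <- matrix(0, 32, 32); o[, 17:32] <- 50
  f <- PhaseFrame(o, intensity = matrix(1, 32, 32))
  st <- computePixelStatistics(f)
  sm <- st[, , "sobel_mag"]
  ## analytic Sobel response to a step of height h is 4h on the two
  ## columns adjacent to the step, zero away from it
  expect_equal(unique(as.vector(sm[, 16:17])), 4 * 50)
  expect_true(all(sm[, c(1:14, 19:32)] == 0))
})

test_that("non-finite pixels are reported with coordinates", {
  o <- matrix(0, 8, 8); o[3, 5] <- NA
  f <- PhaseFrame(matrix(0, 8, 8), intensity = matrix(1, 8, 8))
  methods::slot(f, "opd", check = FALSE) <- o  # bypass class validity
  expect_error(computePixelStatistics(f), "row 3, col 5")
})

test_that("training rejects single-class labels", {
  mv <- wrappedScene(2)
  st <- computePixelStatistics(mv[[1]])
  expect_error(
    trainUnwrapModel(st, matrix(FALSE, 128, 128)), "single class")
})

test_that("training separates a linearly separable pixel set perfectly", {
  ## two classes split by the opd channel alone
  set.seed(4)
  o <- matrix(runif(32 * 32, 0, 100), 32, 32)
  lab <- o > 50
  o[lab] <- o[lab] + 200
  f <- PhaseFrame(o, intensity = matrix(1, 32, 32))
  st <- computePixelStatistics(f)
  m <- suppressWarnings(trainUnwrapModel(st, lab, seed = 1))
  sc <- scoreWrapPixels(f, m)
  expect_equal(mean((sc > m@threshold) == lab), 1)
})

test_that("swapping the class labels leaves the decisions unchanged", {
  mv <- wrappedScene(3)
  st <- computePixelStatistics(mv[[1]])
  lab <- groundTruth(mv)$wrapMasks[[1]]
  m1 <- suppressWarnings(trainUnwrapModel(st, lab, seed = 2))
  m2 <- suppressWarnings(trainUnwrapModel(st, !lab, seed = 2))
  ## the discriminant direction is the same up to sign; after the
  ## positive-class orientation step the decisions coincide
  ratio <- m2@weights[m1@weights != 0] / m1@weights[m1@weights != 0]
  expect_lt(stats::sd(ratio) / abs(mean(ratio)), 1e-6)
  sc1 <- scoreWrapPixels(mv[[1]], m1)
  sc2 <- scoreWrapPixels(mv[[1]], m2)
  expect_identical(sc1 > m1@threshold, !(sc2 > m2@threshold))
})

test_that("wrap-region pixels of a held-out frame are recalled", {
  model <- trainedUnwrapModel()
  mv <- wrappedScene(201)
  truth <- groundTruth(mv)$wrapMasks[[1]]
  sc <- scoreWrapPixels(mv[[1]], model)
  expect_gte(mean(sc[truth] > model@threshold), 0.9)
})

test_that("detection is empty (with a warning) on unwrapped frames", {
  model <- trainedUnwrapModel()
  scn <- cellScenario("f", center = c(64, 64), initialMass = 300)
  mv <- simulateMovie(scn, frames = 1, dim = c(128, 128), seed = 9)
  expect_warning(mask <- detectWrapRegions(mv[[1]], model),
                 "empty correction mask")
  expect_false(any(mask))
})

test_that("detected masks overlap the ledger wrap masks", {
  model <- trainedUnwrapModel()
  for (s in 201:203) {
    mv <- wrappedScene(s)
    truth <- groundTruth(mv)$wrapMasks[[1]]
    mask <- suppressWarnings(detectWrapRegions(mv[[1]], model))
    iou <- sum(mask & truth) / sum(mask | truth)
    expect_gte(iou, 0.9)
  }
})

test_that("two wrapped cells give two disjoint mask components", {
  set.seed(42)
  mk <- function(ctr, id) cellScenario(id, center = ctr,
    initialMass = 400, tEntryMid = -20, tFurrow = 200,
    tExitMid = c(220, 220))
  mv <- simulateMovie(list(mk(c(40, 40), "a"), mk(c(88, 88), "b")),
                      frames = 1, dim = c(128, 128), seed = 42,
                      noiseSd = 0, wrap = TRUE)
  model <- trainedUnwrapModel()
  mask <- suppressWarnings(detectWrapRegions(mv[[1]], model))
  comp <- EBImage::bwlabel(EBImage::Image(mask * 1))
  expect_equal(max(comp), 2)
})

test_that("correction adds exactly one wavelength inside the mask only", {
  f <- PhaseFrame(matrix(c(70, 400, 10, 0), 2, 2), wavelength = 530)
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  out <- correctPhase(f, mask)
  expect_equal(opd(out)[1, 1], 600)           # inverse of wrapping
  expect_identical(opd(out)[-1], opd(f)[-1])  # nothing else altered
  ## empty mask is the identity
  same <- correctPhase(f, matrix(FALSE, 2, 2))
  expect_identical(opd(same), opd(f))
  ## corrections are positive: mass can only grow
  expect_gte(sum(opd(out)), sum(opd(f)))
})

test_that("models serialize to JSON and back", {
  model <- trainedUnwrapModel()
  path <- withr::local_tempfile(fileext = ".json")
  writeUnwrapModel(model, path)
  back <- readUnwrapModel(path)
  expect_equal(back@weights, model@weights)
  expect_equal(back@threshold, model@threshold)
  expect_identical(back@channels, model@channels)
})
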