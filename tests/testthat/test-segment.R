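test_that("region masses follow the closed-form refractive-increment law",
{
  ## uniform disk: exactly 100 px of 100 nm in a 1 um/px frame
  o <- matrix(0, 40, 40)
  pick <- order(as.vector(
    outer((1:40 - 20.5)^2, (1:40 - 20.5)^2, "+")))[1:100]
  o[pick] <- 100
  f <- PhaseFrame(o)
  lab <- matrix(0L, 40, 40); lab[pick] <- 1L
  rg <- measureRegions(lab, f)
  expect_equal(rg$mass_pg, 55.5556, tolerance = 1e-4)
  expect_equal(rg$area_um2, 100)
  expect_equal(rg$mean_phase_nm, 100)
})

test_that("mass scales linearly with OPD", {
  mv <- divisionMovie(5, noiseSd = 0, frames = 1)
  f <- mv[[1]]
  lab <- segmentCells(f)
  m1 <- measureRegions(lab, f)$mass_pg
  f3 <- PhaseFrame(opd(f) * 3, pixelSize = pixelSize(f))
  m3 <- measureRegions(lab, f3)$mass_pg
  expect_equal(m3, 3 * m1, tolerance = 1e-12)
})

test_that("shape factor is near 1 for disks and pi/4 for squares", {
  mk <- function(mask) {
    f <- PhaseFrame(mask * 100)
    measureRegions(ifelse(mask, 1L, 0L), f)$shape_factor
  }
  n <- 120
  g <- outer((1:n - n / 2)^2, (1:n - n / 2)^2, "+")
  circle <- matrix(g <= 40^2, n, n)
  expect_gt(mk(circle), 0.85)
  expect_lt(mk(circle), 1.1)
  square <- matrix(FALSE, n, n); square[11:110, 11:110] <- TRUE
  expect_equal(mk(square), pi / 4, tolerance = 0.03)
})

test_that("segmentation finds separated cells and splits touching pairs",
{
  scns <- list(cellScenario("a", center = c(30, 30), initialMass = 300),
               cellScenario("b", center = c(85, 85), initialMass = 420))
  mv <- simulateMovie(scns, frames = 1, dim = c(120, 120), seed = 3)
  lab <- segmentCells(mv[[1]])
  expect_equal(max(lab), 2)

  ## daughter pair separated at the saddle
  dmv <- divisionMovie(6, noiseSd = 0)
  k <- groundTruth(dmv)$events$furrow_frame
  lab2 <- segmentCells(dmv[[k]])
  expect_equal(max(lab2), 2)

  ## empty frame: no labels, no error
  expect_equal(max(segmentCells(PhaseFrame(matrix(0, 64, 64)))), 0)
  noise <- PhaseFrame(matrix(rnorm(64^2, 0, 3), 64, 64))
  expect_equal(max(segmentCells(noise)), 0)
})

test_that("watershed split conserves the pair mass within 2%", {
  mv <- divisionMovie(7, noiseSd = 0)
  gt <- groundTruth(mv)
  k <- gt$events$furrow_frame
  f <- mv[[k]]
  rg <- measureRegions(segmentCells(f), f)
  expect_equal(nrow(rg), 2)
  truthPair <- sum(gt$masses$mass_pg[gt$masses$frame == k])
  expect_lt(abs(sum(rg$mass_pg) - truthPair) / truthPair, 0.02)
})

test_that("total segmented mass matches the ledger within 2% (noiseless)",
{
  scns <- list(cellScenario("a", center = c(30, 30), initialMass = 300),
               cellScenario("b", center = c(85, 85), initialMass = 420,
                            tEntryMid = -10))  # one flat, one rounded
  mv <- simulateMovie(scns, frames = 1, dim = c(120, 120), seed = 3,
                      noiseSd = 0)
  f <- mv[[1]]
  rg <- measureRegions(segmentCells(f), f)
  truth <- sum(groundTruth(mv)$masses$mass_pg)
  expect_lt(abs(sum(rg$mass_pg) - truth) / truth, 0.02)
})

test_that("confluence is the covered-area percentage", {
  expect_equal(computeConfluence(matrix(0L, 10, 10)), 0)
  expect_equal(computeConfluence(matrix(1L, 10, 10)), 100)
  lab <- matrix(0L, 240, 320); lab[seq_len(7680)] <- 1L
  expect_equal(computeConfluence(lab), 10)
})
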