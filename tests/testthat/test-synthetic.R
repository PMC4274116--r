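test_that("rendered mass equals the closed-form OPD integral", {
  ## uniform 100 um^2 disk at 100 nm: closed form gives 55.6 pg
  o <- matrix(0, 64, 64)
  expect_equal(opdSumToMassPg(100 * 100), 55.5556, tolerance = 1e-4)

  ## renderDiskFrame normalizes the discrete integral exactly
  f <- renderDiskFrame(55.6, radiusUm = 5.64, dim = c(64, 64))
  expect_equal(opdSumToMassPg(sum(opd(f))), 55.6, tolerance = 1e-10)

  ## mass 0 -> all-zero patch
  f0 <- renderDiskFrame(0, radiusUm = 5, dim = c(32, 32))
  expect_true(all(opd(f0) == 0))

  ## a rendered scenario recovers its ledger mass within 0.1%
  scn <- cellScenario("a", center = c(40, 40), initialMass = 321.5)
  patch <- renderCell(scn, 0, dim = c(80, 80))
  expect_equal(opdSumToMassPg(sum(patch)), 321.5, tolerance = 1e-3)
})

test_that("rounding preserves integrated OPD and raises the peak", {
  flat <- cellScenario("a", center = c(40, 40), initialMass = 300,
                       growthRate = 0)
  round <- cellScenario("a", center = c(40, 40), initialMass = 300,
                        growthRate = 0, tEntryMid = -50)
  pf <- renderCell(flat, 0, dim = c(80, 80))
  pr <- renderCell(round, 0, dim = c(80, 80))
  expect_equal(sum(pf), sum(pr), tolerance = 1e-10)
  expect_gt(max(pr), max(pf))
  expect_lt(sum(pr > 1), sum(pf > 1))   # smaller footprint when rounded
})

test_that("footprint exceeding the frame names the cell and time", {
  scn <- cellScenario("edgecase", center = c(5, 40))
  expect_error(renderCell(scn, 0, dim = c(80, 80)), "edgecase")
})

test_that("ledger delta-m matches hand computation of the split", {
  ## f = 0.75, no redistribution: delta m = 2|0.75 - 0.25| = 1.0
  scn <- cellScenario("a", tFurrow = 0, tEntryMid = -30,
                      tExitMid = c(25, 25), splitFraction = 0.75,
                      growthRate = 0)
  d <- trueDeltaMSeries(scn, seq(0, 30, 3))
  expect_equal(d$delta_m_abs, rep(1.0, 11))

  ## symmetric split: zero for all t >= 0
  s2 <- cellScenario("a", tFurrow = 0, tEntryMid = -30,
                     tExitMid = c(25, 25), splitFraction = 0.5,
                     growthRate = 0)
  expect_equal(trueDeltaMSeries(s2, seq(0, 30, 3))$delta_m_signed,
               rep(0, 11))
})

test_that("redistribution transfers mass linearly and conserves the pair",
{
  scn <- cellScenario("a", tFurrow = 0, tEntryMid = -30,
                      tExitMid = c(25, 25), splitFraction = 0.5,
                      redistributionRate = 0.002,
                      redistributionDuration = 30, growthRate = 0.3)
  tt <- seq(0, 60, 3)
  d <- trueDeltaMSeries(scn, tt)
  ## pair total = furrow mass + accumulated growth at every frame
  expect_equal(d$m_d1 + d$m_d2, scn@initialMass + 0.3 * tt,
               tolerance = 1e-12)
  ## transfer is linear up to the stated duration, then stops
  expect_equal(diff(d$m_d1[1:10] - 0.15 * tt[1:10]),
               rep(0.002 * 350 * 3, 9), tolerance = 1e-10)
  ## after the transfer window the mass difference stays frozen
  expect_equal(d$m_d1[12] - d$m_d2[12], d$m_d1[21] - d$m_d2[21],
               tolerance = 1e-10)
})

test_that("movies are seed-deterministic and ledgers noise-independent", {
  scn <- cellScenario("a", center = c(40, 40))
  m1 <- simulateMovie(scn, frames = 3, dim = c(80, 80), seed = 11)
  m2 <- simulateMovie(scn, frames = 3, dim = c(80, 80), seed = 11)
  m3 <- simulateMovie(scn, frames = 3, dim = c(80, 80), seed = 12)
  expect_identical(opd(m1[[2]]), opd(m2[[2]]))
  expect_false(identical(opd(m1[[2]]), opd(m3[[2]])))
  ## noiseless: ledgers and movies identical across seeds
  n1 <- simulateMovie(scn, frames = 3, dim = c(80, 80), seed = 11,
                      noiseSd = 0)
  n2 <- simulateMovie(scn, frames = 3, dim = c(80, 80), seed = 99,
                      noiseSd = 0)
  expect_identical(groundTruth(n1)$masses, groundTruth(n2)$masses)
  expect_identical(opd(n1[[3]]), opd(n2[[3]]))
})

test_that("total ledger mass equals the integrated OPD volume per frame", {
  scns <- list(cellScenario("a", center = c(30, 30), initialMass = 280),
               cellScenario("b", center = c(85, 85), initialMass = 410,
                            growthRate = 0.5))
  mv <- simulateMovie(scns, frames = 4, dim = c(120, 120), noiseSd = 0,
                      seed = 1)
  gt <- groundTruth(mv)
  for (k in 1:4) {
    truth <- sum(gt$masses$mass_pg[gt$masses$frame == k])
    expect_equal(opdSumToMassPg(sum(opd(mv[[k]]))), truth,
                 tolerance = 1e-3)
  }
})

test_that("overlapping initial placements are rejected with cell names", {
  scns <- list(cellScenario("a", center = c(40, 40)),
               cellScenario("b", center = c(50, 40)))
  expect_error(simulateMovie(scns, frames = 1, dim = c(80, 80), seed = 1),
               "overlapping.*'[ab]'.*'[ab]'")
})

test_that("phase wrapping is modular, masked, and single-wrap only", {
  f <- PhaseFrame(matrix(c(600, 400, 0, 1059), 2, 2), wavelength = 530)
  w <- applyWrapping(f)
  expect_equal(opd(w$frame)[1, 1], 70)      # 600 mod 530
  expect_equal(opd(w$frame)[2, 1], 400)     # untouched
  expect_identical(w$mask, matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  ## all-zero frame unchanged, empty mask
  z <- applyWrapping(PhaseFrame(matrix(0, 4, 4)))
  expect_true(all(opd(z$frame) == 0) && !any(z$mask))
  ## >= 2 wavelengths is outside the correction regime
  expect_error(applyWrapping(PhaseFrame(matrix(1060, 1, 1),
                                        wavelength = 530)),
               "two wavelengths")
})

test_that("wrapped movies keep lobes separated by an OPD saddle", {
  mv <- divisionMovie(3, noiseSd = 0)
  gt <- groundTruth(mv)
  k <- gt$events$furrow_frame
  o <- opd(mv[[k]])
  st <- massdivide:::.scenarioState(gt$scenarios[[1]], frameTime(mv[[k]]))
  c1 <- st[[1]]$center; c2 <- st[[2]]$center
  mid <- (c1 + c2) / 2
  peak1 <- o[round(c1[2]) + 1, round(c1[1]) + 1]
  saddle <- o[round(mid[2]) + 1, round(mid[1]) + 1]
  expect_lt(saddle, 0.8 * peak1)
  expect_gt(saddle, 0)
})
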