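test_that("sigmoid matched filter finds midpoints and ignores flat traces",
{
  tt <- seq(0, 300, 3)
  ## flat trace: nothing
  expect_equal(nrow(fitSigmoidTrace(tt, rep(80, length(tt)), "rising")), 0)
  ## ideal rising sigmoid with midpoint at frame 40 (t = 117)
  v <- 100 + 300 / (1 + exp(-(tt - 117) / 6))
  fits <- fitSigmoidTrace(tt, v, "rising")
  expect_equal(nrow(fits), 1)
  expect_lte(abs(fits$midpoint - 117), 3)   # within one frame
  expect_gt(fits$amplitude, 20)
  ## orientation contract: a falling sigmoid matches only direction =
  ## falling
  vf <- 100 + 300 / (1 + exp((tt - 117) / 6))
  expect_equal(nrow(fitSigmoidTrace(tt, vf, "rising")), 0)
  expect_equal(nrow(fitSigmoidTrace(tt, vf, "falling")), 1)
  ## trace shorter than the window: empty result
  expect_equal(nrow(fitSigmoidTrace(tt[1:10], v[1:10], "rising")), 0)
})

test_that("a clean adherent division yields exactly one event at the ledger furrow",
{
  mv <- divisionMovie(21)
  out <- runMovie(mv, "adherent")
  gt <- groundTruth(mv)
  expect_equal(nrow(out$events), 1)
  expect_equal(out$events$furrow_frame, gt$events$furrow_frame)
  expect_equal(out$events$t_furrow_min, gt$events$t_furrow)
  ## relative-mass normalization: daughters sum close to the parent
  parentLast <- out$tracks[out$tracks$track_id ==
                             out$events$parent_track, ]
  parentMass <- parentLast$mass_pg[which.max(parentLast$frame)]
  rel <- (out$events$m_d1_pg + out$events$m_d2_pg) / parentMass
  expect_gt(rel, 0.8); expect_lt(rel, 1.2)
})

test_that("rounding without division yields no event", {
  mv <- simulateMovie(growthScenario(rounds = TRUE), frames = 48,
                      dim = c(72, 72), seed = 22)
  out <- runMovie(mv, "adherent")
  expect_equal(nrow(out$events), 0)
})

test_that("a parent with a single successor fails criterion 1 and is logged",
{
  ## tracks table built by hand: one track ends, one begins nearby
  tr <- data.frame(
    track_id = c(1, 1, 1, 2, 2, 2),
    frame = c(1, 2, 3, 4, 5, 6),
    t_min = c(0, 3, 6, 9, 12, 15),
    label = 1, mass_pg = c(400, 401, 402, 200, 201, 202),
    area_um2 = 500, perimeter_px = 80, mean_phase_nm = 100,
    shape_factor = 0.9, x_um = 40, y_um = 40)
  ev <- detectDivisions(tr, "nonadherent", edgeFrames = 0)
  expect_equal(nrow(ev), 0)
  log <- attr(ev, "log")
  expect_match(log$reason[log$parent_track == 1], "criterion1")
})

test_that("non-adherent splits are detected by the mass criterion alone",
{
  nonadh <- function(f) cellScenario("n", center = c(30, 30),
    initialMass = 300, growthRate = 0, adherent = FALSE,
    flatRadius = 10, roundRadius = 5, tFurrow = 9, splitFraction = f)
  mkTracks <- function(f) {
    mv <- simulateMovie(nonadh(f), frames = 10, interval = 3,
                        dim = c(60, 60), seed = 30, noiseSd = 1)
    runMovie(mv, "nonadherent")
  }
  out <- mkTracks(0.5)
  expect_equal(nrow(out$events), 1)
  ## entry/exit undefined for non-adherent events
  times <- measureDivisionTimes(out$events)
  expect_false(times$defined)
  expect_true(is.na(times$time_in_mitosis))

  ## a 0.8/0.2 split falls outside the daughter-mass window
  out2 <- mkTracks(0.8)
  expect_equal(nrow(out2$events), 0)
  expect_match(attr(out2$events, "log")$reason, "criterion1",
               all = FALSE)

  ## no splits at all -> empty list
  mv3 <- simulateMovie(cellScenario("n", center = c(30, 30),
                                    adherent = FALSE, flatRadius = 10,
                                    roundRadius = 5),
                       frames = 5, dim = c(60, 60), seed = 31)
  expect_equal(nrow(runMovie(mv3, "nonadherent")$events), 0)
})

test_that("mitotic timing matches the programmed entry and exit midpoints",
{
  mv <- divisionMovie(23, noiseSd = 1)
  out <- runMovie(mv, "adherent")
  expect_equal(nrow(out$events), 1)
  times <- measureDivisionTimes(out$events)
  ## programmed: entry 30 min before furrow, exits 25 min after
  expect_lte(abs(times$time_in_mitosis - 30), 3.01)
  expect_lte(abs(times$time_rounded_post - 25), 3.01)
  ## simultaneous daughter flattening: post time equals either exit
  expect_equal(out$events$exit_mid_min_d1, out$events$exit_mid_min_d2,
               tolerance = 3)
})

test_that("delta-m series starts non-negative with d1 the heavier daughter",
{
  mv <- divisionMovie(24, f = 0.42)   # daughter 2 of the split is heavier
  out <- runMovie(mv, "adherent")
  s <- deltaMSeries(out$events[1, ], out$tracks)
  expect_gte(s$delta_m_signed[1], 0)
  expect_equal(s$time_rel[1], 0)
  expect_true(all(s$delta_m_abs <= 2))
})
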