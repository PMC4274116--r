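test_that("delta-m matches hand computations and its bounds", {
  expect_equal(deltaM(200, 200), 0)
  expect_equal(deltaM(300, 100), 1.0)        # 2*200/400
  expect_equal(deltaM(5, 0), 2.0)            # upper bound
  expect_equal(deltaM(100, 300, signed = TRUE), -1.0)
  expect_error(deltaM(0, 0), "positive")
})

test_that("delta-m is invariant under mass rescaling", {
  set.seed(40)
  for (i in 1:20) {
    m1 <- runif(1, 50, 500); m2 <- runif(1, 50, 500)
    k <- runif(1, 0.01, 100)
    expect_equal(deltaM(k * m1, k * m2), deltaM(m1, m2),
                 tolerance = 1e-12)
  }
})

test_that("asymmetry dynamics recover intercept, rate and theta", {
  mkSeries <- function(dm0, r, tt = seq(0, 60, 3))
    data.frame(time = tt, time_rel = tt,
               delta_m_signed = dm0 + r * tt,
               delta_m_abs = abs(dm0 + r * tt))
  ## constant series: r = 0, theta = atan2(0, dm0) = 0
  rec <- asymmetryDynamics(mkSeries(0.3, 0))
  expect_equal(rec$rate, 0, tolerance = 1e-12)
  expect_equal(rec$theta, 0)
  ## pure growth from zero: theta = pi/2
  rec2 <- asymmetryDynamics(mkSeries(0, 0.02 / 60))
  expect_equal(rec2$theta, pi / 2)
  ## fewer than 3 post-furrow frames: flagged unusable
  rec3 <- asymmetryDynamics(mkSeries(0.3, 0, tt = c(0, 3)))
  expect_false(rec3$usable)

  ## programmed redistribution: sign of the measured rate matches
  for (rho in c(-0.001, 0.001)) {
    scn <- cellScenario("a", tFurrow = 0, tEntryMid = -30,
                        tExitMid = c(25, 25), splitFraction = 0.6,
                        redistributionRate = rho, growthRate = 0)
    d <- trueDeltaMSeries(scn, seq(0, 30, 3))
    rec <- asymmetryDynamics(d, horizon = 30)
    expect_equal(sign(rec$rate), sign(rho))
  }
})

test_that("event ordering by theta is descending and shuffle-stable", {
  rec <- data.frame(event_id = 1:3, theta = c(pi / 2, 0, -pi / 4),
                    usable = TRUE)
  expect_equal(orderEvents(rec), 1:3)
  shuffled <- rec[c(3, 1, 2), ]
  expect_equal(shuffled$event_id[orderEvents(shuffled)], 1:3)
  ## ties break on event id
  tied <- data.frame(event_id = c(7, 3), theta = c(0.5, 0.5),
                     usable = TRUE)
  expect_equal(tied$event_id[orderEvents(tied)], c(3, 7))
})

test_that("population curves: symmetric events average to zero, CV by hand",
{
  sym <- lapply(1:3, function(i)
    data.frame(time = seq(0, 30, 3), time_rel = seq(0, 30, 3),
               delta_m_signed = 0, delta_m_abs = 0))
  pc <- populationCurves(sym)
  expect_true(all(pc$asymmetry$mean_abs_dm == 0))

  ## masses {9, 11} in one bin: CV = sd/mean = 1.414/10
  expect_equal(coefficientOfVariation(c(9, 11)), sqrt(2) / 10,
               tolerance = 1e-12)
  ms <- data.frame(time_rel = c(5, 6, 25, 26), mass = c(9, 11, 10, 10),
                   track = c(1, 2, 1, 2))
  pc2 <- populationCurves(sym, massSamples = ms)
  expect_equal(pc2$cv$cv[pc2$cv$t_mid == 5], sqrt(2) / 10,
               tolerance = 1e-12)
  expect_equal(pc2$cv$cv[pc2$cv$t_mid == 25], 0)
})

test_that("heatmap rows follow the event ordering", {
  mk <- function(id, dm0, r) {
    tt <- seq(0, 30, 3)
    list(series = data.frame(time = tt, time_rel = tt,
                             delta_m_signed = dm0 + r * tt,
                             delta_m_abs = abs(dm0 + r * tt)),
         rec = asymmetryDynamics(
           data.frame(time = tt, time_rel = tt,
                      delta_m_signed = dm0 + r * tt,
                      delta_m_abs = abs(dm0 + r * tt)), eventId = id))
  }
  evs <- list(mk(1, 0.4, -0.004), mk(2, 0.02, 0.004), mk(3, 0.4, 0))
  H <- heatmapMatrix(lapply(evs, `[[`, "series"),
                     do.call(rbind, lapply(evs, `[[`, "rec")))
  expect_equal(rownames(H), c("2", "3", "1"))   # descending theta
  expect_equal(unname(H["1", 1]), 0.4)
})

test_that("Welch t test matches an independent hand computation", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  got <- welchTTest(a, b)
  oracle <- welchOracle(a, b)
  expect_equal(got$statistic, oracle$statistic, tolerance = 1e-10)
  expect_equal(got$df, oracle$df, tolerance = 1e-10)
  expect_equal(got$p.value, oracle$p.value, tolerance = 1e-10)
  ## symmetry: swapping samples negates t, keeps p
  swp <- welchTTest(b, a)
  expect_equal(swp$statistic, -got$statistic)
  expect_equal(swp$p.value, got$p.value)
  ## identical samples: t = 0, p = 1
  same <- welchTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(welchTTest(1, c(1, 2)), "at least 2")

  ## random samples against the oracle
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1), 0.5, 2)
    g <- welchTTest(x, y); o <- welchOracle(x, y)
    expect_equal(g$p.value, o$p.value, tolerance = 1e-10)
  }
})

test_that("regression F test matches its algebraic identities", {
  ## constant y: slope 0, p = 1
  flat <- regressionFTest(1:10, rep(4, 10))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p.value, 1)
  ## exact line: p = 0
  exact <- regressionFTest(1:10, 2 * (1:10))
  expect_equal(exact$slope, 2)
  expect_equal(exact$p.value, 0)
  ## F equals the squared t statistic of the slope
  set.seed(42)
  x <- seq(0, 10, length.out = 50)
  y <- 1 + 0.3 * x + rnorm(50)
  got <- regressionFTest(x, y)
  tstat <- summary(stats::lm(y ~ x))$coefficients[2, "t value"]
  expect_equal(got$statistic, tstat^2, tolerance = 1e-8)
  expect_error(regressionFTest(rep(1, 5), 1:5), "constant")
})
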