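## Shared fixtures: all synthetic, generated in code at test time.

## A complete adherent division movie on a small canvas. Furrow at
## frame 26 (t = 75 min); entry midpoint 30 min before the furrow,
## exits 25 min after.
divisionScenario <- function(f = 0.55, rho = 0, id = "cell",
                             center = c(36, 36), mass = 350,
                             growth = 0.2, tFurrow = 75) {
  cellScenario(id, initialMass = mass, growthRate = growth,
               center = center, tEntryMid = tFurrow - 30,
               tFurrow = tFurrow, tExitMid = c(tFurrow + 25, tFurrow + 25),
               splitFraction = f, redistributionRate = rho)
}

divisionMovie <- function(seed, f = 0.55, noiseSd = 3, frames = 48,
                          dim = c(72, 72), ...) {
  simulateMovie(divisionScenario(f = f, ...), frames = frames,
                interval = 3, noiseSd = noiseSd, seed = seed, dim = dim)
}

## a cell that just grows (optionally rounding without dividing)
growthScenario <- function(center = c(36, 36), mass = 350,
                           rounds = FALSE) {
  cellScenario("g", initialMass = mass, growthRate = 0.2,
               center = center,
               tEntryMid = if (rounds) 75 else NA_real_)
}

segmentMovie <- function(movie, cfg = segmentationConfig()) {
  do.call(rbind, lapply(seq_len(nFrames(movie)), function(k) {
    fr <- movie[[k]]
    rg <- measureRegions(segmentCells(fr, cfg), fr, cfg)
    if (nrow(rg)) cbind(frame = k, rg) else NULL
  }))
}

runMovie <- function(movie, mode = c("adherent", "nonadherent"),
                     cfg = segmentationConfig()) {
  mode <- match.arg(mode)
  tracks <- buildTracks(segmentMovie(movie, cfg))
  events <- detectDivisions(tracks, mode)
  list(tracks = tracks, events = events)
}

## one-frame wrapped scene: a rounded (phase-wrapped) cell plus a flat
## cell, with the ledger wrap mask
wrappedScene <- function(seed, noiseSd = 3, dim = c(128, 128)) {
  set.seed(seed)
  s1 <- cellScenario("m", center = c(40, 40) + runif(2, -6, 6),
                     initialMass = runif(1, 330, 450), tEntryMid = -20,
                     tFurrow = 200, tExitMid = c(220, 220))
  s2 <- cellScenario("f", center = c(88, 88) + runif(2, -6, 6),
                     initialMass = runif(1, 250, 350))
  simulateMovie(list(s1, s2), frames = 1, dim = dim, seed = seed,
                noiseSd = noiseSd, wrap = TRUE)
}

## train a small unwrap model once per test run (cached)
trainedUnwrapModel <- local({
  model <- NULL
  function(nFrames = 16) {
    if (!is.null(model)) return(model)
    stacks <- vector("list", nFrames)
    labels <- vector("list", nFrames)
    for (i in seq_len(nFrames)) {
      mv <- wrappedScene(i)
      stacks[[i]] <- computePixelStatistics(mv[[1]])
      labels[[i]] <- groundTruth(mv)$wrapMasks[[1]]
    }
    model <<- suppressWarnings(trainUnwrapModel(stacks, labels, seed = 5))
    model
  }
})

## brute-force minimum-cost partial matching (the linking oracle):
## enumerates every one-to-one pairing, cost = sum of squared
## displacements + maxDisp^2 per unmatched region on either side
bruteForceLink <- function(regionsA, regionsB, maxDisp = 20) {
  n <- nrow(regionsA); m <- nrow(regionsB)
  D2 <- outer(regionsA$x_um, regionsB$x_um, "-")^2 +
    outer(regionsA$y_um, regionsB$y_um, "-")^2
  best <- list(cost = Inf, pairs = NULL)
  recurse <- function(i, usedB, pairs, cost) {
    if (i > n) {
      cost <- cost + (m - sum(usedB)) * maxDisp^2
      if (cost < best$cost - 1e-12)
        best <<- list(cost = cost, pairs = pairs)
      return(invisible())
    }
    recurse(i + 1, usedB, pairs, cost + maxDisp^2)  # leave i unmatched
    for (j in seq_len(m)) {
      if (!usedB[j] && D2[i, j] <= maxDisp^2) {
        usedB[j] <- TRUE
        recurse(i + 1, usedB, rbind(pairs, c(i, j)), cost + D2[i, j])
        usedB[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, m), NULL, 0)
  best
}

## hand-computed Welch t statistic and two-sided p (independent of
## stats::t.test)
welchOracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  list(statistic = tstat, df = df,
       p.value = 2 * stats::pt(-abs(tstat), df))
}
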