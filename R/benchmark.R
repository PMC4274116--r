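#' Measure population mass-partitioning asymmetry on simulated divisions
#'
#' Simulates \code{nEvents} independent division movies whose daughter-1
#' mass fraction is drawn from a truncated normal, runs each through
#' segmentation, tracking and (non-adherent) division detection, and
#' returns the measured absolute asymmetry at the furrow frame per
#' event. With the default fraction spread (sd 0.03133) the population
#' mean of \eqn{|\Delta m_0|} is \eqn{4\sigma\sqrt{2/\pi} \approx 0.100},
#' i.e. the ~10% average mass asymmetry seen in cultured mammalian cell
#' lines.
#'
#' @param nEvents number of simulated divisions.
#' @param seed integer; event i uses seed + i for its noise field.
#' @param fMean,fSd mean and sd of the daughter-1 mass fraction.
#' @param fRange truncation bounds of the fraction.
#' @param noiseSd background noise, nm.
#' @param mass parent mass at the furrow, pg.
#' @param dim frame dimensions of each small movie.
#' @return data.frame with one row per event: f_true, delta_m0_true,
#'   delta_m0_measured (NA when the detector rejected the event),
#'   detected.
#' @examples
#' b <- partitionBenchmark(10, seed = 1)
#' mean(b$delta_m0_measured, na.rm = TRUE)
#' @export
partitionBenchmark <- function(nEvents, seed = 1L, fMean = 0.5,
                               fSd = 0.03133, fRange = c(0.01, 0.99),
                               noiseSd = 1, mass = 300,
                               dim = c(48, 48)) {
  fTrue <- .withSeed(seed, {
    f <- stats::rnorm(nEvents, fMean, fSd)
    while (any(bad <- f <= fRange[1] | f >= fRange[2]))
      f[bad] <- stats::rnorm(sum(bad), fMean, fSd)
    f
  })
  cfg <- segmentationConfig()
  center <- (dim[c(2, 1)] - 1) / 2
  out <- data.frame(f_true = fTrue,
                    delta_m0_true = 2 * abs(2 * fTrue - 1),
                    delta_m0_measured = NA_real_, detected = FALSE)
  for (i in seq_len(nEvents)) {
    scn <- cellScenario("b", initialMass = mass, growthRate = 0,
                        center = center, adherent = FALSE,
                        flatRadius = 10, roundRadius = 5,
                        tFurrow = 6, splitFraction = fTrue[i])
    mv <- simulateMovie(scn, frames = 4, interval = 3,
                        noiseSd = noiseSd, seed = seed + i, dim = dim)
    regions <- do.call(rbind, lapply(seq_len(4), function(k) {
      fr <- mv[[k]]
      rg <- measureRegions(segmentCells(fr, cfg), fr, cfg)
      if (nrow(rg)) cbind(frame = k, rg) else NULL
    }))
    tracks <- buildTracks(regions)
    ev <- detectDivisions(tracks, "nonadherent", edgeFrames = 0)
    if (nrow(ev) == 1) {
      out$delta_m0_measured[i] <- abs(ev$delta_m0_signed)
      out$detected[i] <- TRUE
    }
  }
  out
}
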