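#' Construct a CellScenario
#'
#' Programs one synthetic cell for \code{\link{simulateMovie}}. Defaults
#' describe an adherent fibroblast-like cell: ~350 pg of dry mass growing
#' at 0.3 pg/min, a flattened footprint of radius 13 um that contracts to
#' 6 um when the cell rounds up for mitosis (which pushes peak OPD above
#' one 530 nm wavelength, so wrapped movies exercise the unwrapping path).
#' A cell divides when \code{tFurrow} is finite; at the furrow the parent
#' mass splits \code{splitFraction} : 1 - \code{splitFraction} between two
#' touching daughter lobes, and \code{redistributionRate} then transfers
#' mass linearly between the connected daughters for
#' \code{redistributionDuration} minutes while conserving the pair total.
#'
#' @param id character label.
#' @param initialMass dry mass at t = 0, pg.
#' @param growthRate pg/min, may be 0.
#' @param center initial centroid (x, y), um.
#' @param drift drift velocity (x, y), um/min.
#' @param adherent logical.
#' @param flatRadius,roundRadius footprint radii, um (flat > round > 0).
#' @param transitionTau logistic time constant of rounding/flattening, min.
#' @param tEntryMid,tFurrow,tExitMid division timing, absolute minutes
#'   (NA = no division; non-adherent cells need only \code{tFurrow}).
#' @param splitFraction daughter-1 share of the parent mass at the furrow.
#' @param redistributionRate signed fraction of furrow-time parent mass
#'   per minute moved from daughter 2 to daughter 1.
#' @param redistributionDuration minutes over which the transfer runs.
#' @param daughterAxis separation axis, radians.
#' @return A \linkS4class{CellScenario}.
#' @examples
#' cellScenario("a", center = c(60, 60), tEntryMid = 30, tFurrow = 60,
#'              tExitMid = c(85, 85), splitFraction = 0.55)
#' @export
cellScenario <- function(id = "cell", initialMass = 350, growthRate = 0.3,
                         center = c(120, 160), drift = c(0, 0),
                         adherent = TRUE, flatRadius = 13, roundRadius = 6,
                         transitionTau = 6, tEntryMid = NA_real_,
                         tFurrow = NA_real_,
                         tExitMid = c(NA_real_, NA_real_),
                         splitFraction = 0.5, redistributionRate = 0,
                         redistributionDuration = 30, daughterAxis = 0) {
  if (length(tExitMid) == 1) tExitMid <- rep(tExitMid, 2)
  new("CellScenario", id = id, initialMass = initialMass,
      growthRate = growthRate, center = as.numeric(center),
      drift = as.numeric(drift), adherent = adherent,
      flatRadius = flatRadius, roundRadius = roundRadius,
      transitionTau = transitionTau, tEntryMid = tEntryMid,
      tFurrow = tFurrow, tExitMid = as.numeric(tExitMid),
      splitFraction = splitFraction,
      redistributionRate = redistributionRate,
      redistributionDuration = redistributionDuration,
      daughterAxis = daughterAxis)
}

.divides <- function(scn) is.finite(scn@tFurrow)

## center-to-center distance of the daughter lobes at the furrow, as a
## multiple of the summed lobe radii
.lobeSeparation <- 1.15

## footprint radius interpolated so that 1/R^2 (hence mean phase shift at
## constant mass) moves logistically between the flat and round states;
## s = 1 is fully rounded
.radiusFromLogistic <- function(rFlat, rRound, s) {
  1 / sqrt(1 / rFlat^2 + (1 / rRound^2 - 1 / rFlat^2) * s)
}

## Entity states (id, center, radius, mass) of one scenario at one time.
## This is the generator's analytic core: the ledger and the rendering both
## derive from it, so rendered movies and ground truth cannot disagree.
.scenarioState <- function(scn, time) {
  drifted <- scn@center + scn@drift * time
  if (!.divides(scn) || time < scn@tFurrow) {
    mass <- scn@initialMass + scn@growthRate * time
    if (scn@adherent) {
      s <- if (is.finite(scn@tEntryMid))
        .logistic((time - scn@tEntryMid) / scn@transitionTau) else 0
      ## mean phase shift scales as 1/R^2; interpolating 1/R^2
      ## logistically makes the observable mean-phase trace a logistic
      ## whose midpoint is exactly tEntryMid
      R <- .radiusFromLogistic(scn@flatRadius, scn@roundRadius, s)
    } else {
      R <- scn@roundRadius
    }
    return(list(list(id = scn@id, center = drifted, radius = R,
                     mass = mass)))
  }
  ## daughter pair
  dt <- time - scn@tFurrow
  Mf <- scn@initialMass + scn@growthRate * scn@tFurrow
  transfer <- scn@redistributionRate * Mf *
    min(dt, scn@redistributionDuration)
  m <- c(scn@splitFraction, 1 - scn@splitFraction) * Mf +
    c(transfer, -transfer) + scn@growthRate * dt / 2
  share <- m / sum(m)
  rRound <- scn@roundRadius * sqrt(share)
  if (scn@adherent) {
    s <- .logistic((time - scn@tExitMid) / scn@transitionTau)
    rFlat <- scn@flatRadius * sqrt(share)
    R <- mapply(function(rf, rr, si) .radiusFromLogistic(rf, rr, 1 - si),
                rFlat, rRound, s)
  } else {
    R <- rRound
  }
  ## touching lobes separated by an OPD saddle; the slight initial gap
  ## keeps the watershed's mass partitioning faithful to the programmed
  ## split, and the pair drifts slowly apart afterwards
  sep <- .lobeSeparation * sum(R) + 0.05 * dt
  u <- c(cos(scn@daughterAxis), sin(scn@daughterAxis))
  list(
    list(id = paste0(scn@id, "-d1"), center = drifted - u * sep / 2,
         radius = R[1], mass = m[1]),
    list(id = paste0(scn@id, "-d2"), center = drifted + u * sep / 2,
         radius = R[2], mass = m[2])
  )
}

#' Ground-truth mass and asymmetry series for a scenario
#'
#' Evaluates the generator's analytic ledger (no rendering): per-entity
#' true masses, and for dividing scenarios the true daughter mass
#' asymmetry over time. The signed asymmetry follows the convention that
#' daughter 1 is the heavier daughter at the furrow, so the signed value
#' starts non-negative.
#'
#' @param scenario a \linkS4class{CellScenario}.
#' @param times numeric vector of absolute times, min.
#' @return \code{trueMasses}: data.frame (time, cell, mass_pg).
#'   \code{trueDeltaMSeries}: data.frame (time, time_rel, m_d1, m_d2,
#'   delta_m_signed, delta_m_abs) restricted to post-furrow times
#'   (zero rows for non-dividing scenarios).
#' @examples
#' scn <- cellScenario("a", tFurrow = 0, tEntryMid = -30,
#'                     tExitMid = c(25, 25), splitFraction = 0.75,
#'                     growthRate = 0)
#' trueDeltaMSeries(scn, seq(0, 30, 3))$delta_m_abs  # constant 1.0
#' @export
trueMasses <- function(scenario, times) {
  rows <- lapply(times, function(tt) {
    st <- .scenarioState(scenario, tt)
    data.frame(time = tt,
               cell = vapply(st, `[[`, character(1), "id"),
               mass_pg = vapply(st, `[[`, numeric(1), "mass"))
  })
  do.call(rbind, rows)
}

#' @rdname trueMasses
#' @export
trueDeltaMSeries <- function(scenario, times) {
  if (!.divides(scenario))
    return(data.frame(time = numeric(0), time_rel = numeric(0),
                      m_d1 = numeric(0), m_d2 = numeric(0),
                      delta_m_signed = numeric(0),
                      delta_m_abs = numeric(0)))
  times <- times[times >= scenario@tFurrow]
  m1 <- m2 <- numeric(length(times))
  for (i in seq_along(times)) {
    st <- .scenarioState(scenario, times[i])
    m1[i] <- st[[1]]$mass; m2[i] <- st[[2]]$mass
  }
  ## heavier-at-furrow daughter first
  if (length(times) && m2[1] > m1[1]) { tmp <- m1; m1 <- m2; m2 <- tmp }
  signed <- 2 * (m1 - m2) / (m1 + m2)
  data.frame(time = times, time_rel = times - scenario@tFurrow,
             m_d1 = m1, m_d2 = m2, delta_m_signed = signed,
             delta_m_abs = abs(signed))
}

## Render one radially smooth super-Gaussian mass blob onto a canvas.
## The discrete profile is normalized so the integrated OPD volume equals
## the target mass exactly (no discretization bias in the ledger).
.renderBlob <- function(nr, nc, pixelSize, center, radius, massPg, alpha) {
  out <- matrix(0, nr, nc)
  if (massPg == 0) return(out)
  ext <- 2.2 * radius
  x <- (seq_len(nc) - 1) * pixelSize
  y <- (seq_len(nr) - 1) * pixelSize
  ci <- which(abs(x - center[1]) <= ext)
  ri <- which(abs(y - center[2]) <= ext)
  if (!length(ci) || !length(ri)) return(out)
  dx2 <- (x[ci] - center[1])^2
  dy2 <- (y[ri] - center[2])^2
  r2 <- outer(dy2, dx2, "+") / radius^2
  prof <- exp(-r2^2)                       # super-Gaussian, order 4
  s <- sum(prof)
  if (s == 0) return(out)
  out[ri, ci] <- prof * (massPgToOpdSum(massPg, pixelSize, alpha) / s)
  out
}

#' Render one scenario's cells at a time point
#'
#' Adds the scenario's cell (or daughter pair) as radially smooth
#' super-Gaussian OPD blobs on a zeroed canvas. The discrete integral of
#' each blob is normalized to the scenario's true mass at that time, so
#' integrated OPD volume divided by \code{alpha} recovers the ledger mass
#' exactly; rounded states have a smaller footprint and a strictly higher
#' peak OPD than flat states of the same mass.
#'
#' @param scenario a \linkS4class{CellScenario}.
#' @param time absolute time, min.
#' @param dim canvas dimensions c(rows, cols), pixels.
#' @param pixelSize pixel pitch, um.
#' @param alpha specific refractive increment, m^3/kg.
#' @return An OPD matrix (nm) of size \code{dim}.
#' @export
renderCell <- function(scenario, time, dim = c(240, 320), pixelSize = 1.0,
                       alpha = 1.8e-4) {
  nr <- dim[1]; nc <- dim[2]
  xmax <- (nc - 1) * pixelSize; ymax <- (nr - 1) * pixelSize
  canvas <- matrix(0, nr, nc)
  for (ent in .scenarioState(scenario, time)) {
    ext <- 2.2 * ent$radius
    if (ent$center[1] - ext < 0 || ent$center[1] + ext > xmax ||
        ent$center[2] - ext < 0 || ent$center[2] + ext > ymax)
      stop("cell '", ent$id, "' footprint exceeds the frame at t = ",
           time, " min", call. = FALSE)
    canvas <- canvas + .renderBlob(nr, nc, pixelSize, ent$center,
                                   ent$radius, ent$mass, alpha)
  }
  canvas
}

#' Render a uniform-OPD disk as a PhaseFrame
#'
#' A flat disk of uniform OPD whose discrete integral is normalized to the
#' requested mass; used for closed-form checks of the mass calibration.
#'
#' @param massPg disk dry mass, pg (0 gives an all-zero frame).
#' @param radiusUm disk radius, um.
#' @param dim frame dimensions c(rows, cols), px.
#' @param pixelSize um per pixel.
#' @param center disk center (x, y) in um; default frame middle.
#' @param wavelength nm.
#' @param time min.
#' @param alpha m^3/kg.
#' @return A \linkS4class{PhaseFrame}.
#' @examples
#' f <- renderDiskFrame(55.6, radiusUm = 5.6, dim = c(64, 64))
#' sum(opd(f)) * 1e-6 / 1.8e-4   # recovers 55.6 pg
#' @export
renderDiskFrame <- function(massPg, radiusUm, dim = c(128, 128),
                            pixelSize = 1.0, center = NULL,
                            wavelength = 530, time = 0, alpha = 1.8e-4) {
  nr <- dim[1]; nc <- dim[2]
  if (is.null(center))
    center <- c((nc - 1) / 2, (nr - 1) / 2) * pixelSize
  x <- (seq_len(nc) - 1) * pixelSize
  y <- (seq_len(nr) - 1) * pixelSize
  inside <- outer((y - center[2])^2, (x - center[1])^2, "+") <= radiusUm^2
  o <- matrix(0, nr, nc)
  n <- sum(inside)
  if (massPg > 0 && n > 0)
    o[inside] <- massPgToOpdSum(massPg, pixelSize, alpha) / n
  PhaseFrame(o, intensity = .defaultIntensity(o, pixelSize, 100),
             pixelSize = pixelSize, wavelength = wavelength, time = time)
}

## gradient magnitude by central differences (nm per pixel)
.gradMag <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- (m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]) / 2
  gy <- (m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]) / 2
  sqrt(gx^2 + gy^2)
}

## the companion intensity channel: a constant minus the local OPD gradient
## magnitude (cells appear dark-edged), plus whatever noise the caller adds
.defaultIntensity <- function(opdClean, pixelSize, base = 100) {
  base - .gradMag(opdClean)
}

#' Simulate a synthetic quantitative phase movie
#'
#' Renders seeded time-lapse phase movies of growing, rounding and
#' dividing cells, together with a complete ground-truth ledger. Dividing
#' scenarios appear from the furrow frame onwards as two touching lobes
#' separated by an OPD saddle; programmed redistribution moves mass
#' between connected lobes while conserving the pair total. Identical
#' inputs and seed give bit-identical movies; with \code{noiseSd = 0} the
#' ledger does not depend on the seed at all.
#'
#' @param scenarios a \linkS4class{CellScenario} or list of them.
#' @param frames number of frames.
#' @param interval frame interval, min (default 3).
#' @param noiseSd additive Gaussian background noise on the OPD, nm
#'   (default 3).
#' @param seed integer seed for the noise fields, or NULL.
#' @param dim frame dimensions c(rows, cols), px. The default 240 x 320 at
#'   1 um/px matches a 240 x 320 um field of view.
#' @param pixelSize um per pixel.
#' @param wavelength nm.
#' @param wrap logical: if TRUE, frames are phase-wrapped (OPD modulo one
#'   wavelength wherever it reaches the wavelength) and the per-frame wrap
#'   masks are recorded in the ledger. True OPD must stay below two
#'   wavelengths.
#' @param startTime time of the first frame, min.
#' @param intensityBase constant level of the intensity channel.
#' @param alpha specific refractive increment, m^3/kg.
#' @return A \linkS4class{PhaseMovie}; see \code{\link{groundTruth}} for
#'   the ledger layout.
#' @examples
#' scn <- cellScenario("a", center = c(40, 40), flatRadius = 13,
#'                     initialMass = 300)
#' mv <- simulateMovie(scn, frames = 3, dim = c(80, 80), seed = 1)
#' nFrames(mv)
#' @export
simulateMovie <- function(scenarios, frames, interval = 3, noiseSd = 3,
                          seed = NULL, dim = c(240, 320), pixelSize = 1.0,
                          wavelength = 530, wrap = FALSE, startTime = 0,
                          intensityBase = 100, alpha = 1.8e-4) {
  if (is(scenarios, "CellScenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) > 0, frames >= 1, interval > 0)
  lapply(scenarios, validObject)
  ids <- vapply(scenarios, function(s) s@id, character(1))
  if (anyDuplicated(ids)) stop("scenario ids must be unique")

  ## non-overlapping initial placements
  if (length(scenarios) > 1) {
    st0 <- lapply(scenarios, .scenarioState, time = startTime)
    for (i in seq_along(st0)) for (j in seq_len(i - 1)) {
      for (a in st0[[i]]) for (b in st0[[j]]) {
        if (sqrt(sum((a$center - b$center)^2)) <
            1.1 * (a$radius + b$radius))
          stop("overlapping initial placements: cells '", a$id,
               "' and '", b$id, "'", call. = FALSE)
      }
    }
  }

  times <- startTime + (seq_len(frames) - 1) * interval
  nr <- dim[1]; nc <- dim[2]

  .withSeed(seed, {
    frameList <- vector("list", frames)
    wrapMasks <- vector("list", frames)
    massRows <- vector("list", frames)
    for (k in seq_len(frames)) {
      canvas <- matrix(0, nr, nc)
      ents <- list()
      for (scn in scenarios) {
        canvas <- canvas + renderCell(scn, times[k], dim = dim,
                                      pixelSize = pixelSize, alpha = alpha)
        ents <- c(ents, .scenarioState(scn, times[k]))
      }
      massRows[[k]] <- data.frame(
        frame = k, time = times[k],
        cell = vapply(ents, `[[`, character(1), "id"),
        mass_pg = vapply(ents, `[[`, numeric(1), "mass"))
      if (wrap && any(canvas >= 2 * wavelength))
        stop("true OPD reaches two wavelengths in frame ", k,
             "; outside the single positive correction regime",
             call. = FALSE)
      observed <- canvas
      if (noiseSd > 0)
        observed <- observed + matrix(stats::rnorm(nr * nc, 0, noiseSd),
                                      nr, nc)
      intens <- .defaultIntensity(canvas, pixelSize, intensityBase)
      if (noiseSd > 0)
        intens <- intens + matrix(stats::rnorm(nr * nc, 0, noiseSd / 2),
                                  nr, nc)
      mask <- observed >= wavelength
      if (wrap) {
        observed[mask] <- observed[mask] %% wavelength
        wrapMasks[[k]] <- mask
      } else {
        wrapMasks[[k]] <- matrix(FALSE, nr, nc)
      }
      frameList[[k]] <- PhaseFrame(observed, intensity = intens,
                                   pixelSize = pixelSize,
                                   wavelength = wavelength,
                                   time = times[k])
    }

    dividing <- Filter(.divides, scenarios)
    events <- if (length(dividing)) {
      do.call(rbind, lapply(dividing, function(s) {
        ff <- which(times >= s@tFurrow)[1]
        dm0 <- trueDeltaMSeries(s, s@tFurrow)
        heavier <- if (s@splitFraction >= 0.5) "d1" else "d2"
        data.frame(cell = s@id, t_entry_mid = s@tEntryMid,
                   t_furrow = s@tFurrow,
                   furrow_frame = if (length(ff)) ff else NA_integer_,
                   t_exit_mid_1 = s@tExitMid[1],
                   t_exit_mid_2 = s@tExitMid[2],
                   split_fraction = s@splitFraction,
                   redistribution_rate = s@redistributionRate,
                   heavier_daughter = heavier,
                   delta_m0_true = dm0$delta_m_signed[1])
      }))
    } else {
      data.frame()
    }
    deltaM <- if (length(dividing)) {
      do.call(rbind, lapply(dividing, function(s) {
        d <- trueDeltaMSeries(s, times)
        if (nrow(d)) cbind(cell = s@id, d,
                           frame = match(d$time, times)) else NULL
      }))
    } else {
      data.frame()
    }

    gt <- list(
      masses = do.call(rbind, massRows),
      wrapMasks = wrapMasks,
      events = events,
      deltaM = deltaM,
      scenarios = scenarios,
      params = list(noiseSd = noiseSd, seed = seed, wrap = wrap,
                    wavelength = wavelength, pixelSize = pixelSize,
                    interval = interval, dim = dim, alpha = alpha,
                    startTime = startTime)
    )
    new("PhaseMovie", frames = frameList, interval = interval,
        groundTruth = gt)
  })
}

#' Phase-wrap a frame
#'
#' Replaces OPD by OPD modulo one wavelength wherever the OPD reaches the
#' wavelength, emulating the integer-wavelength ambiguity of quantitative
#' phase reconstruction. Only the single-wrap regime is supported: true
#' OPD at or above two wavelengths is an error.
#'
#' @param frame a \linkS4class{PhaseFrame}.
#' @return list with elements \code{frame} (the wrapped
#'   \linkS4class{PhaseFrame}) and \code{mask} (logical matrix of wrapped
#'   pixels).
#' @examples
#' f <- PhaseFrame(matrix(c(600, 400), 1, 2), wavelength = 530)
#' applyWrapping(f)$frame@opd   # 70, 400
#' @export
applyWrapping <- function(frame) {
  stopifnot(is(frame, "PhaseFrame"))
  lam <- frame@wavelength
  if (any(frame@opd >= 2 * lam))
    stop("true OPD reaches two wavelengths; outside the single positive ",
         "correction regime", call. = FALSE)
  mask <- frame@opd >= lam
  o <- frame@opd
  o[mask] <- o[mask] %% lam
  out <- frame
  out@opd <- o
  list(frame = out, mask = mask)
}
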