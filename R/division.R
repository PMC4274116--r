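#' Sigmoid matched filtering of a mean-phase-shift trace
#'
#' Slides a logistic template across the trace and reports local maxima
#' of the zero-mean, unit-norm correlation above a threshold, each with
#' its fitted amplitude. The midpoint is the time at which the mean phase
#' shift has risen (or decayed) to 50% of the fitted swing: a rising fit
#' marks mitotic entry (cell rounding), a falling fit marks mitotic exit
#' (daughter flattening).
#'
#' @param time frame times of the trace, min (regularly spaced).
#' @param values mean phase shift per frame, nm.
#' @param direction "rising" or "falling".
#' @param tau logistic time constant, min (default 6).
#' @param windowMin half-width of the matching window, min (default 30).
#' @param threshold minimum normalized correlation (default 0.7).
#' @param minAmplitude minimum fitted sigmoid swing, nm (default 20).
#' @return data.frame with one detection per row: midpoint, amplitude,
#'   width, score, direction. Zero rows when the trace is shorter than
#'   the window or nothing matches.
#' @export
fitSigmoidTrace <- function(time, values, direction = c("rising",
                            "falling"), tau = 6, windowMin = 30,
                            threshold = 0.7, minAmplitude = 20) {
  direction <- match.arg(direction)
  stopifnot(length(time) == length(values), tau > 0)
  emptyFit <- data.frame(midpoint = numeric(0), amplitude = numeric(0),
                         width = numeric(0), score = numeric(0),
                         direction = character(0))
  n <- length(values)
  if (n < 3) return(emptyFit)
  interval <- stats::median(diff(time))
  k <- max(2L, as.integer(round(windowMin / interval)))
  if (n < 2 * k + 1) return(emptyFit)

  tmpl <- .logistic(seq(-k, k) * interval / tau)
  if (direction == "falling") tmpl <- 1 - tmpl
  t0 <- tmpl - mean(tmpl)
  tnorm <- sqrt(sum(t0^2))
  varT <- sum(t0^2)

  ## replicate-pad so the template can center on every frame; midpoints
  ## near the trace ends are matched against partially flat windows
  padded <- c(rep(values[1], k), values, rep(values[n], k))
  centers <- seq_len(n)
  score <- amp <- numeric(length(centers))
  for (ii in seq_along(centers)) {
    v <- padded[(centers[ii]):(centers[ii] + 2 * k)]
    v0 <- v - mean(v)
    vn <- sqrt(sum(v0^2))
    if (vn == 0) { score[ii] <- 0; amp[ii] <- 0; next }
    score[ii] <- sum(v0 * t0) / (vn * tnorm)
    amp[ii] <- sum(v0 * t0) / varT      # least-squares swing of the fit
  }
  isMax <- vapply(seq_along(centers), function(ii) {
    lo <- max(1, ii - 1); hi <- min(length(centers), ii + 1)
    score[ii] >= max(score[lo:hi])
  }, logical(1))
  sel <- which(isMax & score > threshold & amp >= minAmplitude)
  if (!length(sel)) return(emptyFit)
  data.frame(midpoint = time[centers[sel]], amplitude = amp[sel],
             width = tau, score = score[sel], direction = direction)
}

.divisionParams <- function(vicinityRadius = 30,
                            massWindow = c(0.35, 0.65),
                            pairWindow = c(0.8, 1.2), tau = 6,
                            windowMin = 30, threshold = 0.7,
                            minAmplitude = 20, edgeFrames = 3) {
  list(vicinityRadius = vicinityRadius, massWindow = massWindow,
       pairWindow = pairWindow, tau = tau, windowMin = windowMin,
       threshold = threshold, minAmplitude = minAmplitude,
       edgeFrames = edgeFrames)
}

.emptyEvents <- function() {
  data.frame(event_id = integer(0), parent_track = integer(0),
             d1_track = integer(0), d2_track = integer(0),
             furrow_frame = integer(0), t_furrow_min = numeric(0),
             entry_mid_min = numeric(0), exit_mid_min_d1 = numeric(0),
             exit_mid_min_d2 = numeric(0),
             time_in_mitosis_min = numeric(0),
             time_rounded_post_min = numeric(0), m_d1_pg = numeric(0),
             m_d2_pg = numeric(0), delta_m0_signed = numeric(0))
}

#' Detect cell-division events in built tracks
#'
#' A division is emitted when (criterion 1) a parent track ends and two
#' new tracks begin in the next frame within the vicinity radius, each
#' with roughly 50% of the parent's last mass (the daughter-mass window)
#' and a combined mass close to the parent's; for adherent cells
#' additionally (criterion 2) the parent's mean-phase trace carries a
#' rising sigmoid fit before the furrow (mitotic entry) and (criterion 3)
#' both daughter traces carry falling fits after it (mitotic exit). In
#' non-adherent mode only criterion 1 applies and entry/exit times are
#' undefined. Daughter 1 is the heavier daughter at t = 0 (the furrow
#' frame, the first frame in which the watershed separates the pair), so
#' the signed asymmetry starts non-negative. Candidates failing a
#' criterion are logged in \code{attr(result, "log")} with the failed
#' criterion; events within \code{edgeFrames} frames of the movie
#' boundaries are rejected for lack of trace.
#'
#' @param tracks track table from \code{\link{buildTracks}}.
#' @param mode "adherent" or "nonadherent".
#' @param vicinityRadius um; daughters must start within this distance of
#'   the parent's last centroid (default 30).
#' @param massWindow per-daughter mass window as a fraction of the
#'   parent's last mass (default 0.35..0.65).
#' @param pairWindow combined-daughter mass window (default 0.8..1.2).
#' @param tau,windowMin,threshold,minAmplitude sigmoid matched-filter
#'   parameters, see \code{\link{fitSigmoidTrace}}.
#' @param edgeFrames boundary margin in frames (default 3).
#' @return data.frame of events (see \code{.emptyEvents} columns), with a
#'   candidate log in \code{attr(, "log")}.
#' @export
detectDivisions <- function(tracks, mode = c("adherent", "nonadherent"),
                            vicinityRadius = 30,
                            massWindow = c(0.35, 0.65),
                            pairWindow = c(0.8, 1.2), tau = 6,
                            windowMin = 30, threshold = 0.7,
                            minAmplitude = 20, edgeFrames = 3) {
  mode <- match.arg(mode)
  events <- .emptyEvents()
  log <- data.frame(parent_track = integer(0), reason = character(0))
  if (nrow(tracks) == 0) {
    attr(events, "log") <- log
    return(events)
  }
  maxFrame <- max(tracks$frame)
  byTrack <- split(seq_len(nrow(tracks)), tracks$track_id)
  ends <- vapply(byTrack, function(ix) max(tracks$frame[ix]), numeric(1))
  starts <- vapply(byTrack, function(ix) min(tracks$frame[ix]),
                   numeric(1))
  ids <- as.integer(names(byTrack))
  fail <- function(tid, why)
    log <<- rbind(log, data.frame(parent_track = tid, reason = why))
  evId <- 0L

  for (pi in order(ids)) {
    pid <- ids[pi]
    e <- ends[pi]
    if (e >= maxFrame) next               # track survives to movie end
    pix <- byTrack[[pi]][order(tracks$frame[byTrack[[pi]]])]
    last <- tracks[pix[length(pix)], ]
    f0 <- e + 1
    startersIdx <- which(starts == f0 & ids != pid)
    if (length(startersIdx)) {
      d <- vapply(startersIdx, function(si) {
        first <- tracks[byTrack[[si]][which.min(
          tracks$frame[byTrack[[si]]])], ]
        sqrt((first$x_um - last$x_um)^2 + (first$y_um - last$y_um)^2)
      }, numeric(1))
      startersIdx <- startersIdx[d <= vicinityRadius]
    }
    if (length(startersIdx) < 2) {
      fail(pid, "criterion1: fewer than two daughter candidates")
      next
    }
    firstRows <- lapply(startersIdx, function(si)
      tracks[byTrack[[si]][which.min(tracks$frame[byTrack[[si]]])], ])
    masses <- vapply(firstRows, `[[`, numeric(1), "mass_pg")
    okMass <- masses >= massWindow[1] * last$mass_pg &
      masses <= massWindow[2] * last$mass_pg
    cand <- which(okMass)
    pair <- NULL
    if (length(cand) >= 2) {
      combos <- utils::combn(cand, 2)
      sums <- masses[combos[1, ]] + masses[combos[2, ]]
      okPair <- sums >= pairWindow[1] * last$mass_pg &
        sums <= pairWindow[2] * last$mass_pg
      if (any(okPair)) {
        best <- which(okPair)[which.min(
          abs(sums[okPair] - last$mass_pg))]
        pair <- combos[, best]
      }
    }
    if (is.null(pair)) {
      fail(pid, "criterion1: no daughter pair in the mass windows")
      next
    }
    if (f0 <= edgeFrames || f0 > maxFrame - edgeFrames) {
      fail(pid, "furrow too close to the movie boundary")
      next
    }

    dIdx <- startersIdx[pair]
    dm <- vapply(firstRows[pair], `[[`, numeric(1), "mass_pg")
    if (dm[2] > dm[1]) { dIdx <- rev(dIdx); dm <- rev(dm) }
    tFurrow <- firstRows[[pair[1]]]$t_min

    entryMid <- exitMid1 <- exitMid2 <- NA_real_
    if (mode == "adherent") {
      pTrace <- tracks[pix, ]
      rises <- fitSigmoidTrace(pTrace$t_min, pTrace$mean_phase_nm,
                               "rising", tau, windowMin, threshold,
                               minAmplitude)
      rises <- rises[rises$midpoint <= tFurrow, , drop = FALSE]
      if (nrow(rises) == 0) {
        fail(pid, "criterion2: no rising sigmoid fit on the parent")
        next
      }
      entryMid <- max(rises$midpoint)
      exits <- lapply(dIdx, function(si) {
        dt <- tracks[byTrack[[si]][order(tracks$frame[byTrack[[si]]])], ]
        ff <- fitSigmoidTrace(dt$t_min, dt$mean_phase_nm, "falling",
                              tau, windowMin, threshold, minAmplitude)
        ff[ff$midpoint >= tFurrow, , drop = FALSE]
      })
      if (any(vapply(exits, nrow, integer(1)) == 0)) {
        fail(pid, "criterion3: missing falling sigmoid fit on a daughter")
        next
      }
      exitMid1 <- min(exits[[1]]$midpoint)
      exitMid2 <- min(exits[[2]]$midpoint)
    }

    evId <- evId + 1L
    events <- rbind(events, data.frame(
      event_id = evId, parent_track = pid,
      d1_track = ids[dIdx[1]], d2_track = ids[dIdx[2]],
      furrow_frame = f0, t_furrow_min = tFurrow,
      entry_mid_min = entryMid, exit_mid_min_d1 = exitMid1,
      exit_mid_min_d2 = exitMid2,
      time_in_mitosis_min = tFurrow - entryMid,
      time_rounded_post_min = min(exitMid1, exitMid2) - tFurrow,
      m_d1_pg = dm[1], m_d2_pg = dm[2],
      delta_m0_signed = 2 * (dm[1] - dm[2]) / (dm[1] + dm[2])))
  }
  attr(events, "log") <- log
  events
}

#' Mitotic timing of a division event
#'
#' Time in mitosis is the span from the parent's mitotic-entry midpoint
#' (the 50% point of the abrupt mean-phase rise) to the furrow; the
#' post-furrow rounded time runs from the furrow to the first daughter's
#' flattening midpoint. Both are undefined (NA, flagged) for
#' non-adherent events, which carry no sigmoid fits.
#'
#' @param events one or more rows of the \code{\link{detectDivisions}}
#'   event table.
#' @return data.frame: event_id, time_in_mitosis, time_rounded_post,
#'   defined (logical).
#' @export
measureDivisionTimes <- function(events) {
  defined <- is.finite(events$entry_mid_min) &
    is.finite(events$exit_mid_min_d1) & is.finite(events$exit_mid_min_d2)
  data.frame(
    event_id = events$event_id,
    time_in_mitosis = ifelse(defined,
      events$t_furrow_min - events$entry_mid_min, NA_real_),
    time_rounded_post = ifelse(defined,
      pmin(events$exit_mid_min_d1, events$exit_mid_min_d2) -
        events$t_furrow_min, NA_real_),
    defined = defined)
}

#' Daughter-pair mass asymmetry series for one event
#'
#' Joins the two daughter tracks frame by frame from the furrow onwards
#' and computes the signed and absolute pair-normalized mass difference.
#' Daughter 1 is the heavier daughter at t = 0, so the signed series
#' starts non-negative.
#'
#' @param event one row of the \code{\link{detectDivisions}} table.
#' @param tracks the track table the event refers to.
#' @return data.frame: time, time_rel, m_d1, m_d2, delta_m_signed,
#'   delta_m_abs.
#' @export
deltaMSeries <- function(event, tracks) {
  d1 <- tracks[tracks$track_id == event$d1_track, ]
  d2 <- tracks[tracks$track_id == event$d2_track, ]
  common <- intersect(d1$frame, d2$frame)
  d1 <- d1[match(common, d1$frame), ]
  d2 <- d2[match(common, d2$frame), ]
  signed <- 2 * (d1$mass_pg - d2$mass_pg) / (d1$mass_pg + d2$mass_pg)
  data.frame(time = d1$t_min, time_rel = d1$t_min - event$t_furrow_min,
             m_d1 = d1$mass_pg, m_d2 = d2$mass_pg,
             delta_m_signed = signed, delta_m_abs = abs(signed))
}
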