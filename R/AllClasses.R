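#' @import methods
NULL

#' PhaseFrame: one quantitative phase image
#'
#' A single quantitative phase image. Pixel values are optical path
#' difference (OPD) in nanometers; an optional companion intensity image
#' (arbitrary units) is carried along because the phase-unwrapping feature
#' bank uses it.
#'
#' @slot opd numeric matrix, OPD in nm (rows = y, columns = x).
#' @slot intensity numeric matrix of the same dimensions, or a 0 x 0 matrix
#'   when no intensity channel is available.
#' @slot pixelSize pixel pitch in micrometers.
#' @slot wavelength illumination wavelength in nanometers.
#' @slot time acquisition time in minutes.
#'
#' @aliases PhaseFrame
#' @exportClass PhaseFrame
setClass("PhaseFrame",
  representation(
    opd = "matrix",
    intensity = "matrix",
    pixelSize = "numeric",
    wavelength = "numeric",
    time = "numeric"
  ),
  prototype(
    opd = matrix(0, 0, 0),
    intensity = matrix(0, 0, 0),
    pixelSize = 1.0,
    wavelength = 530,
    time = 0
  )
)

setValidity("PhaseFrame", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@opd)))
    msg <- c(msg, "opd contains non-finite values")
  if (length(object@intensity) > 0 &&
      !identical(dim(object@intensity), dim(object@opd)))
    msg <- c(msg, "intensity dimensions differ from opd")
  if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@wavelength) != 1 || !is.finite(object@wavelength) ||
      object@wavelength <= 0)
    msg <- c(msg, "wavelength must be a single positive number")
  if (length(object@time) != 1 || !is.finite(object@time))
    msg <- c(msg, "time must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a PhaseFrame
#'
#' @param opd numeric matrix of OPD values in nm.
#' @param intensity optional companion intensity matrix (same dimensions).
#' @param pixelSize pixel pitch, micrometers.
#' @param wavelength illumination wavelength, nm.
#' @param time frame time, minutes.
#' @return A \linkS4class{PhaseFrame}.
#' @examples
#' f <- PhaseFrame(matrix(0, 16, 16))
#' dim(f)
#' @export
PhaseFrame <- function(opd, intensity = NULL, pixelSize = 1.0,
                       wavelength = 530, time = 0) {
  if (is.null(intensity)) intensity <- matrix(numeric(0), 0, 0)
  new("PhaseFrame", opd = opd, intensity = intensity,
      pixelSize = pixelSize, wavelength = wavelength, time = time)
}

#' CellScenario: programmed behavior of one synthetic cell
#'
#' Describes one synthetic cell: its mass trajectory, adhesion mode,
#' rounding geometry and (optionally) a division with a programmed daughter
#' mass split and post-furrow mass redistribution. Times are absolute movie
#' minutes. A scenario divides when \code{tFurrow} is finite.
#'
#' @slot id character label for the cell.
#' @slot initialMass dry mass at t = 0, pg.
#' @slot growthRate mass accumulation rate, pg/min (>= 0).
#' @slot center initial centroid, micrometers (x, y).
#' @slot drift constant drift velocity, micrometers/min (x, y).
#' @slot adherent logical; adherent cells flatten/round, non-adherent cells
#'   keep a constant rounded footprint.
#' @slot flatRadius footprint radius when flattened, micrometers.
#' @slot roundRadius footprint radius when rounded in mitosis, micrometers.
#' @slot transitionTau logistic time constant of rounding/flattening, min.
#' @slot tEntryMid sigmoid midpoint of pre-division rounding, min (NA for
#'   non-dividing or non-adherent cells).
#' @slot tFurrow time of the deep cleavage furrow (first split frame), min.
#' @slot tExitMid per-daughter sigmoid midpoints of post-division
#'   flattening, min (length 2).
#' @slot splitFraction daughter-1 share of parent mass at the furrow,
#'   in (0, 1).
#' @slot redistributionRate signed fraction of the furrow-time parent mass
#'   transferred per minute from daughter 2 to daughter 1 while the pair is
#'   connected (positive values enrich daughter 1).
#' @slot redistributionDuration duration of the linear transfer, min.
#' @slot daughterAxis orientation of the daughter separation axis, radians.
#'
#' @aliases CellScenario
#' @exportClass CellScenario
setClass("CellScenario",
  representation(
    id = "character",
    initialMass = "numeric",
    growthRate = "numeric",
    center = "numeric",
    drift = "numeric",
    adherent = "logical",
    flatRadius = "numeric",
    roundRadius = "numeric",
    transitionTau = "numeric",
    tEntryMid = "numeric",
    tFurrow = "numeric",
    tExitMid = "numeric",
    splitFraction = "numeric",
    redistributionRate = "numeric",
    redistributionDuration = "numeric",
    daughterAxis = "numeric"
  )
)

setValidity("CellScenario", function(object) {
  msg <- character(0)
  if (object@initialMass <= 0) msg <- c(msg, "initialMass must be > 0")
  if (object@growthRate < 0) msg <- c(msg, "growthRate must be >= 0")
  if (object@splitFraction <= 0 || object@splitFraction >= 1)
    msg <- c(msg, "splitFraction must lie strictly inside (0, 1)")
  if (!(object@flatRadius > object@roundRadius && object@roundRadius > 0))
    msg <- c(msg, "need flatRadius > roundRadius > 0")
  if (object@transitionTau <= 0) msg <- c(msg, "transitionTau must be > 0")
  if (length(object@center) != 2 || length(object@drift) != 2)
    msg <- c(msg, "center and drift must have length 2")
  if (is.finite(object@tFurrow)) {
    if (object@adherent && !is.finite(object@tEntryMid))
      msg <- c(msg, "adherent dividing scenario needs tEntryMid")
    if (object@adherent && is.finite(object@tEntryMid) &&
        object@tEntryMid >= object@tFurrow)
      msg <- c(msg, "tEntryMid must precede tFurrow")
    if (object@adherent && any(!is.finite(object@tExitMid)))
      msg <- c(msg, "adherent dividing scenario needs both tExitMid values")
    if (any(is.finite(object@tExitMid) & object@tExitMid <= object@tFurrow))
      msg <- c(msg, "tExitMid values must follow tFurrow")
    ## redistribution must not exhaust either daughter
    moved <- abs(object@redistributionRate) * object@redistributionDuration
    share <- min(object@splitFraction, 1 - object@splitFraction)
    if (moved > 0.95 * share)
      msg <- c(msg, "redistribution would exhaust a daughter's mass")
  }
  if (length(msg)) msg else TRUE
})

#' PhaseMovie: a time-ordered phase image stack plus ground truth
#'
#' Container returned by \code{\link{simulateMovie}}: a list of
#' \linkS4class{PhaseFrame}s at a fixed frame interval plus the generator's
#' ground-truth ledger (true per-cell masses, wrap masks, event times, true
#' asymmetry series).
#'
#' @slot frames list of \linkS4class{PhaseFrame}.
#' @slot interval frame interval, minutes.
#' @slot groundTruth list with elements \code{masses} (data.frame: frame,
#'   time, cell, mass_pg), \code{wrapMasks} (list of logical matrices),
#'   \code{events} (data.frame of programmed division events),
#'   \code{deltaM} (data.frame: cell, frame, time, time_rel,
#'   delta_m_signed, delta_m_abs), \code{scenarios} (list of
#'   \linkS4class{CellScenario}), and \code{params}.
#'
#' @aliases PhaseMovie
#' @exportClass PhaseMovie
setClass("PhaseMovie",
  representation(
    frames = "list",
    interval = "numeric",
    groundTruth = "list"
  ),
  prototype(frames = list(), interval = 3, groundTruth = list())
)

setValidity("PhaseMovie", function(object) {
  msg <- character(0)
  if (!all(vapply(object@frames, is, logical(1), "PhaseFrame")))
    msg <- c(msg, "frames must all be PhaseFrame objects")
  if (length(object@frames) > 1) {
    tt <- vapply(object@frames, function(f) f@time, numeric(1))
    if (any(diff(tt) <= 0))
      msg <- c(msg, "frame times must be strictly increasing")
  }
  if (object@interval <= 0) msg <- c(msg, "interval must be > 0")
  if (length(msg)) msg else TRUE
})

#' UnwrapModel: trained linear pixel classifier for phase unwrapping
#'
#' Linear discriminant weights over the 16-channel pixel-statistic bank,
#' plus the decision threshold chosen on a held-out split and a training
#' summary.
#'
#' @slot weights numeric vector, one weight per feature channel.
#' @slot threshold decision threshold in score units.
#' @slot channels character vector of feature channel names (order fixed).
#' @slot trainingSummary list: pixel counts, class balance, held-out
#'   balanced accuracy.
#' @slot version feature-bank version string.
#'
#' @aliases UnwrapModel
#' @exportClass UnwrapModel
setClass("UnwrapModel",
  representation(
    weights = "numeric",
    threshold = "numeric",
    channels = "character",
    trainingSummary = "list",
    version = "character"
  )
)

setValidity("UnwrapModel", function(object) {
  msg <- character(0)
  if (length(object@weights) != length(object@channels))
    msg <- c(msg, "one weight per channel required")
  if (length(object@weights) != 16)
    msg <- c(msg, "feature bank has 16 channels")
  if (!is.finite(object@threshold)) msg <- c(msg, "threshold must be finite")
  if (length(msg)) msg else TRUE
})
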