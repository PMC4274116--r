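#' Accessors for PhaseFrame and PhaseMovie
#'
#' @param object a \linkS4class{PhaseFrame} or \linkS4class{PhaseMovie}.
#' @return \code{opd} and \code{intensityImage} return matrices;
#'   \code{pixelSize} (um), \code{wavelength} (nm) and \code{frameTime}
#'   (min) return numbers; \code{frames} returns the list of frames;
#'   \code{groundTruth} the generator ledger; \code{nFrames} the frame
#'   count.
#' @name phase-accessors
NULL

#' @rdname phase-accessors
#' @export
setGeneric("opd", function(object) standardGeneric("opd"))

#' @rdname phase-accessors
#' @export
setGeneric("intensityImage",
           function(object) standardGeneric("intensityImage"))

#' @rdname phase-accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname phase-accessors
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' @rdname phase-accessors
#' @export
setGeneric("frameTime", function(object) standardGeneric("frameTime"))

#' @rdname phase-accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname phase-accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname phase-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname phase-accessors
setMethod("opd", "PhaseFrame", function(object) object@opd)

#' @rdname phase-accessors
setMethod("intensityImage", "PhaseFrame", function(object) {
  if (length(object@intensity) == 0) NULL else object@intensity
})

#' @rdname phase-accessors
setMethod("pixelSize", "PhaseFrame", function(object) object@pixelSize)

#' @rdname phase-accessors
setMethod("wavelength", "PhaseFrame", function(object) object@wavelength)

#' @rdname phase-accessors
setMethod("frameTime", "PhaseFrame", function(object) object@time)

#' @rdname phase-accessors
setMethod("frames", "PhaseMovie", function(object) object@frames)

#' @rdname phase-accessors
setMethod("groundTruth", "PhaseMovie", function(object) object@groundTruth)

#' @rdname phase-accessors
setMethod("nFrames", "PhaseMovie", function(object) length(object@frames))

#' @describeIn phase-accessors dimensions of the OPD grid.
#' @export
setMethod("dim", "PhaseFrame", function(x) dim(x@opd))

#' Extract one frame from a movie
#' @param x a \linkS4class{PhaseMovie}.
#' @param i frame index.
#' @param j,... unused.
#' @return A \linkS4class{PhaseFrame}.
#' @export
setMethod("[[", "PhaseMovie", function(x, i, j, ...) x@frames[[i]])

#' @describeIn phase-accessors number of frames.
#' @param x a \linkS4class{PhaseMovie}.
#' @export
setMethod("length", "PhaseMovie", function(x) length(x@frames))

setMethod("show", "PhaseFrame", function(object) {
  cat("PhaseFrame:", nrow(object@opd), "x", ncol(object@opd),
      sprintf("px (%.2f um/px), lambda = %g nm, t = %g min\n",
              object@pixelSize, object@wavelength, object@time))
  cat("  OPD range [nm]:",
      sprintf("%.1f .. %.1f", min(object@opd), max(object@opd)),
      if (length(object@intensity)) "(+ intensity channel)" else "", "\n")
})

setMethod("show", "PhaseMovie", function(object) {
  cat("PhaseMovie:", length(object@frames), "frames at",
      object@interval, "min intervals\n")
  gt <- object@groundTruth
  if (length(gt)) {
    cat("  cells:", length(unique(gt$masses$cell)),
        "| programmed divisions:",
        if (is.null(gt$events)) 0 else nrow(gt$events), "\n")
  }
})

setMethod("show", "UnwrapModel", function(object) {
  cat("UnwrapModel (feature bank", object@version, "):",
      length(object@weights), "channels, threshold =",
      signif(object@threshold, 4), "\n")
  ts <- object@trainingSummary
  if (length(ts))
    cat("  trained on", ts$nPixels, "pixels (",
        sprintf("%.1f%% positive", 100 * ts$positiveFraction),
        "), held-out balanced accuracy",
        sprintf("%.3f", ts$heldOutBalancedAccuracy), "\n")
})

setMethod("show", "CellScenario", function(object) {
  cat("CellScenario", object@id, ":",
      sprintf("%.0f pg, %s", object@initialMass,
              if (object@adherent) "adherent" else "non-adherent"))
  if (is.finite(object@tFurrow))
    cat(sprintf(", divides at t = %g min (f = %.2f)",
                object@tFurrow, object@splitFraction))
  cat("\n")
})
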