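#' Segmentation configuration
#'
#' Parameters of the watershed segmentation and the mass measurement.
#'
#' @param sigma Gaussian low-pass sigma in pixels used before
#'   thresholding/watershed (default 2; 0 disables smoothing). Smoothing
#'   steers segmentation only; mass is always summed over the raw OPD so
#'   it stays unbiased.
#' @param minArea minimum region area in um^2; smaller regions are
#'   discarded as noise specks (default 50).
#' @param minOPD absolute floor (nm) a smoothed pixel must exceed to count
#'   as foreground, guarding the Otsu threshold against empty, noise-only
#'   frames (default 10, about seventeen times the generator's default noise sd).
#' @param tolerance watershed tolerance in nm: neighbouring intensity
#'   maxima closer than this are merged instead of split (default 15).
#' @param alpha specific refractive increment, m^3/kg.
#' @return A named list of class \code{SegmentationConfig}.
#' @export
segmentationConfig <- function(sigma = 2, minArea = 50, minOPD = 10,
                               tolerance = 15, alpha = 1.8e-4) {
  stopifnot(sigma >= 0, minArea >= 0, minOPD >= 0, tolerance > 0,
            alpha > 0)
  structure(list(sigma = sigma, minArea = minArea, minOPD = minOPD,
                 tolerance = tolerance, alpha = alpha),
            class = "SegmentationConfig")
}

#' Segment individual cells in a corrected frame
#'
#' The OPD image is Gaussian low-pass filtered, foreground is selected by
#' Otsu's threshold (with an absolute floor for noise-only frames), and
#' touching cells are split along the OPD ridge between local maxima by
#' the watershed transform. Regions below the minimum area are discarded;
#' the survivors are relabelled 1..n in order of their first (row-major)
#' pixel, which makes labelling deterministic.
#'
#' @param frame a \linkS4class{PhaseFrame} (already unwrapped/corrected).
#' @param cfg a \code{\link{segmentationConfig}}.
#' @return Integer label matrix; 0 is background. An all-background frame
#'   yields an all-zero matrix.
#' @export
segmentCells <- function(frame, cfg = segmentationConfig()) {
  stopifnot(is(frame, "PhaseFrame"), inherits(cfg, "SegmentationConfig"))
  o <- frame@opd
  sm <- if (cfg$sigma > 0) .gaussSmooth(o, cfg$sigma) else o
  mx <- max(sm)
  lab <- matrix(0L, nrow(o), ncol(o))
  if (mx <= cfg$minOPD) return(lab)
  ## Otsu on log-compressed OPD: the threshold must separate background
  ## from cells, and log compression stops one bright rounded cell from
  ## pulling the split far above dim flattened cells
  lg <- log1p(pmax(sm, 0))
  thr <- expm1(EBImage::otsu(EBImage::Image(lg / max(lg)),
                             range = c(0, 1)) * max(lg))
  thr <- max(thr, cfg$minOPD)
  high <- sm > thr
  if (!any(high)) return(lab)
  ## hysteresis: extend cell support from the Otsu level down to the
  ## absolute floor, so the dim skirt of each cell is kept and mass is
  ## not clipped at the threshold; noise-only components carry no
  ## Otsu-level pixel and are dropped
  low <- sm > cfg$minOPD
  lowLab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(low * 1))),
                   nrow(o), ncol(o))
  keepComp <- unique(lowLab[high & lowLab > 0])
  mask <- lowLab > 0 & lowLab %in% keepComp
  if (!any(mask)) return(lab)
  ws <- EBImage::watershed(EBImage::Image(sm * mask),
                           tolerance = cfg$tolerance, ext = 1)
  lab <- matrix(as.integer(ws), nrow(o), ncol(o))

  ## drop specks, relabel deterministically by first row-major pixel
  minPx <- cfg$minArea / frame@pixelSize^2
  counts <- tabulate(lab)
  keep <- which(counts >= minPx)
  if (!length(keep)) return(matrix(0L, nrow(o), ncol(o)))
  firstPix <- vapply(keep, function(l) which(lab == l)[1], numeric(1))
  keep <- keep[order(firstPix)]
  out <- matrix(0L, nrow(o), ncol(o))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

## boundary chain length in pixel units: 8-connected contour walk with
## diagonal steps weighted sqrt(2) (regionprops-style); reproduces
## shape factor ~0.91 for digital disks and -> pi/4 for squares
.chainPerimeter <- function(mask) {
  if (sum(mask) == 1) return(4)
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  total <- 0
  for (pts in oc) {
    if (nrow(pts) < 2) { total <- total + 4; next }
    d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
    total <- total + sum(sqrt(rowSums(d^2)))
  }
  max(total, 4)
}

#' Measure segmented cell regions
#'
#' For each labelled region: dry mass as the sum of mass per pixel over
#' the segmented area (raw OPD, converted through the specific refractive
#' increment), area, boundary perimeter, geometric centroid, mean phase
#' shift (mean OPD over the footprint), and the shape factor
#' \eqn{4\pi A / P^2} (1 for a perfect circle).
#'
#' @param labels integer label matrix from \code{\link{segmentCells}}.
#' @param frame the \linkS4class{PhaseFrame} the labels refer to.
#' @param cfg a \code{\link{segmentationConfig}} (for \code{alpha}).
#' @return data.frame with one row per region: label, t_min, mass_pg,
#'   area_um2, perimeter_px, mean_phase_nm, shape_factor, x_um, y_um.
#'   Pixel coordinates are 0-based, so a cell whose first pixel row/col is
#'   1 sits at 0 um.
#' @export
measureRegions <- function(labels, frame, cfg = segmentationConfig()) {
  stopifnot(identical(dim(labels), dim(frame@opd)))
  px <- frame@pixelSize
  nlab <- max(labels)
  cols <- c("label", "t_min", "mass_pg", "area_um2", "perimeter_px",
            "mean_phase_nm", "shape_factor", "x_um", "y_um")
  if (nlab == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
    return(out)
  }
  rows <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    pix <- which(labels == l)
    if (!length(pix)) {
      warning("label ", l, " has no pixels; skipped")
      next
    }
    rc <- arrayInd(pix, dim(labels))
    areaPx <- length(pix)
    opdSum <- sum(frame@opd[pix])
    per <- .chainPerimeter(labels == l)
    rows[[l]] <- data.frame(
      label = l,
      t_min = frame@time,
      mass_pg = opdSumToMassPg(opdSum, px, cfg$alpha),
      area_um2 = areaPx * px^2,
      perimeter_px = per,
      mean_phase_nm = opdSum / areaPx,
      shape_factor = 4 * pi * areaPx / per^2,
      x_um = (mean(rc[, 2]) - 1) * px,
      y_um = (mean(rc[, 1]) - 1) * px)
  }
  do.call(rbind, rows)
}

#' Percentage of the imaging area covered by cells
#'
#' @param labels integer label matrix.
#' @return Confluence in percent.
#' @examples
#' computeConfluence(matrix(c(0, 1, 1, 0), 2, 2))  # 50
#' @export
computeConfluence <- function(labels) {
  100 * mean(labels > 0)
}
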