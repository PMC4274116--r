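## Phase unwrapping: a trained linear pixel classifier scores every pixel,
## a random walker turns the score map into connected regions, and each
## region receives a single positive one-wavelength correction.

.unwrapBankVersion <- "bank-1"

#' Names of the 16 pixel-statistic channels
#'
#' Fixed order of the feature bank computed by
#' \code{\link{computePixelStatistics}}: the raw OPD, the intensity image,
#' a phase-quality magnitude map (windowed gradient-variance measure),
#' Sobel x/y/magnitude and Laplacian edge filters, Gaussian-smoothed OPD
#' at two scales, local standard deviation at two window sizes, local
#' range, median-filter residual, morphological gradient, the intensity
#' Sobel magnitude, and the distance by which the OPD falls below one
#' wavelength (wrap proximity).
#'
#' @return Character vector of length 16.
#' @export
unwrapChannelNames <- function() {
  c("opd", "intensity", "phase_quality", "sobel_x", "sobel_y",
    "sobel_mag", "laplacian", "gauss_s2", "gauss_s5", "local_sd_3",
    "local_sd_7", "local_range_3", "median3_residual", "morph_gradient",
    "intensity_sobel_mag", "wrap_proximity")
}

#' Compute the 16-channel pixel-statistic bank for one frame
#'
#' @param frame a \linkS4class{PhaseFrame} carrying both an OPD and an
#'   intensity channel.
#' @return A numeric array of dimension \code{c(nrow, ncol, 16)} with
#'   channel names (see \code{\link{unwrapChannelNames}}) on the third
#'   dimension.
#' @export
computePixelStatistics <- function(frame) {
  stopifnot(is(frame, "PhaseFrame"))
  o <- frame@opd
  if (!all(is.finite(o))) {
    bad <- arrayInd(which(!is.finite(o))[1], dim(o))
    stop("non-finite OPD pixel at (row ", bad[1], ", col ", bad[2], ")",
         call. = FALSE)
  }
  if (length(frame@intensity) == 0)
    stop("frame has no intensity channel; the feature bank requires both ",
         "opd and intensity", call. = FALSE)
  iv <- frame@intensity
  if (!all(is.finite(iv))) {
    bad <- arrayInd(which(!is.finite(iv))[1], dim(iv))
    stop("non-finite intensity pixel at (row ", bad[1], ", col ", bad[2],
         ")", call. = FALSE)
  }
  nr <- nrow(o); nc <- ncol(o)

  sx <- .conv2(o, .sobelX)
  sy <- .conv2(o, .sobelY)
  gx <- (.shift(o, 0, -1) - .shift(o, 0, 1)) / 2
  gy <- (.shift(o, -1, 0) - .shift(o, 1, 0)) / 2
  isx <- .conv2(iv, .sobelX)
  isy <- .conv2(iv, .sobelY)

  out <- array(0, dim = c(nr, nc, 16),
               dimnames = list(NULL, NULL, unwrapChannelNames()))
  out[, , "opd"] <- o
  out[, , "intensity"] <- iv
  out[, , "phase_quality"] <- sqrt(.boxVar(gx, 5) + .boxVar(gy, 5))
  out[, , "sobel_x"] <- sx
  out[, , "sobel_y"] <- sy
  out[, , "sobel_mag"] <- sqrt(sx^2 + sy^2)
  out[, , "laplacian"] <- .conv2(o, .laplace4)
  out[, , "gauss_s2"] <- .gaussSmooth(o, 2)
  out[, , "gauss_s5"] <- .gaussSmooth(o, 5)
  out[, , "local_sd_3"] <- sqrt(.boxVar(o, 3))
  out[, , "local_sd_7"] <- sqrt(.boxVar(o, 7))
  out[, , "local_range_3"] <- .morphMax(o, .offsetsBox3) -
    .morphMin(o, .offsetsBox3)
  out[, , "median3_residual"] <- o - .median3(o)
  out[, , "morph_gradient"] <- .morphMax(o, .offsetsDiamond3) -
    .morphMin(o, .offsetsDiamond3)
  out[, , "intensity_sobel_mag"] <- sqrt(isx^2 + isy^2)
  out[, , "wrap_proximity"] <- pmax(frame@wavelength - o, 0)
  out
}

.stackToMatrix <- function(stack) {
  d <- dim(stack)
  matrix(stack, nrow = d[1] * d[2], ncol = d[3],
         dimnames = list(NULL, dimnames(stack)[[3]]))
}

#' Train the linear pixel classifier for wrap detection
#'
#' Fits a two-class linear discriminant (wrapped-region pixels versus all
#' others) over the 16-channel feature bank and chooses the decision
#' threshold that maximizes balanced accuracy on a held-out split of the
#' training pixels.
#'
#' @param stacks one feature stack from
#'   \code{\link{computePixelStatistics}}, or a list of them.
#' @param labels logical wrap-region mask (or list of masks) matching the
#'   stacks.
#' @param holdoutFraction fraction of pixels held out for threshold
#'   selection (default 0.2).
#' @param maxPixelsPerClass subsampling cap per class, to bound memory.
#' @param seed integer seed for the subsampling and split.
#' @return An \linkS4class{UnwrapModel}.
#' @export
trainUnwrapModel <- function(stacks, labels, holdoutFraction = 0.2,
                             maxPixelsPerClass = 2e5, seed = 1L) {
  if (is.array(stacks) && length(dim(stacks)) == 3) stacks <- list(stacks)
  if (is.matrix(labels)) labels <- list(labels)
  stopifnot(length(stacks) == length(labels))
  X <- do.call(rbind, lapply(stacks, .stackToMatrix))
  y <- unlist(lapply(labels, as.logical), use.names = FALSE)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2)
    stop("labels contain a single class; need both wrapped and ",
         "unwrapped pixels", call. = FALSE)

  .withSeed(seed, {
    idxPos <- which(y); idxNeg <- which(!y)
    if (length(idxPos) > maxPixelsPerClass)
      idxPos <- sort(sample(idxPos, maxPixelsPerClass))
    if (length(idxNeg) > maxPixelsPerClass)
      idxNeg <- sort(sample(idxNeg, maxPixelsPerClass))
    idx <- c(idxPos, idxNeg)
    X <- X[idx, , drop = FALSE]
    y <- y[idx]

    ## stratified held-out split for threshold selection; systematic
    ## (every k-th pixel per class) so it is deterministic and invariant
    ## under swapping the class labels
    k <- max(2L, round(1 / holdoutFraction))
    sys <- function(idx) idx[seq_along(idx) %% k == 0]
    hold <- c(sys(which(y)), sys(which(!y)))
    if (!length(hold)) hold <- c(which(y)[1], which(!y)[1])
    tr <- setdiff(seq_along(y), hold)

    keep <- which(apply(X[tr, , drop = FALSE], 2, stats::sd) > 0)
    if (length(keep) < 1) stop("all feature channels are constant")
    fit <- MASS::lda(X[tr, keep, drop = FALSE],
                     grouping = factor(y[tr], levels = c(FALSE, TRUE)))
    w <- numeric(ncol(X))
    w[keep] <- fit$scaling[, 1]

    score <- as.numeric(X %*% w)
    ## orient so wrapped pixels score high
    if (mean(score[y]) < mean(score[!y])) {
      w <- -w
      score <- -score
    }

    sHold <- score[hold]; yHold <- y[hold]
    cand <- sort(unique(stats::quantile(
      sHold, probs = seq(0.001, 0.999, length.out = 511), names = FALSE)))
    ba <- vapply(cand, function(th) {
      pred <- sHold > th
      (mean(pred[yHold]) + mean(!pred[!yHold])) / 2
    }, numeric(1))
    threshold <- cand[which.max(ba)]

    new("UnwrapModel", weights = w, threshold = threshold,
        channels = unwrapChannelNames(),
        trainingSummary = list(
          nPixels = length(y),
          positiveFraction = mean(y),
          heldOutBalancedAccuracy = max(ba)),
        version = .unwrapBankVersion)
  })
}

#' Score a frame with an unwrap model
#'
#' @param frame a \linkS4class{PhaseFrame}.
#' @param model an \linkS4class{UnwrapModel}.
#' @return Numeric matrix of discriminant scores.
#' @export
scoreWrapPixels <- function(frame, model) {
  stopifnot(is(model, "UnwrapModel"))
  if (!identical(model@channels, unwrapChannelNames()))
    stop("model was trained on a different feature bank version")
  stack <- computePixelStatistics(frame)
  matrix(.stackToMatrix(stack) %*% model@weights,
         nrow(frame@opd), ncol(frame@opd))
}

#' Detect phase-wrapped regions
#'
#' Scores every pixel with the linear classifier and refines the
#' above-threshold candidate set with a random walker: high-confidence
#' seeds are the morphological core of the candidate regions,
#' low-confidence (background) seeds are everything more than two pixels
#' away from any candidate, and the two-pixel shell in between is
#' assigned by the walker. The walker's edge weights combine the score
#' image with the raw OPD, whose one-pixel cliff at a wrap boundary
#' anchors the cut. When no pixel clears the decision threshold the mask
#' is empty and a warning is logged.
#'
#' @param frame a \linkS4class{PhaseFrame}.
#' @param model an \linkS4class{UnwrapModel} trained on the same feature
#'   bank version.
#' @param beta random-walker edge-weight sharpness (default 90).
#' @param shell width (px) of the uncertain band around candidate
#'   regions that the walker adjudicates (default 2).
#' @param pad margin (px) around candidate pixels inside which the walker
#'   problem is solved; everything outside is background.
#' @return Logical correction mask of the frame's dimensions.
#' @export
detectWrapRegions <- function(frame, model, beta = 90, shell = 2,
                              pad = 15) {
  score <- scoreWrapPixels(frame, model)
  nr <- nrow(score); nc <- ncol(score)
  empty <- matrix(FALSE, nr, nc)
  cand <- score > model@threshold
  if (!any(cand)) {
    warning("no pixels above the decision threshold; empty correction mask")
    return(empty)
  }
  dil <- function(m, times) {
    x <- m * 1
    for (i in seq_len(times)) x <- .morphMax(x, .offsetsBox3)
    x > 0
  }
  ## high-confidence seeds: the morphological core of the candidate
  ## regions, restricted to the upper part of the candidate score range
  ## (the shell of barely-above-threshold pixels must stay unseeded)
  fg <- !dil(!cand, 1) &
    score >= stats::quantile(score[cand], 0.6, names = FALSE)
  if (!any(fg)) fg <- !dil(!cand, 1)
  if (!any(fg)) fg <- score == max(score[cand]) & cand
  bg <- !dil(cand, shell)

  ## solve the walker on a padded bounding box of the candidate pixels
  rows <- range(which(rowSums(cand) > 0))
  cols <- range(which(colSums(cand) > 0))
  ri <- max(1, rows[1] - pad):min(nr, rows[2] + pad)
  ci <- max(1, cols[1] - pad):min(nc, cols[2] + pad)
  subScore <- score[ri, ci, drop = FALSE]
  subOpd <- frame@opd[ri, ci, drop = FALSE]
  subFg <- fg[ri, ci, drop = FALSE]
  subBg <- bg[ri, ci, drop = FALSE] & !subFg
  if (!any(subBg)) {
    ## fall back to the box border as background
    subBg <- matrix(FALSE, nrow(subScore), ncol(subScore))
    subBg[c(1, nrow(subBg)), ] <- TRUE
    subBg[, c(1, ncol(subBg))] <- TRUE
    subBg <- subBg & !subFg
  }
  prob <- randomWalkerSegment(list(subScore, subOpd), subFg, subBg,
                              beta = beta)
  subMask <- prob > 0.5

  ## keep connected components that contain a foreground seed
  lab <- EBImage::bwlabel(EBImage::Image(subMask * 1))
  labm <- matrix(as.integer(lab), nrow(subMask), ncol(subMask))
  keep <- unique(labm[subFg & labm > 0])
  subMask <- labm > 0 & labm %in% keep

  mask <- empty
  mask[ri, ci] <- subMask
  mask
}

#' Apply single positive wavelength corrections
#'
#' Adds exactly one wavelength to every masked pixel; no other pixel is
#' altered. Negative or multi-wavelength corrections are not supported by
#' construction. Applying the same mask twice doubles the correction, so
#' repeated use must recompute the mask.
#'
#' @param frame a \linkS4class{PhaseFrame}.
#' @param mask logical matrix matching the frame grid.
#' @return The corrected \linkS4class{PhaseFrame}.
#' @export
correctPhase <- function(frame, mask) {
  stopifnot(is(frame, "PhaseFrame"),
            identical(dim(mask), dim(frame@opd)))
  out <- frame
  out@opd <- frame@opd + frame@wavelength * mask
  out
}

#' Serialize an unwrap model to JSON
#' @param model an \linkS4class{UnwrapModel}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeUnwrapModel <- function(model, path) {
  stopifnot(is(model, "UnwrapModel"))
  jsonlite::write_json(
    list(weights = model@weights, threshold = model@threshold,
         channels = model@channels, trainingSummary = model@trainingSummary,
         version = model@version),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeUnwrapModel
#' @return \code{readUnwrapModel} returns the \linkS4class{UnwrapModel}.
#' @export
readUnwrapModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("UnwrapModel", weights = as.numeric(j$weights),
      threshold = as.numeric(j$threshold),
      channels = as.character(j$channels),
      trainingSummary = as.list(j$trainingSummary),
      version = as.character(j$version))
}
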