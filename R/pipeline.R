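#' Pipeline configuration
#'
#' Validated bundle of every stage's parameters. All randomness in a
#' pipeline run (noise synthesis, classifier training splits) flows from
#' the single \code{seed}.
#'
#' @param pixelSize um per pixel.
#' @param wavelength illumination wavelength, nm.
#' @param interval frame interval, min.
#' @param alpha specific refractive increment, m^3/kg.
#' @param adherent logical; selects the division-detection mode.
#' @param seed integer.
#' @param sigma,minArea,minOPD,tolerance see
#'   \code{\link{segmentationConfig}}.
#' @param maxDisp,massCutFraction see \code{\link{buildTracks}}.
#' @param vicinityRadius,massWindow,pairWindow,tau,windowMin,threshold,minAmplitude,edgeFrames
#'   see \code{\link{detectDivisions}}.
#' @param horizon asymmetry-rate fit horizon, min.
#' @return A named list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(pixelSize = 1.0, wavelength = 530,
                           interval = 3, alpha = 1.8e-4, adherent = TRUE,
                           seed = 1L, sigma = 2, minArea = 50,
                           minOPD = 10, tolerance = 15, maxDisp = 20,
                           massCutFraction = 0.85, vicinityRadius = 30,
                           massWindow = c(0.35, 0.65),
                           pairWindow = c(0.8, 1.2), tau = 6,
                           windowMin = 30, threshold = 0.7,
                           minAmplitude = 20, edgeFrames = 3,
                           horizon = 60) {
  cfg <- list(pixelSize = pixelSize, wavelength = wavelength,
              interval = interval, alpha = alpha, adherent = adherent,
              seed = as.integer(seed), sigma = sigma, minArea = minArea,
              minOPD = minOPD, tolerance = tolerance, maxDisp = maxDisp,
              massCutFraction = massCutFraction,
              vicinityRadius = vicinityRadius, massWindow = massWindow,
              pairWindow = pairWindow, tau = tau, windowMin = windowMin,
              threshold = threshold, minAmplitude = minAmplitude,
              edgeFrames = edgeFrames, horizon = horizon)
  for (nm in c("pixelSize", "wavelength", "interval", "alpha", "maxDisp",
               "tolerance", "tau", "windowMin", "horizon"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("config field '", nm, "' must be positive", call. = FALSE)
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys match \code{\link{pipelineConfig}}
#'   arguments.
#' @return A \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipelineConfig, vals)
}

## OPD stacks are stored as 32-bit float TIFF pages mapped into [0, 1]
## by a fixed affine transform (the TIFF writer clips outside [0, 1]);
## the transform is recorded in a JSON sidecar next to the stack.
.tiffScale <- 4096
.tiffOffset <- 0.25

#' Write / read a phase movie as multi-page TIFF plus ledger
#'
#' \code{writeMovieTIFF} writes the OPD stack (32-bit float, nm, one page
#' per frame, time order = page order), an intensity stack when present,
#' per-frame ground-truth wrap masks (8-bit), and the ledger plus
#' geometry metadata as JSON. \code{readMovieTIFF} reconstructs the
#' \linkS4class{PhaseMovie} (ledger masses and event times included;
#' wrap masks are restored from the mask stack).
#'
#' @param movie a \linkS4class{PhaseMovie}.
#' @param prefix path prefix; files written are \code{<prefix>_opd.tif},
#'   \code{<prefix>_intensity.tif}, \code{<prefix>_wrapmask.tif} and
#'   \code{<prefix>_meta.json}.
#' @return \code{prefix}, invisibly.
#' @export
writeMovieTIFF <- function(movie, prefix) {
  stopifnot(is(movie, "PhaseMovie"))
  fr <- movie@frames
  enc <- lapply(fr, function(f) f@opd / .tiffScale + .tiffOffset)
  tiff::writeTIFF(enc, paste0(prefix, "_opd.tif"), bits.per.sample = 32)
  hasInt <- all(vapply(fr, function(f) length(f@intensity) > 0,
                       logical(1)))
  if (hasInt) {
    encI <- lapply(fr, function(f) f@intensity / .tiffScale + .tiffOffset)
    tiff::writeTIFF(encI, paste0(prefix, "_intensity.tif"),
                    bits.per.sample = 32)
  }
  gt <- movie@groundTruth
  if (!is.null(gt$wrapMasks) && length(gt$wrapMasks)) {
    tiff::writeTIFF(lapply(gt$wrapMasks, function(m) m * 1),
                    paste0(prefix, "_wrapmask.tif"), bits.per.sample = 8)
  }
  f1 <- fr[[1]]
  meta <- list(
    nFrames = length(fr),
    times = vapply(fr, function(f) f@time, numeric(1)),
    pixelSize = f1@pixelSize, wavelength = f1@wavelength,
    interval = movie@interval, hasIntensity = hasInt,
    tiffScale = .tiffScale, tiffOffset = .tiffOffset,
    ledger = list(masses = gt$masses, events = gt$events,
                  deltaM = gt$deltaM, params = gt$params))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(prefix)
}

#' @rdname writeMovieTIFF
#' @return \code{readMovieTIFF} returns a \linkS4class{PhaseMovie}.
#' @export
readMovieTIFF <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  sc <- meta$tiffScale; off <- meta$tiffOffset
  pages <- tiff::readTIFF(paste0(prefix, "_opd.tif"), all = TRUE)
  ints <- if (isTRUE(meta$hasIntensity))
    tiff::readTIFF(paste0(prefix, "_intensity.tif"), all = TRUE)
  else NULL
  maskPath <- paste0(prefix, "_wrapmask.tif")
  masks <- if (file.exists(maskPath)) {
    lapply(tiff::readTIFF(maskPath, all = TRUE), function(m) m > 0.5)
  } else NULL
  fr <- lapply(seq_along(pages), function(k) {
    PhaseFrame((pages[[k]] - off) * sc,
               intensity = if (!is.null(ints)) (ints[[k]] - off) * sc,
               pixelSize = meta$pixelSize, wavelength = meta$wavelength,
               time = meta$times[k])
  })
  gt <- list(masses = meta$ledger$masses, events = meta$ledger$events,
             deltaM = meta$ledger$deltaM, params = meta$ledger$params,
             wrapMasks = masks)
  new("PhaseMovie", frames = fr, interval = meta$interval,
      groundTruth = gt)
}

## polynomial rolling hash over a character serialization, for manifests
.configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes unwrap (when a model is supplied) -> segmentation ->
#' tracking -> division detection -> partitioning statistics on a phase
#' movie and writes every intermediate table plus a manifest to
#' \code{outDir}. A stage failure aborts with the stage name and frame
#' index; re-running with identical inputs, config and seed gives
#' bit-identical deterministic outputs.
#'
#' @param movie a \linkS4class{PhaseMovie}, or a path prefix for
#'   \code{\link{readMovieTIFF}}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if needed), or NULL to skip
#'   writing.
#' @param model optional \linkS4class{UnwrapModel} enabling the unwrap
#'   stage.
#' @return Invisibly, a list: regions, tracks, events, times (mitotic
#'   timing), records (asymmetry dynamics), series (per-event delta-m),
#'   curves (population summaries), confluence (per frame, percent),
#'   log (stage counts).
#' @export
runPipeline <- function(movie, config = pipelineConfig(), outDir = NULL,
                        model = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.character(movie)) movie <- readMovieTIFF(movie)
  stopifnot(is(movie, "PhaseMovie"))
  fr <- movie@frames
  for (k in seq_along(fr)) {
    if (!all(is.finite(fr[[k]]@opd)))
      stop("stage validate: corrupted frame ", k,
           " (non-finite OPD)", call. = FALSE)
  }
  scfg <- segmentationConfig(sigma = config$sigma,
                             minArea = config$minArea,
                             minOPD = config$minOPD,
                             tolerance = config$tolerance,
                             alpha = config$alpha)
  stageLog <- list()

  if (!is.null(model)) {
    for (k in seq_along(fr)) {
      mask <- withCallingHandlers(
        detectWrapRegions(fr[[k]], model),
        warning = function(w) invokeRestart("muffleWarning"))
      fr[[k]] <- correctPhase(fr[[k]], mask)
    }
    stageLog$unwrap <- list(framesCorrected = length(fr))
  }

  regions <- vector("list", length(fr))
  confluence <- numeric(length(fr))
  for (k in seq_along(fr)) {
    lab <- tryCatch(segmentCells(fr[[k]], scfg), error = function(e)
      stop("stage segment: frame ", k, ": ", conditionMessage(e),
           call. = FALSE))
    confluence[k] <- computeConfluence(lab)
    rg <- measureRegions(lab, fr[[k]], scfg)
    if (nrow(rg)) rg <- cbind(frame = k, rg)
    regions[[k]] <- rg
  }
  regions <- do.call(rbind, regions[vapply(regions, nrow,
                                           integer(1)) > 0])
  if (is.null(regions))
    regions <- cbind(frame = integer(0),
                     measureRegions(matrix(0L, 1, 1),
                                    PhaseFrame(matrix(0, 1, 1)), scfg))
  stageLog$segment <- list(nRegions = nrow(regions))

  tracks <- buildTracks(regions, maxDisp = config$maxDisp,
                        massCutFraction = config$massCutFraction)
  stageLog$track <- list(nTracks = length(unique(tracks$track_id)))

  events <- detectDivisions(
    tracks, mode = if (config$adherent) "adherent" else "nonadherent",
    vicinityRadius = config$vicinityRadius,
    massWindow = config$massWindow, pairWindow = config$pairWindow,
    tau = config$tau, windowMin = config$windowMin,
    threshold = config$threshold, minAmplitude = config$minAmplitude,
    edgeFrames = config$edgeFrames)
  stageLog$detect <- list(nEvents = nrow(events),
                          nRejected = nrow(attr(events, "log")))

  series <- lapply(seq_len(nrow(events)), function(i)
    deltaMSeries(events[i, ], tracks))
  records <- if (nrow(events)) do.call(rbind, lapply(
    seq_len(nrow(events)), function(i)
      asymmetryDynamics(series[[i]], events$event_id[i],
                        horizon = config$horizon)))
  else data.frame()
  times <- if (nrow(events)) measureDivisionTimes(events)
  else data.frame()

  curves <- NULL
  if (nrow(events)) {
    massSamples <- do.call(rbind, lapply(seq_len(nrow(events)),
                                         function(i) {
      ev <- events[i, ]
      rel <- lapply(c(ev$parent_track, ev$d1_track, ev$d2_track),
                    function(tid) {
        tr <- tracks[tracks$track_id == tid, ]
        data.frame(track = tid, time_rel = tr$t_min - ev$t_furrow_min,
                   mass = tr$mass_pg)
      })
      do.call(rbind, rel)
    }))
    curves <- populationCurves(series, massSamples)
  }

  result <- list(regions = regions, tracks = tracks, events = events,
                 times = times, records = records, series = series,
                 curves = curves, confluence = confluence,
                 log = stageLog)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, nm) utils::write.csv(
      df, file.path(outDir, nm), row.names = FALSE)
    wr(regions, "regions.csv")
    wr(tracks, "tracks.csv")
    evOut <- events
    attr(evOut, "log") <- NULL
    wr(evOut, "events.csv")
    wr(attr(events, "log"), "division_log.csv")
    if (nrow(events)) {
      wr(records, "asymmetry.csv")
      wr(times, "division_times.csv")
      wr(curves$asymmetry, "population_asymmetry.csv")
      if (!is.null(curves$cv)) wr(curves$cv, "population_cv.csv")
      if (!is.null(curves$growthVsTime))
        wr(curves$growthVsTime, "growth_vs_time.csv")
      if (!is.null(curves$growthVsMass))
        wr(curves$growthVsMass, "growth_vs_mass.csv")
      utils::write.csv(heatmapMatrix(series, records, signed = TRUE),
                       file.path(outDir, "heatmap_signed.csv"))
      utils::write.csv(heatmapMatrix(series, records, signed = FALSE),
                       file.path(outDir, "heatmap_abs.csv"))
    }
    wr(data.frame(frame = seq_along(confluence),
                  confluence_pct = confluence), "confluence.csv")
    manifest <- list(
      package = "massdivide",
      version = as.character(utils::packageVersion("massdivide")),
      configHash = .configHash(unclass(config)),
      seed = config$seed,
      nFrames = length(fr), counts = stageLog)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
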