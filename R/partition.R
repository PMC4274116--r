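#' Daughter-cell mass partitioning asymmetry
#'
#' \eqn{\Delta m = 2 |m_{d1} - m_{d2}| / (m_{d1} + m_{d2})}: the
#' pair-normalized daughter mass difference, 0 for a perfectly symmetric
#' split and 2 in the limit of one daughter carrying everything. The
#' signed form drops the absolute value (daughter 1 is defined as the
#' initially heavier daughter, so the signed value at t = 0 is
#' non-negative). Scale-invariant: multiplying both masses by k leaves
#' it unchanged.
#'
#' @param m1,m2 daughter masses, pg (vectorized).
#' @param signed logical; keep the sign of m1 - m2.
#' @return Dimensionless asymmetry in [0, 2] (absolute form).
#' @examples
#' deltaM(300, 100)        # 1.0
#' deltaM(200, 200)        # 0
#' @export
deltaM <- function(m1, m2, signed = FALSE) {
  tot <- m1 + m2
  if (any(tot <= 0)) stop("pair mass must be positive", call. = FALSE)
  d <- 2 * (m1 - m2) / tot
  if (signed) d else abs(d)
}

#' Asymmetry dynamics of a division event
#'
#' Initial signed asymmetry, the least-squares rate of change of the
#' signed asymmetry over the post-furrow fit horizon, and the
#' four-quadrant inverse-tangent ordering key
#' \eqn{\theta = \mathrm{atan2}(r, \Delta m_0)} that maps both the
#' initial asymmetry and its trend onto one axis.
#'
#' @param series a \code{\link{deltaMSeries}} data.frame (or the
#'   generator's \code{\link{trueDeltaMSeries}}).
#' @param eventId identifier carried into the record.
#' @param horizon fit horizon after the furrow, min (default 60).
#' @return One-row data.frame: event_id, delta_m0, rate, theta, n_frames,
#'   usable (FALSE when fewer than 3 post-furrow frames exist; such
#'   records are excluded from heatmaps).
#' @export
asymmetryDynamics <- function(series, eventId = 1L, horizon = 60) {
  fit <- series[series$time_rel >= 0 & series$time_rel <= horizon, ,
                drop = FALSE]
  if (nrow(fit) < 3) {
    return(data.frame(event_id = eventId, delta_m0 = NA_real_,
                      rate = NA_real_, theta = NA_real_,
                      n_frames = nrow(fit), usable = FALSE))
  }
  dm0 <- fit$delta_m_signed[which.min(fit$time_rel)]
  r <- unname(stats::coef(stats::lm(delta_m_signed ~ time_rel,
                                    data = fit))[2])
  data.frame(event_id = eventId, delta_m0 = dm0, rate = r,
             theta = atan2(r, dm0), n_frames = nrow(fit), usable = TRUE)
}

#' Order events for the asymmetry heatmap
#'
#' Sorts asymmetry records by the ordering key \eqn{atan2(r, \Delta m_0)}
#' (descending), which arranges the population into contiguous behavior
#' groups: symmetric divisions that stay symmetric, asymmetric ones whose
#' asymmetry decreases, asymmetric stable ones, and symmetric ones whose
#' asymmetry grows. Ties break on event id, so the order is stable under
#' input shuffling.
#'
#' @param records data.frame of \code{\link{asymmetryDynamics}} rows.
#' @return Integer permutation of the row indices of usable records.
#' @export
orderEvents <- function(records) {
  usable <- which(is.finite(records$theta))
  usable[order(-records$theta[usable], records$event_id[usable])]
}

#' Coefficient of variation
#' @param x numeric sample.
#' @return sd(x)/mean(x).
#' @export
coefficientOfVariation <- function(x) stats::sd(x) / mean(x)

.sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Population summaries of division asymmetry, mass dispersion and growth
#'
#' Computes (i) mean absolute asymmetry versus time after the furrow with
#' s.e.m. over events per bin, (ii) the cell-cycle-synchronized mass
#' coefficient of variation per 10-minute bin of division-aligned time
#' over -90..90 min, and (iii) binned growth rates (finite differences of
#' track mass over time) versus aligned time and versus relative mass.
#' Empty bins are reported as missing rows, not zeros.
#'
#' @param seriesList list of \code{\link{deltaMSeries}} data.frames, one
#'   per event.
#' @param massSamples optional data.frame with columns \code{time_rel}
#'   (division-aligned time, min), \code{mass} (pg) and \code{track}
#'   supplying mass and growth samples for (ii) and (iii).
#' @param binWidth asymmetry bin width, min (default 10).
#' @param cvRange aligned-time range for the CV bins (default -90..90).
#' @param growthBinWidth time bin width for growth rates, min
#'   (default 60).
#' @return list with data.frames \code{asymmetry} (t_mid, mean_abs_dm,
#'   sem, n), \code{cv} (t_mid, cv, n), \code{growthVsTime} (t_mid,
#'   growth_pg_min, sem, n), \code{growthVsMass} (mass_mid,
#'   growth_pg_min, sem, n).
#' @export
populationCurves <- function(seriesList, massSamples = NULL,
                             binWidth = 10, cvRange = c(-90, 90),
                             growthBinWidth = 60) {
  stopifnot(length(seriesList) >= 1)
  allDm <- do.call(rbind, lapply(seriesList, function(s)
    s[, c("time_rel", "delta_m_abs")]))
  edges <- seq(floor(min(allDm$time_rel)),
               ceiling(max(allDm$time_rel)) + binWidth, by = binWidth)
  bin <- cut(allDm$time_rel, edges, right = FALSE)
  asym <- do.call(rbind, lapply(split(allDm$delta_m_abs, bin),
                                function(v) {
    if (!length(v)) return(NULL)
    data.frame(mean_abs_dm = mean(v), sem = .sem(v), n = length(v))
  }))
  mids <- edges[-length(edges)] + binWidth / 2
  asym <- cbind(t_mid = mids[match(rownames(asym), levels(bin))], asym)
  rownames(asym) <- NULL

  cv <- growthT <- growthM <- NULL
  if (!is.null(massSamples) && nrow(massSamples) > 0) {
    cvEdges <- seq(cvRange[1], cvRange[2], by = 10)
    inCv <- massSamples$time_rel >= cvRange[1] &
      massSamples$time_rel < cvRange[2]
    cvBin <- cut(massSamples$time_rel[inCv], cvEdges, right = FALSE)
    cvRows <- lapply(levels(cvBin), function(lv) {
      v <- massSamples$mass[inCv][cvBin == lv]
      if (length(v) < 2) return(NULL)
      data.frame(lv = lv, cv = coefficientOfVariation(v), n = length(v))
    })
    cv <- do.call(rbind, cvRows)
    if (!is.null(cv)) {
      cv$t_mid <- (cvEdges[-length(cvEdges)] + 5)[match(cv$lv,
                                                        levels(cvBin))]
      cv <- cv[, c("t_mid", "cv", "n")]
    }

    ## finite-difference growth rates within tracks
    gr <- do.call(rbind, lapply(split(massSamples,
                                      massSamples$track), function(tr) {
      tr <- tr[order(tr$time_rel), ]
      if (nrow(tr) < 2) return(NULL)
      data.frame(time_rel = (tr$time_rel[-1] + tr$time_rel[-nrow(tr)]) / 2,
                 mass = (tr$mass[-1] + tr$mass[-nrow(tr)]) / 2,
                 rate = diff(tr$mass) / diff(tr$time_rel))
    }))
    if (!is.null(gr) && nrow(gr)) {
      gtEdges <- seq(floor(min(gr$time_rel) / growthBinWidth) *
                       growthBinWidth,
                     max(gr$time_rel) + growthBinWidth,
                     by = growthBinWidth)
      gtBin <- cut(gr$time_rel, gtEdges, right = FALSE)
      growthT <- do.call(rbind, lapply(levels(gtBin), function(lv) {
        v <- gr$rate[gtBin == lv]
        if (!length(v)) return(NULL)
        data.frame(t_mid = gtEdges[match(lv, levels(gtBin))] +
                     growthBinWidth / 2,
                   growth_pg_min = mean(v), sem = .sem(v),
                   n = length(v))
      }))
      mEdges <- pretty(gr$mass, n = 8)
      mBin <- cut(gr$mass, mEdges, right = FALSE)
      growthM <- do.call(rbind, lapply(levels(mBin), function(lv) {
        v <- gr$rate[mBin == lv]
        if (!length(v)) return(NULL)
        i <- match(lv, levels(mBin))
        data.frame(mass_mid = (mEdges[i] + mEdges[i + 1]) / 2,
                   growth_pg_min = mean(v), sem = .sem(v),
                   n = length(v))
      }))
    }
  }
  list(asymmetry = asym, cv = cv, growthVsTime = growthT,
       growthVsMass = growthM)
}

#' Heatmap matrix of per-event asymmetry versus time
#'
#' Events (rows, in \code{\link{orderEvents}} order) by time bins
#' (columns); cells hold the signed or absolute asymmetry, NA where an
#' event has no frame in a bin.
#'
#' @param seriesList list of \code{\link{deltaMSeries}} data.frames.
#' @param records matching \code{\link{asymmetryDynamics}} rows.
#' @param binWidth min (default one frame interval, 3).
#' @param signed signed or absolute values (both views are meaningful;
#'   default signed).
#' @return Numeric matrix with event ids as rownames.
#' @export
heatmapMatrix <- function(seriesList, records, binWidth = 3,
                          signed = TRUE) {
  ord <- orderEvents(records)
  if (!length(ord)) return(matrix(numeric(0), 0, 0))
  tmax <- max(vapply(seriesList, function(s)
    max(c(s$time_rel, 0)), numeric(1)))
  edges <- seq(0, tmax + binWidth, by = binWidth)
  out <- matrix(NA_real_, length(ord), length(edges) - 1,
                dimnames = list(records$event_id[ord],
                                utils::head(edges, -1)))
  col <- if (signed) "delta_m_signed" else "delta_m_abs"
  for (i in seq_along(ord)) {
    s <- seriesList[[ord[i]]]
    s <- s[s$time_rel >= 0, , drop = FALSE]
    b <- findInterval(s$time_rel, edges, rightmost.closed = TRUE)
    ok <- b >= 1 & b <= ncol(out)
    out[i, b[ok]] <- s[[col]][ok]
  }
  out
}

#' Welch's two-sample t test (unequal variances and sample sizes)
#'
#' @param a,b numeric samples, each of size >= 2.
#' @return list: statistic, df (Welch-Satterthwaite), p.value
#'   (two-sided).
#' @export
welchTTest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = FALSE,
                      alternative = "two.sided")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' F test of a least-squares linear regression against a constant model
#'
#' Tests the null hypothesis that the linear fit does no better than a
#' single constant term: \eqn{F = (SSE_0 - SSE_1) / (SSE_1 / (n - 2))}
#' on (1, n - 2) degrees of freedom. An exact fit (zero residual) is
#' reported as p = 0.
#'
#' @param x,y numeric vectors, n >= 3; x must not be constant.
#' @return list: slope, statistic, p.value.
#' @export
regressionFTest <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sse1 <- sum(stats::resid(fit)^2)
  sse0 <- sum((y - mean(y))^2)
  slope <- unname(stats::coef(fit)[2])
  if (sse1 <= .Machine$double.eps * sse0 || sse1 == 0)
    return(list(slope = slope, statistic = Inf, p.value = 0))
  Fstat <- (sse0 - sse1) / (sse1 / (n - 2))
  list(slope = slope, statistic = Fstat,
       p.value = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE))
}
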