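## Frame-to-frame track linking in the colloid-tracking spirit: a global
## one-to-one assignment minimizing total squared centroid displacement,
## with a fixed cost for leaving a region unmatched. No installed package
## provides a min-cost assignment solver, so the Jonker-Volgenant
## shortest-augmenting-path algorithm is implemented here.

#' Minimum-cost assignment (Jonker-Volgenant)
#'
#' Solves the rectangular linear assignment problem by shortest
#' augmenting paths with dual potentials, O(n^2 m).
#'
#' @param cost numeric cost matrix (rows <= columns; transposed
#'   internally otherwise). Finite entries only.
#' @return Integer vector \code{a} of length \code{nrow(cost)} with
#'   \code{a[i]} the column assigned to row i.
#' @export
solveAssignment <- function(cost) {
  if (nrow(cost) > ncol(cost)) {
    byCol <- solveAssignment(t(cost))
    out <- integer(nrow(cost))
    out[byCol] <- seq_along(byCol)
    return(out)
  }
  n <- nrow(cost); m <- ncol(cost)
  INF <- Inf
  u <- numeric(n + 1)
  v <- numeric(m + 1)            # index j+1 <-> column j, col 0 virtual
  p <- integer(m + 1)            # row assigned to column (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m)
    used <- logical(m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- which(!used[-1])
      cur <- cost[i0, free] - u[i0 + 1] - v[free + 1]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd] + 1] <- j0
      delta <- min(minv[free])
      j1 <- free[which.min(minv[free])]
      usedIdx <- which(used)
      u[p[usedIdx] + 1] <- u[p[usedIdx] + 1] + delta
      v[usedIdx] <- v[usedIdx] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

#' Link regions between two consecutive frames
#'
#' One-to-one assignment minimizing total squared centroid displacement
#' among pairs within \code{maxDisp}; every unmatched region (a track
#' start or end) carries a fixed cost of \code{maxDisp^2}. Regions are
#' processed in label order, so equal-cost ties resolve toward lower
#' label ids.
#'
#' @param regionsA,regionsB data.frames with columns \code{label},
#'   \code{x_um}, \code{y_um} (e.g. from \code{\link{measureRegions}}).
#' @param maxDisp maximum linking displacement, um.
#' @return data.frame with columns \code{from}, \code{to} (labels in A
#'   and B); zero rows when nothing links.
#' @export
linkFrames <- function(regionsA, regionsB, maxDisp = 20) {
  stopifnot(maxDisp > 0)
  emptyLink <- data.frame(from = integer(0), to = integer(0))
  n <- nrow(regionsA); m <- nrow(regionsB)
  if (n == 0 || m == 0) return(emptyLink)
  regionsA <- regionsA[order(regionsA$label), , drop = FALSE]
  regionsB <- regionsB[order(regionsB$label), , drop = FALSE]
  D2 <- outer(regionsA$x_um, regionsB$x_um, "-")^2 +
    outer(regionsA$y_um, regionsB$y_um, "-")^2
  BIG <- maxDisp^2 * (n + m + 1) + sum(D2[D2 <= maxDisp^2]) + 1
  C <- matrix(BIG, n + m, m + n)
  C[seq_len(n), seq_len(m)] <- ifelse(D2 <= maxDisp^2, D2, BIG)
  for (i in seq_len(n)) C[i, m + i] <- maxDisp^2
  for (j in seq_len(m)) C[n + j, j] <- maxDisp^2
  C[(n + 1):(n + m), (m + 1):(m + n)] <- 0
  a <- solveAssignment(C)
  keep <- which(seq_len(n + m) <= n & a <= m)
  keep <- keep[D2[cbind(keep, a[keep])] <= maxDisp^2]
  data.frame(from = regionsA$label[keep], to = regionsB$label[a[keep]])
}

#' Build cell tracks across a movie
#'
#' Links per-frame regions into time-ordered tracks. The linking cost is
#' purely positional; on top of the assignment, a link is vetoed when the
#' successor's mass falls below \code{massCutFraction} of the current
#' mass, so a dividing parent's track ends at the furrow frame and both
#' daughters start fresh tracks. There is no gap closing: a missed frame
#' terminates a track.
#'
#' @param regions data.frame of per-frame region measurements carrying a
#'   \code{frame} column plus the \code{\link{measureRegions}} columns.
#' @param maxDisp maximum linking displacement per frame, um (default 20).
#' @param massCutFraction mass-drop veto fraction (default 0.85).
#' @return data.frame of track points: track_id, frame, t_min, label,
#'   mass_pg, area_um2, perimeter_px, mean_phase_nm, shape_factor, x_um,
#'   y_um. Track ids are assigned deterministically in (frame, label)
#'   order of each track's first point.
#' @export
buildTracks <- function(regions, maxDisp = 20, massCutFraction = 0.85) {
  cols <- c("track_id", "frame", "t_min", "label", "mass_pg", "area_um2",
            "perimeter_px", "mean_phase_nm", "shape_factor", "x_um",
            "y_um")
  if (is.null(regions) || nrow(regions) == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
    return(out)
  }
  stopifnot(all(c("frame", "label", "t_min", "mass_pg", "x_um", "y_um")
                %in% names(regions)))
  frameIds <- sort(unique(regions$frame))
  ft <- vapply(frameIds,
               function(f) regions$t_min[regions$frame == f][1], numeric(1))
  if (any(diff(ft) <= 0))
    stop("frames are not time-ordered", call. = FALSE)

  regions <- regions[order(regions$frame, regions$label), , drop = FALSE]
  regions$track_id <- NA_integer_
  nextId <- 1L
  prevIdx <- which(regions$frame == frameIds[1])
  for (k in prevIdx) {
    regions$track_id[k] <- nextId
    nextId <- nextId + 1L
  }
  for (fi in seq_along(frameIds)[-1]) {
    curIdx <- which(regions$frame == frameIds[fi])
    prev <- regions[prevIdx, , drop = FALSE]
    cur <- regions[curIdx, , drop = FALSE]
    links <- linkFrames(prev, cur, maxDisp)
    assigned <- rep(FALSE, length(curIdx))
    if (nrow(links)) for (r in seq_len(nrow(links))) {
      pi <- prevIdx[match(links$from[r], prev$label)]
      ci <- curIdx[match(links$to[r], cur$label)]
      ## division veto: a cell cannot lose this much mass in one frame
      if (regions$mass_pg[ci] <
          massCutFraction * regions$mass_pg[pi]) next
      regions$track_id[ci] <- regions$track_id[pi]
      assigned[match(links$to[r], cur$label)] <- TRUE
    }
    for (ci in curIdx[!assigned]) {
      regions$track_id[ci] <- nextId
      nextId <- nextId + 1L
    }
    prevIdx <- curIdx
  }
  rownames(regions) <- NULL
  keep <- intersect(cols, names(regions))
  regions[, keep]
}
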