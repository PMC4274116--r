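#' Random-walker segmentation on a 4-connected pixel grid
#'
#' Grady-style random-walker segmentation for two labels. Edge weights
#' between 4-neighbours are \eqn{w = \exp(-\beta (g_i - g_j)^2)} on the
#' range-normalized guidance image; the probability that a walker started
#' at each unseeded pixel first reaches a foreground seed is the solution
#' of a sparse linear system in the graph Laplacian.
#'
#' @param field numeric guidance matrix (any range; normalized
#'   internally), or a list of such matrices: with several channels the
#'   squared gradients add, so the walker respects the sharpest cliff in
#'   any channel.
#' @param fgSeeds,bgSeeds logical matrices marking foreground/background
#'   seed pixels; they must be disjoint and non-empty.
#' @param beta edge-weight sharpness.
#' @param eps small weight floor keeping the graph connected.
#' @return Matrix of foreground probabilities in [0, 1]; seed pixels carry
#'   exactly 1 (foreground) or 0 (background).
#' @export
randomWalkerSegment <- function(field, fgSeeds, bgSeeds, beta = 90,
                                eps = 1e-6) {
  if (!is.list(field)) field <- list(field)
  nr <- nrow(field[[1]]); nc <- ncol(field[[1]])
  stopifnot(identical(dim(fgSeeds), dim(field[[1]])),
            identical(dim(bgSeeds), dim(field[[1]])),
            any(fgSeeds), any(bgSeeds), !any(fgSeeds & bgSeeds))
  norm1 <- function(f) {
    rng <- range(f)
    if (diff(rng) > 0) (f - rng[1]) / diff(rng) else f * 0
  }
  gs <- lapply(field, norm1)

  n <- nr * nc
  idx <- matrix(seq_len(n), nr, nc)
  vFrom <- c(as.vector(idx[-nr, ]), as.vector(idx[, -nc]))
  vTo <- c(as.vector(idx[-1, ]), as.vector(idx[, -1]))
  d2 <- 0
  for (g in gs)
    d2 <- d2 + c(as.vector(g[-nr, ] - g[-1, ]),
                 as.vector(g[, -nc] - g[, -1]))^2
  w <- exp(-beta * d2) + eps

  W <- Matrix::sparseMatrix(i = c(vFrom, vTo), j = c(vTo, vFrom),
                            x = c(w, w), dims = c(n, n))
  L <- Matrix::Diagonal(n, Matrix::rowSums(W)) - W

  seeded <- which(fgSeeds | bgSeeds)
  b <- as.numeric(fgSeeds[seeded])
  uns <- which(!(fgSeeds | bgSeeds))

  prob <- matrix(0, nr, nc)
  prob[fgSeeds] <- 1
  if (length(uns)) {
    x <- Matrix::solve(L[uns, uns, drop = FALSE],
                       -L[uns, seeded, drop = FALSE] %*% b)
    prob[uns] <- pmin(pmax(as.numeric(x), 0), 1)
  }
  prob
}
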