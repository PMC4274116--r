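## Small image-filter helpers used by the pixel-statistic bank.
## All filters use replicate (nearest-pixel) boundary handling so that a
## constant image produces exactly zero edge/texture response.

## shift image by (di, dj) with replicate padding; positive di moves
## content down, positive dj moves it right
.shift <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - di, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dj, 1L), nc)
  m[ri, ci, drop = FALSE]
}

## convolve with an arbitrary small kernel by shift-and-add
.conv2 <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  cr <- (kr + 1) %/% 2; cc <- (kc + 1) %/% 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    k <- kernel[i, j]
    if (k != 0) out <- out + k * .shift(m, cr - i, cc - j)
  }
  out
}

## separable 1-D convolution along rows/cols with replicate padding
.conv1 <- function(m, k, along = c("row", "col")) {
  along <- match.arg(along)
  half <- (length(k) - 1) %/% 2
  out <- matrix(0, nrow(m), ncol(m))
  for (o in seq_along(k)) {
    d <- o - half - 1
    out <- out + k[o] *
      (if (along == "row") .shift(m, d, 0) else .shift(m, 0, d))
  }
  out
}

.gaussKernel1d <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

.gaussSmooth <- function(m, sigma) {
  k <- .gaussKernel1d(sigma)
  .conv1(.conv1(m, k, "row"), k, "col")
}

.boxMean <- function(m, size) {
  k <- rep(1 / size, size)
  .conv1(.conv1(m, k, "row"), k, "col")
}

.boxVar <- function(m, size) {
  pmax(.boxMean(m * m, size) - .boxMean(m, size)^2, 0)
}

## grayscale dilation/erosion over a structuring element given as a list
## of (di, dj) offsets
.morphMax <- function(m, offsets) {
  out <- m
  for (o in offsets) out <- pmax(out, .shift(m, o[1], o[2]))
  out
}

.morphMin <- function(m, offsets) {
  out <- m
  for (o in offsets) out <- pmin(out, .shift(m, o[1], o[2]))
  out
}

.offsetsBox3 <- local({
  g <- expand.grid(di = -1:1, dj = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0), ]
  lapply(seq_len(nrow(g)), function(i) c(g$di[i], g$dj[i]))
})

.offsetsDiamond3 <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))

## exact 3x3 median via a 19-comparator sorting network, vectorized over
## all pixels (no installed package provides a 2-D median filter on
## arbitrary-range matrices)
.median3 <- function(m) {
  p <- list(
    .shift(m, -1, -1), .shift(m, -1, 0), .shift(m, -1, 1),
    .shift(m,  0, -1), m,                .shift(m,  0, 1),
    .shift(m,  1, -1), .shift(m,  1, 0), .shift(m,  1, 1))
  swap <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  ## Paeth's 9-element median network
  swap(1, 2); swap(4, 5); swap(7, 8); swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 2); swap(4, 5); swap(7, 8); swap(1, 4); swap(4, 7); swap(1, 4)
  swap(3, 6); swap(6, 9); swap(3, 6); swap(2, 5); swap(5, 8); swap(2, 5)
  swap(5, 3); swap(5, 7); swap(3, 5)
  p[[5]]
}

.sobelX <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
.sobelY <- t(.sobelX)
.laplace4 <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
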