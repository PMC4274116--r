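## Unit conversions between integrated optical path difference and dry mass.
##
## OPD is carried in nm and pixel areas in um^2; the specific refractive
## increment alpha is in m^3/kg. 1 nm * 1 um^2 = 1e-21 m^3, and 1 kg =
## 1e15 pg, so mass_pg = sum(OPD_nm) * pixelArea_um2 * 1e-6 / alpha.

#' Convert an integrated OPD sum to dry mass
#'
#' Dry mass is proportional to the integrated optical path difference over
#' the cell footprint through the specific refractive increment
#' \eqn{\alpha}: \eqn{m = (1/\alpha) \int OPD \, dA}.
#'
#' @param opdSum sum of OPD values over the footprint, nm.
#' @param pixelSize pixel pitch, micrometers.
#' @param alpha specific refractive increment, m^3/kg
#'   (default 1.8e-4, a whole-cell average).
#' @return Dry mass in picograms.
#' @examples
#' ## a uniform 100 um^2 footprint at 100 nm OPD carries 55.6 pg
#' opdSumToMassPg(100 * 100, pixelSize = 1, alpha = 1.8e-4)
#' @export
opdSumToMassPg <- function(opdSum, pixelSize = 1.0, alpha = 1.8e-4) {
  stopifnot(alpha > 0, pixelSize > 0)
  opdSum * pixelSize^2 * 1e-6 / alpha
}

#' @rdname opdSumToMassPg
#' @param massPg dry mass, pg.
#' @return \code{massPgToOpdSum} returns the OPD sum (nm) that a mass
#'   corresponds to at the given pixel size.
#' @export
massPgToOpdSum <- function(massPg, pixelSize = 1.0, alpha = 1.8e-4) {
  massPg * alpha * 1e6 / pixelSize^2
}

## logistic used for rounding/flattening transitions and matched filtering
.logistic <- function(x) 1 / (1 + exp(-x))

## run code with a temporarily fixed RNG seed, restoring global state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
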