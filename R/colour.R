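# RGB -> XYZ -> CIE L*a*b* conversion chain.
#
# The XYZ transform uses the classic CIE RGB primaries matrix; the Lab stage
# uses the standard cube-root compression with breakpoint 0.008856 and linear
# coefficients 7.787 and 16/116 below it.

# Fixed RGB -> XYZ matrix (rows X, Y, Z; columns R, G, B).
.rgb2xyzMatrix <- matrix(c(
  0.490, 0.310, 0.200,
  0.177, 0.813, 0.011,
  0.000, 0.010, 0.990), nrow = 3, byrow = TRUE,
  dimnames = list(c("X", "Y", "Z"), c("R", "G", "B")))

.labBreak <- 0.008856

#' Equal-energy reference white
#'
#' The tristimulus values of RGB = (1, 1, 1) under the conversion matrix,
#' i.e. its row sums (1.000, 1.001, 1.000). This is the default white point:
#' with it, pure white maps to L* = 100, a* = b* = 0 exactly.
#'
#' @return named numeric(3) with Xn, Yn, Zn
#' @export
equalEnergyWhite <- function() {
  stats::setNames(rowSums(.rgb2xyzMatrix), c("Xn", "Yn", "Zn"))
}

.checkRgbArray <- function(rgb, maxValue) {
  if (is.matrix(rgb)) rgb <- array(rgb, dim = c(dim(rgb), 1L))
  d <- dim(rgb)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("rgb must be a height x width x 3 array")
  if (!all(is.finite(rgb)))
    stop("rgb contains non-finite pixel values")
  if (maxValue <= 0) stop("maxValue must be positive")
  rgb
}

#' Convert an RGB raster to tristimulus XYZ
#'
#' Channels are normalized to [0, 1] by \code{maxValue} and multiplied by the
#' fixed 3 x 3 CIE conversion matrix. All matrix coefficients are
#' non-negative, so valid RGB input yields non-negative X, Y, Z.
#'
#' @param rgb numeric array, height x width x 3, values in [0, maxValue].
#' @param maxValue channel maximum of the input coding (255 for 8-bit).
#' @return numeric array of the same shape with planes X, Y, Z.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' rgbToXyz(px)[1, 1, ]  # (0.490, 0.177, 0.000)
#' @export
rgbToXyz <- function(rgb, maxValue = 255) {
  rgb <- .checkRgbArray(rgb, maxValue)
  d <- dim(rgb)
  flat <- matrix(rgb, ncol = 3L) / maxValue
  xyz <- flat %*% t(.rgb2xyzMatrix)
  array(xyz, dim = d)
}

# f(t): cube root above the breakpoint, matched linear segment below, chosen
# so value and slope agree at the breakpoint (intercept 16/116 by convention).
.labF <- function(t) {
  ifelse(t > .labBreak, t^(1/3), 7.787 * t + 16 / 116)
}

#' Convert tristimulus XYZ to CIE L*a*b*
#'
#' L* = 116 (Y/Yn)^(1/3) - 16 for Y/Yn above 0.008856. Below the breakpoint
#' the default is the standard matched linear segment 903.3 (Y/Yn)
#' (continuous with the upper branch); \code{lowBranch = "as_printed"}
#' instead applies 903.3 (Y/Yn)^(1/3), a variant sometimes seen in the
#' agronomy literature, which is discontinuous at the breakpoint and can
#' exceed 100. a* = 500 [f(X/Xn) - f(Y/Yn)] and b* = 200 [f(Y/Yn) - f(Z/Zn)].
#'
#' @param xyz numeric array, height x width x 3 (planes X, Y, Z).
#' @param white numeric(3) strictly positive reference white (Xn, Yn, Zn).
#' @param lowBranch "linear" (default) or "as_printed"; see Details.
#' @return a \linkS4class{LabImage}
#' @export
xyzToLab <- function(xyz, white = equalEnergyWhite(),
                     lowBranch = c("linear", "as_printed")) {
  lowBranch <- match.arg(lowBranch)
  if (length(white) != 3L || any(!is.finite(white)) || any(white <= 0))
    stop("white point must be three strictly positive finite values")
  d <- dim(xyz)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("xyz must be a height x width x 3 array")
  if (!all(is.finite(xyz))) stop("xyz contains non-finite values")

  xr <- xyz[, , 1L] / white[1L]
  yr <- xyz[, , 2L] / white[2L]
  zr <- xyz[, , 3L] / white[3L]

  Lstar <- ifelse(yr > .labBreak,
                  116 * yr^(1/3) - 16,
                  if (lowBranch == "linear") 903.3 * yr else 903.3 * yr^(1/3))
  # guard against tiny negative round-off at yr ~ 1
  if (lowBranch == "linear") Lstar <- pmin(pmax(Lstar, 0), 100)
  astar <- 500 * (.labF(xr) - .labF(yr))
  bstar <- 200 * (.labF(yr) - .labF(zr))

  out <- array(c(Lstar, astar, bstar), dim = c(d[1L], d[2L], 3L))
  new("LabImage", data = out, whitePoint = unname(as.numeric(white)),
      lowBranch = lowBranch)
}

#' Convert an RGB raster to CIE L*a*b*
#'
#' Composition of \code{\link{rgbToXyz}} and \code{\link{xyzToLab}}. This is
#' the working colour representation of the classifier: L*a*b* separates
#' lightness from the green-red and blue-yellow axes and is less sensitive to
#' the illumination variability of outdoor field photographs than RGB.
#'
#' @inheritParams rgbToXyz
#' @inheritParams xyzToLab
#' @return a \linkS4class{LabImage}
#' @examples
#' img <- array(runif(2 * 2 * 3, 0, 255), dim = c(2, 2, 3))
#' lab <- rgbToLab(img)
#' range(labData(lab)[, , 1])  # L* within [0, 100]
#' @export
rgbToLab <- function(rgb, white = equalEnergyWhite(), maxValue = 255,
                     lowBranch = c("linear", "as_printed")) {
  xyzToLab(rgbToXyz(rgb, maxValue = maxValue), white = white,
           lowBranch = match.arg(lowBranch))
}
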