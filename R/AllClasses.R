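#' @import methods
NULL

#' LabImage: a CIE L*a*b* raster
#'
#' Holds a height x width x 3 array of per-pixel (L*, a*, b*) values together
#' with the reference white point and the lightness low-branch convention used
#' during conversion. L* is perceived lightness in [0, 100]; a* and b* are the
#' green-red and blue-yellow opponent axes (roughly within [-110, 110] for
#' 8-bit input).
#'
#' @slot data numeric array, dim = c(height, width, 3), planes L*, a*, b*.
#' @slot whitePoint numeric(3), reference-white tristimulus (Xn, Yn, Zn), > 0.
#' @slot lowBranch character, "linear" or "as_printed"; the formula used for
#'   L* when Y/Yn falls at or below the 0.008856 breakpoint.
#' @exportClass LabImage
setClass("LabImage",
  representation(data = "array", whitePoint = "numeric", lowBranch = "character"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L || d[3] != 3L)
      return("data must be a height x width x 3 array")
    if (d[1] < 1L || d[2] < 1L)
      return("image must have at least one pixel")
    if (!all(is.finite(object@data)))
      return("Lab values must be finite")
    if (length(object@whitePoint) != 3L || any(object@whitePoint <= 0))
      return("white point must be three strictly positive values")
    if (!object@lowBranch %in% c("linear", "as_printed"))
      return("lowBranch must be 'linear' or 'as_printed'")
    if (object@lowBranch == "linear") {
      L <- object@data[, , 1L]
      if (min(L) < -1e-6 || max(L) > 100 + 1e-6)
        return("L* must lie within [0, 100]")
    }
    TRUE
  })

#' GreyHistogram: discrete grey-level histogram
#'
#' Counts over consecutive integer grey levels \code{offset .. offset+L-1}.
#' All automatic thresholders operate on this representation; \code{offset}
#' supports sub-histograms taken from a partition of a wider channel while
#' keeping thresholds in absolute level units.
#'
#' @slot counts numeric vector of non-negative counts, one per level.
#' @slot offset integer, the grey level of the first count (0 for a full
#'   channel histogram).
#' @exportClass GreyHistogram
setClass("GreyHistogram",
  representation(counts = "numeric", offset = "integer"),
  validity = function(object) {
    if (length(object@counts) < 2L)
      return("histogram needs at least two levels (L >= 2)")
    if (any(object@counts < 0) || any(!is.finite(object@counts)))
      return("counts must be finite and non-negative")
    if (length(object@offset) != 1L || object@offset < 0L)
      return("offset must be a single non-negative integer")
    TRUE
  })

#' ChannelThresholds: per-channel automatic thresholds
#'
#' The fused thresholds for one spectral channel, together with the component
#' thresholds (Isodata, Otsu, fuzzy-entropy) that produced each fused value.
#'
#' @slot channel character, one of "L", "a", "b" (or "" when anonymous).
#' @slot nLevels integer, number of quantized grey levels of the channel.
#' @slot thresholds numeric, strictly increasing fused thresholds t_1 < ... < t_M.
#' @slot components data.frame, one row per fused threshold with columns
#'   tIsodata, tOtsu, tFuzzy, fused.
#' @exportClass ChannelThresholds
setClass("ChannelThresholds",
  representation(channel = "character", nLevels = "integer",
                 thresholds = "numeric", components = "data.frame"),
  validity = function(object) {
    tt <- object@thresholds
    if (length(tt) < 1L) return("at least one threshold required")
    if (is.unsorted(tt, strictly = TRUE)) return("thresholds must be strictly increasing")
    if (any(tt < 0) || any(tt > object@nLevels - 2L))
      return("thresholds must lie in [0, L-2]")
    TRUE
  })

#' CodedImage: per-pixel channel codes
#'
#' For each pixel, the partition index of its quantized value in each of the
#' three channels: 0 for values at or below the first threshold, up to M for
#' values above the last, giving n = M + 1 partitions per channel.
#'
#' @slot codes integer array, dim = c(height, width, 3).
#' @slot nPartitions integer, n = M + 1.
#' @exportClass CodedImage
setClass("CodedImage",
  representation(codes = "array", nPartitions = "integer"),
  validity = function(object) {
    d <- dim(object@codes)
    if (length(d) != 3L || d[3] != 3L)
      return("codes must be a height x width x 3 array")
    if (object@nPartitions < 2L)
      return("nPartitions must be at least 2")
    if (min(object@codes) < 0L || max(object@codes) > object@nPartitions - 1L)
      return("codes must lie in 0 .. n-1")
    TRUE
  })

#' LabelMap: per-pixel class labels
#'
#' Integer class labels combining the three channel codes of a pixel,
#' p = n^2 * cL + n * ca + cb, so labels lie in 0 .. n^3 - 1. After merging,
#' the occupied labels are a subset of the originally occupied ones.
#'
#' @slot labels integer matrix (height x width).
#' @slot nPartitions integer, the n used in the labelling formula.
#' @exportClass LabelMap
setClass("LabelMap",
  representation(labels = "matrix", nPartitions = "integer"),
  validity = function(object) {
    if (!is.numeric(object@labels)) return("labels must be numeric")
    n <- object@nPartitions
    if (min(object@labels) < 0L || max(object@labels) > n^3 - 1L)
      return("labels must lie in 0 .. n^3 - 1")
    TRUE
  })

#' PolygonSample: a reference sample unit
#'
#' A polygon (vertex list in pixel coordinates, pixel centres at integers)
#' carrying a single reference class label, used as the sample unit for
#' accuracy assessment instead of single pixels.
#'
#' @slot id character, polygon identifier.
#' @slot role character, the single reference class of the polygon.
#' @slot vertices numeric matrix with columns x (column coordinate) and
#'   y (row coordinate), at least three rows.
#' @exportClass PolygonSample
setClass("PolygonSample",
  representation(id = "character", role = "character", vertices = "matrix"),
  validity = function(object) {
    v <- object@vertices
    if (ncol(v) != 2L || nrow(v) < 3L)
      return("vertices must be an n x 2 matrix with n >= 3")
    if (!all(is.finite(v))) return("vertex coordinates must be finite")
    if (length(object@role) != 1L || !nzchar(object@role))
      return("a polygon carries exactly one reference class")
    TRUE
  })

#' FuzzyErrorMatrix: deterministic and fuzzy confusion accounting
#'
#' A K x K error matrix whose diagonal holds absolutely-correct counts and
#' whose off-diagonal cells each hold a pair (acceptable; unacceptable):
#' sample units with at least 50% overlap with their reference class are
#' acceptable, the rest are errors. Collapsing each pair by addition yields
#' the conventional deterministic error matrix. Rows are the classified
#' class, columns the reference class.
#'
#' @slot correct named numeric(K), diagonal counts.
#' @slot acceptable K x K numeric matrix, zero diagonal.
#' @slot unacceptable K x K numeric matrix, zero diagonal.
#' @exportClass FuzzyErrorMatrix
setClass("FuzzyErrorMatrix",
  representation(correct = "numeric", acceptable = "matrix",
                 unacceptable = "matrix"),
  validity = function(object) {
    K <- length(object@correct)
    cls <- names(object@correct)
    if (is.null(cls)) return("correct counts must be named by class")
    for (nm in c("acceptable", "unacceptable")) {
      m <- slot(object, nm)
      if (!all(dim(m) == c(K, K))) return(sprintf("%s must be K x K", nm))
      if (any(m < 0)) return("counts must be non-negative")
      if (any(diag(m) != 0)) return(sprintf("%s must have a zero diagonal", nm))
    }
    if (any(object@correct < 0)) return("counts must be non-negative")
    TRUE
  })

#' SceneSpec: parameters of a synthetic field scene
#'
#' Describes a four-texture field image: per-class mean colours and target
#' area fractions, additive Gaussian pixel noise, a multiplicative
#' illumination ramp across the image, a characteristic blob size, and a
#' random seed for reproducibility.
#'
#' @slot width,height integer image size in pixels.
#' @slot palette data.frame with columns role, R, G, B, fraction.
#' @slot noiseSd numeric, per-channel additive noise standard deviation
#'   (8-bit digital numbers).
#' @slot gradientAmplitude numeric, the illumination ramp runs linearly from
#'   1 - amplitude to 1 + amplitude across image columns.
#' @slot patchScale numeric, characteristic blob size in pixels.
#' @slot seed integer random seed.
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(width = "integer", height = "integer", palette = "data.frame",
                 noiseSd = "numeric", gradientAmplitude = "numeric",
                 patchScale = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@width < 1L || object@height < 1L) return("image size must be positive")
    p <- object@palette
    need <- c("role", "R", "G", "B", "fraction")
    if (!all(need %in% names(p))) return("palette needs role, R, G, B, fraction")
    if (abs(sum(p$fraction) - 1) > 1e-8) return("class fractions must sum to 1")
    if (any(p$fraction < 0)) return("fractions must be non-negative")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@patchScale < 1) return("patchScale must be >= 1")
    TRUE
  })
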