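# Channel quantization and histogram construction.
#
# The thresholders operate on discrete histograms with L grey levels, so the
# continuous Lab channels are binned: L* onto 0..100 over its [0, 100] range
# and a*, b* onto 0..220 over [-110, 110] by default. Bin counts are
# configurable through nLevels.

.channelRange <- function(channel) {
  switch(channel,
         L = c(0, 100),
         a = c(-110, 110),
         b = c(-110, 110),
         stop("channel must be one of 'L', 'a', 'b'"))
}

.defaultLevels <- function(channel) if (channel == "L") 101L else 221L

#' Quantize one Lab channel to integer grey levels
#'
#' Linearly maps the channel range onto integer levels 0 .. nLevels - 1,
#' rounding to the nearest level and clamping values outside the range.
#'
#' @param lab a \linkS4class{LabImage}
#' @param channel "L", "a" or "b"
#' @param nLevels number of grey levels (default 101 for L*, 221 for a*, b*)
#' @return integer matrix of grey levels, same height/width as the image
#' @export
quantizeChannel <- function(lab, channel = c("L", "a", "b"), nLevels = NULL) {
  channel <- match.arg(channel)
  stopifnot(is(lab, "LabImage"))
  if (is.null(nLevels)) nLevels <- .defaultLevels(channel)
  nLevels <- as.integer(nLevels)
  if (nLevels < 2L) stop("nLevels must be >= 2")
  rng <- .channelRange(channel)
  plane <- switch(channel, L = 1L, a = 2L, b = 3L)
  x <- lab@data[, , plane]
  scale <- (nLevels - 1L) / (rng[2L] - rng[1L])
  q <- round((x - rng[1L]) * scale)
  q <- pmin(pmax(q, 0), nLevels - 1L)
  matrix(as.integer(q), nrow = dim(lab@data)[1L])
}

#' Build a grey-level histogram from integer values
#'
#' @param values integer vector or matrix of grey levels
#' @param nLevels total number of levels L; levels run 0 .. L - 1 (defaults
#'   to max(values) + 1)
#' @return a \linkS4class{GreyHistogram}
#' @export
greyHistogram <- function(values, nLevels = NULL) {
  v <- as.integer(values)
  if (length(v) == 0L) stop("empty input: no pixels to histogram")
  if (any(v < 0L)) stop("grey levels must be non-negative")
  if (is.null(nLevels)) nLevels <- max(v) + 1L
  nLevels <- as.integer(nLevels)
  if (any(v > nLevels - 1L)) stop("values exceed nLevels - 1")
  counts <- tabulate(v + 1L, nbins = nLevels)
  new("GreyHistogram", counts = as.numeric(counts), offset = 0L)
}

# Sub-histogram over absolute levels lo..hi (inclusive), keeping absolute
# level semantics through the offset slot.
subHistogram <- function(hist, lo, hi) {
  lv <- histLevels(hist)
  keep <- lv >= lo & lv <= hi
  if (sum(keep) < 2L) stop("sub-histogram needs at least two levels")
  new("GreyHistogram", counts = hist@counts[keep], offset = as.integer(max(lo, min(lv))))
}

# Occupied-level helpers used by the thresholders.
occupiedRange <- function(hist) {
  lv <- histLevels(hist)[hist@counts > 0]
  if (length(lv) == 0L) stop("empty histogram")
  range(lv)
}

nOccupied <- function(hist) sum(hist@counts > 0)
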