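# Accessor generics and show methods for the core classes.

#' @export
setGeneric("labData", function(x) standardGeneric("labData"))
#' Extract the (height x width x 3) Lab array
#' @param x a \linkS4class{LabImage}
#' @return numeric array with planes L*, a*, b*
#' @export
setMethod("labData", "LabImage", function(x) x@data)

#' @export
setGeneric("whitePoint", function(x) standardGeneric("whitePoint"))
#' Reference white point of a LabImage
#' @param x a \linkS4class{LabImage}
#' @return numeric(3) tristimulus (Xn, Yn, Zn)
#' @export
setMethod("whitePoint", "LabImage", function(x) x@whitePoint)

#' @export
setGeneric("histCounts", function(x) standardGeneric("histCounts"))
#' Histogram counts
#' @param x a \linkS4class{GreyHistogram}
#' @return numeric vector of counts, named by grey level
#' @export
setMethod("histCounts", "GreyHistogram", function(x) {
  stats::setNames(x@counts, histLevels(x))
})

#' @export
setGeneric("histLevels", function(x) standardGeneric("histLevels"))
#' Grey levels of a histogram
#' @param x a \linkS4class{GreyHistogram}
#' @return integer vector of absolute grey levels
#' @export
setMethod("histLevels", "GreyHistogram", function(x) {
  x@offset + seq_along(x@counts) - 1L
})

#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
#' Ordered fused thresholds of a channel
#' @param x a \linkS4class{ChannelThresholds}
#' @return numeric vector, strictly increasing
#' @export
setMethod("thresholds", "ChannelThresholds", function(x) x@thresholds)

#' @export
setGeneric("thresholdComponents", function(x) standardGeneric("thresholdComponents"))
#' Component thresholds (Isodata, Otsu, fuzzy) behind each fused threshold
#' @param x a \linkS4class{ChannelThresholds}
#' @return data.frame with columns tIsodata, tOtsu, tFuzzy, fused
#' @export
setMethod("thresholdComponents", "ChannelThresholds", function(x) x@components)

#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' Per-pixel label matrix
#' @param x a \linkS4class{LabelMap}
#' @return integer matrix (height x width)
#' @export
setMethod("labelMatrix", "LabelMap", function(x) x@labels)

#' @export
setGeneric("nPartitions", function(x) standardGeneric("nPartitions"))
#' Partitions per channel (n = M + 1)
#' @param x a \linkS4class{LabelMap} or \linkS4class{CodedImage}
#' @return integer
#' @export
setMethod("nPartitions", "LabelMap", function(x) x@nPartitions)
#' @rdname nPartitions
#' @export
setMethod("nPartitions", "CodedImage", function(x) x@nPartitions)

#' @export
setGeneric("occupiedLabels", function(x) standardGeneric("occupiedLabels"))
#' Sorted set of labels present in the map
#' @param x a \linkS4class{LabelMap}
#' @return integer vector
#' @export
setMethod("occupiedLabels", "LabelMap", function(x) sort(unique(as.vector(x@labels))))

#' @export
setGeneric("matrixClasses", function(x) standardGeneric("matrixClasses"))
#' Class names of an error matrix
#' @param x a \linkS4class{FuzzyErrorMatrix}
#' @return character vector
#' @export
setMethod("matrixClasses", "FuzzyErrorMatrix", function(x) names(x@correct))

setMethod("show", "LabImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabImage: %d x %d pixels\n", d[1], d[2]))
  cat(sprintf("  white point (Xn, Yn, Zn): %s\n",
              paste(format(object@whitePoint, digits = 4), collapse = ", ")))
  cat(sprintf("  L* range: [%.2f, %.2f]  a*: [%.2f, %.2f]  b*: [%.2f, %.2f]\n",
              min(object@data[, , 1]), max(object@data[, , 1]),
              min(object@data[, , 2]), max(object@data[, , 2]),
              min(object@data[, , 3]), max(object@data[, , 3])))
})

setMethod("show", "GreyHistogram", function(object) {
  cat(sprintf("GreyHistogram: %d levels [%d .. %d], %d pixels, %d occupied levels\n",
              length(object@counts), object@offset,
              object@offset + length(object@counts) - 1L,
              as.integer(sum(object@counts)), sum(object@counts > 0)))
})

setMethod("show", "ChannelThresholds", function(object) {
  cat(sprintf("ChannelThresholds [%s]: M = %d over %d levels\n",
              if (nzchar(object@channel)) object@channel else "?",
              length(object@thresholds), object@nLevels))
  print(object@components, row.names = FALSE)
})

setMethod("show", "LabelMap", function(object) {
  occ <- occupiedLabels(object)
  cat(sprintf("LabelMap: %d x %d pixels, n = %d, %d occupied classes\n",
              nrow(object@labels), ncol(object@labels),
              object@nPartitions, length(occ)))
})

setMethod("show", "PolygonSample", function(object) {
  cat(sprintf("PolygonSample '%s' (class %s): %d vertices\n",
              object@id, object@role, nrow(object@vertices)))
})

setMethod("show", "FuzzyErrorMatrix", function(object) {
  cat(sprintf("FuzzyErrorMatrix: %d classes, grand total %s\n",
              length(object@correct), format(grandTotal(object), big.mark = ",")))
  print(formatErrorMatrix(object), quote = FALSE)
})
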