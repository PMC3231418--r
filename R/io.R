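# Raster and report input/output. PNG/JPEG/TIFF reading goes through
# EBImage; internal arrays are height x width x 3 in 0..255.

.rolePalette <- c(GO = "#2E8B22", DO = "#E6D84A", HD = "#C03A2B", SG = "#2B4FC0")

#' Read a colour photograph as an RGB array
#'
#' @param path PNG/JPEG/TIFF file
#' @return numeric array height x width x 3, values 0..255
#' @export
readSceneImage <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image '%s'", path))
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2L) {                       # greyscale: replicate
    arr <- array(rep(t(img), 3L), dim = c(d[2L], d[1L], 3L))
  } else {
    arr <- aperm(img[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
    arr <- array(as.numeric(arr), dim = dim(arr))
  }
  arr * 255
}

#' Write an RGB array as an image file
#'
#' @param rgb numeric array height x width x 3, values 0..255
#' @param path output file (format from the extension)
#' @return invisibly, the path
#' @export
writeSceneImage <- function(rgb, path) {
  EBImage::writeImage(EBImage::Image(aperm(rgb / 255, c(2L, 1L, 3L)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Write a role map as a colour-coded PNG
#'
#' One palette colour per role: green for GO, yellow for DO, red for HD,
#' blue for SG (matching the usual display convention for damage maps).
#'
#' @param roleMap character matrix of roles
#' @param path output PNG path
#' @param palette named vector of colours, one per role
#' @return invisibly, the path
#' @export
writeRoleMapPng <- function(roleMap, path, palette = .rolePalette) {
  if (!all(as.vector(roleMap) %in% names(palette)))
    stop("role map contains roles missing from the palette")
  cols <- grDevices::col2rgb(palette)
  rgb <- array(0, dim = c(nrow(roleMap), ncol(roleMap), 3L))
  for (ch in 1:3) {
    lut <- stats::setNames(cols[ch, ], colnames(cols))
    rgb[, , ch] <- matrix(lut[as.vector(roleMap)], nrow = nrow(roleMap))
  }
  writeSceneImage(rgb, path)
}

#' Write class statistics as CSV
#'
#' @param stats a \code{\link{classStatistics}} table
#' @param path output CSV path
#' @param roles optional named role vector to join on label
#' @return invisibly, the path
#' @export
writeClassStatsCsv <- function(stats, path, roles = NULL) {
  if (!is.null(roles)) stats$role <- unname(roles[as.character(stats$label)])
  utils::write.csv(format(stats, digits = 10, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a damage report as JSON
#'
#' @param report output of \code{\link{damageReport}}
#' @param path output JSON path
#' @param extra optional named list echoed into the report (e.g. the run
#'   configuration, for provenance)
#' @return invisibly, the path
#' @export
writeDamageReportJson <- function(report, path, extra = NULL) {
  if (!is.null(extra)) report <- c(report, list(config = extra))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Write an accuracy report as JSON
#'
#' @param m a \linkS4class{FuzzyErrorMatrix}
#' @param path output JSON path
#' @param extra optional named list echoed into the report
#' @return invisibly, the path
#' @export
writeAccuracyReportJson <- function(m, path, extra = NULL) {
  rep <- list(grandTotal = grandTotal(m), measures = accuracyReport(m))
  if (!is.null(extra)) rep$config <- extra
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a role map written as a colour-coded PNG
#'
#' Inverse of \code{\link{writeRoleMapPng}} for the same palette.
#'
#' @param path PNG path
#' @param palette named vector of colours, one per role
#' @return character matrix of roles
#' @export
readRoleMapPng <- function(path, palette = .rolePalette) {
  rgb <- round(readSceneImage(path))
  cols <- grDevices::col2rgb(palette)
  key <- paste(cols[1, ], cols[2, ], cols[3, ])
  got <- paste(rgb[, , 1], rgb[, , 2], rgb[, , 3])
  i <- match(got, key)
  if (anyNA(i)) stop("PNG contains colours not in the role palette")
  matrix(colnames(cols)[i], nrow = nrow(rgb))
}
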