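# Polygon sample units: construction, rasterization, CSV round-trip.
#
# Coordinates are pixel-centre based: pixel (row r, col c) has centre
# (x = c, y = r). Rasterization uses even-odd scanline filling against pixel
# centres, so an axis-aligned rectangle with vertices at half-integer
# offsets covers exactly the enclosed pixel grid.

#' Create a polygon sample unit
#'
#' @param id polygon identifier
#' @param role reference class label of the polygon
#' @param x,y numeric vertex coordinates (pixel units; columns and rows)
#' @return a \linkS4class{PolygonSample}
#' @export
polygonSample <- function(id, role, x, y) {
  new("PolygonSample", id = as.character(id), role = as.character(role),
      vertices = cbind(x = as.numeric(x), y = as.numeric(y)))
}

#' Rasterize a polygon to pixel indices
#'
#' Even-odd scanline fill over pixel centres. Raises an error of class
#' \code{frostmap_geometry_error} if the polygon reaches outside the image or
#' covers no pixel centre.
#'
#' @param poly a \linkS4class{PolygonSample}
#' @param dim integer(2), c(nrow, ncol) of the target raster
#' @return integer vector of linear (column-major) pixel indices
#' @export
rasterizePolygon <- function(poly, dim) {
  v <- poly@vertices
  nr <- dim[1L]; nc <- dim[2L]
  geomStop <- function(msg) stop(errorCondition(
    sprintf("polygon '%s': %s", poly@id, msg),
    class = c("frostmap_geometry_error", "error", "condition")))
  if (min(v[, "x"]) < 0.5 - 1e-9 || max(v[, "x"]) > nc + 0.5 + 1e-9 ||
      min(v[, "y"]) < 0.5 - 1e-9 || max(v[, "y"]) > nr + 0.5 + 1e-9)
    geomStop("vertices outside the image bounds")

  x1 <- v[, "x"]; y1 <- v[, "y"]
  x2 <- v[c(2:nrow(v), 1L), "x"]; y2 <- v[c(2:nrow(v), 1L), "y"]
  r0 <- max(1, ceiling(min(y1))); r1 <- min(nr, floor(max(y1)))
  if (r0 > r1) geomStop("covers no pixel centre")
  rows <- r0:r1
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    y <- rows[k]
    # half-open rule in y avoids double-counting shared vertices
    cross <- (pmin(y1, y2) <= y) & (y < pmax(y1, y2))
    if (!any(cross)) next
    xs <- sort(x1[cross] + (y - y1[cross]) * (x2[cross] - x1[cross]) /
                 (y2[cross] - y1[cross]))
    if (length(xs) %% 2L != 0L) next   # touches a vertex exactly; skip row
    for (j in seq(1L, length(xs), by = 2L)) {
      c0 <- max(1L, ceiling(xs[j] - 1e-9))
      c1 <- min(nc, floor(xs[j + 1L] + 1e-9))
      if (c0 <= c1)
        out[[k]] <- c(out[[k]], (c0:c1 - 1L) * nr + y)
    }
  }
  idx <- unlist(out)
  if (length(idx) == 0L) geomStop("covers no pixel centre")
  sort(unique(idx))
}

#' Read polygons from CSV
#'
#' Expects columns polygon_id, class, x, y with one row per vertex; vertices
#' of a polygon are consecutive rows in drawing order.
#'
#' @param path CSV file path
#' @return list of \linkS4class{PolygonSample}
#' @export
readPolygonsCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("polygon_id", "class", "x", "y")
  if (!all(need %in% names(df)))
    stop("polygon CSV needs columns polygon_id, class, x, y")
  lapply(split(df, factor(df$polygon_id, levels = unique(df$polygon_id))),
         function(d) polygonSample(d$polygon_id[1L], d$class[1L], d$x, d$y))
}

#' Write polygons to CSV
#'
#' @param polys list of \linkS4class{PolygonSample}
#' @param path output CSV file path
#' @return invisibly, the path
#' @export
writePolygonsCsv <- function(polys, path) {
  df <- do.call(rbind, lapply(polys, function(p)
    data.frame(polygon_id = p@id, class = p@role,
               x = p@vertices[, "x"], y = p@vertices[, "y"])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
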