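# GeoJSON interchange for layouts, sample points and cell tables.
# Geometry is written in the local projected frame (meters); a "crs_note"
# foreign member records this, since GeoJSON proper assumes WGS84.

rect_coords <- function(xmin, ymin, xmax, ymax) {
  list(list(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax),
            c(xmin, ymax), c(xmin, ymin)))
}

feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry, properties = properties)
}

#' Write and read a field layout as GeoJSON
#'
#' The field boundary and every plot become Polygon features; plot
#' features carry \code{plot_id}, \code{row_id}, \code{cultivar},
#' \code{sowing_date} and \code{role} properties. Coordinates are local
#' projected meters.
#'
#' @param layout a \code{field_layout}.
#' @param path output file.
#' @return \code{write_layout_geojson}: \code{path} invisibly;
#'   \code{read_layout_geojson}: a \code{field_layout}.
#' @export
write_layout_geojson <- function(layout, path) {
  stopifnot(inherits(layout, "field_layout"))
  o <- layout$origin
  feats <- list(feature(
    list(type = "Polygon",
         coordinates = rect_coords(o[1], o[2], o[1] + layout$field_width,
                                   o[2] + layout$field_height)),
    list(kind = "field")))
  p <- layout$plots
  for (k in seq_len(nrow(p))) {
    feats[[k + 1]] <- feature(
      list(type = "Polygon",
           coordinates = rect_coords(p$xmin[k], p$ymin[k], p$xmax[k], p$ymax[k])),
      list(kind = "plot", plot_id = p$plot_id[k], row_id = p$row_id[k],
           cultivar = p$cultivar[k], sowing_date = p$sowing_date[k],
           role = p$role[k]))
  }
  jsonlite::write_json(
    list(type = "FeatureCollection", crs_note = layout$crs_note,
         features = feats),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_layout_geojson
#' @export
read_layout_geojson <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  is_plot <- vapply(g$features, function(f) identical(f$properties$kind, "plot"),
                    logical(1))
  fld <- g$features[[which(!is_plot)[1]]]
  bb <- poly_bbox(fld$geometry$coordinates)
  rows <- lapply(g$features[is_plot], function(f) {
    b <- poly_bbox(f$geometry$coordinates)
    pr <- f$properties
    data.frame(plot_id = pr$plot_id, row_id = pr$row_id,
               cultivar = pr$cultivar %||% NA_character_,
               sowing_date = pr$sowing_date %||% NA_character_,
               role = pr$role %||% "cultivar",
               xmin = b[1], ymin = b[2], xmax = b[3], ymax = b[4],
               stringsAsFactors = FALSE)
  })
  field_layout(bb[3] - bb[1], bb[4] - bb[2], do.call(rbind, rows),
               origin = bb[1:2])
}

poly_bbox <- function(coords) {
  ring <- coords[[1]]
  xs <- vapply(ring, function(pt) as.numeric(pt[[1]]), numeric(1))
  ys <- vapply(ring, function(pt) as.numeric(pt[[2]]), numeric(1))
  c(min(xs), min(ys), max(xs), max(ys))
}

#' Write and read sample points as GeoJSON
#'
#' Point features with \code{sample_id} and \code{plot_id} (null for
#' points in the adjacent area outside plots).
#'
#' @param points data.frame with \code{sample_id}, \code{x}, \code{y},
#'   \code{plot_id}.
#' @param path file path.
#' @export
write_points_geojson <- function(points, path) {
  feats <- lapply(seq_len(nrow(points)), function(k) {
    feature(list(type = "Point",
                 coordinates = c(points$x[k], points$y[k])),
            list(sample_id = points$sample_id[k],
                 plot_id = points$plot_id[k]))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection",
         crs_note = "local projected Cartesian frame, meters",
         features = feats),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_points_geojson
#' @export
read_points_geojson <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(g$features, function(f) {
    data.frame(sample_id = f$properties$sample_id,
               x = as.numeric(f$geometry$coordinates[[1]]),
               y = as.numeric(f$geometry$coordinates[[2]]),
               plot_id = f$properties$plot_id %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export classified grid cells as GeoJSON polygons
#'
#' @param cells output of \code{\link{classify_cells}}.
#' @param grid the \code{field_grid} the cells came from.
#' @param path file path.
#' @param statuses which cell statuses to include (default: retained
#'   cells only, which keeps files small).
#' @export
write_cells_geojson <- function(cells, grid, path, statuses = "retained") {
  keep <- cells[cells$status %in% statuses, , drop = FALSE]
  s <- grid$cell_size
  feats <- lapply(seq_len(nrow(keep)), function(k) {
    feature(list(type = "Polygon",
                 coordinates = rect_coords(keep$x0[k], keep$y0[k],
                                           keep$x0[k] + s, keep$y0[k] + s)),
            list(cell_i = keep$cell_i[k], cell_j = keep$cell_j[k],
                 status = keep$status[k], plot_id = keep$plot_id[k]))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection",
         crs_note = "local projected Cartesian frame, meters",
         features = feats),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
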