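#' Experimental field layout
#'
#' Describes the trial geometry in a local projected frame (meters):
#' the rectangular field, one axis-aligned rectangular polygon per
#' experimental plot with its treatment metadata, and implicitly the
#' corridor (field minus plots). Plot polygons must be pairwise disjoint
#' and lie inside the field.
#'
#' @param field_width,field_height field extent in meters (origin at
#'   (0, 0) unless \code{origin} is given).
#' @param plots data.frame with columns \code{plot_id}, \code{row_id},
#'   \code{cultivar}, \code{sowing_date}, \code{role} (one of
#'   \code{"cultivar"}, \code{"weedy"}, \code{"sheet"},
#'   \code{"destructive"}) and rectangle corners \code{xmin},
#'   \code{ymin}, \code{xmax}, \code{ymax}.
#' @param origin lower-left corner of the field, meters.
#' @return A \code{field_layout} object.
#' @export
field_layout <- function(field_width, field_height, plots, origin = c(0, 0)) {
  stop_if_not_scalar_pos(field_width, "field_width")
  stop_if_not_scalar_pos(field_height, "field_height")
  need <- c("plot_id", "row_id", "cultivar", "sowing_date", "role",
            "xmin", "ymin", "xmax", "ymax")
  if (!all(need %in% names(plots))) {
    stop("'plots' must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(plots$plot_id)) stop("duplicate plot ids", call. = FALSE)
  if (any(is.na(plots$row_id))) stop("every plot needs a row id", call. = FALSE)
  fx <- origin[1]; fy <- origin[2]
  if (any(plots$xmin < fx - 1e-9 | plots$ymin < fy - 1e-9 |
          plots$xmax > fx + field_width + 1e-9 |
          plots$ymax > fy + field_height + 1e-9 |
          plots$xmin >= plots$xmax | plots$ymin >= plots$ymax)) {
    stop("layout error: plots must be non-degenerate and inside the field",
         call. = FALSE)
  }
  n <- nrow(plots)
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      b <- seq(a + 1, n)
      ovx <- pmin(plots$xmax[b], plots$xmax[a]) - pmax(plots$xmin[b], plots$xmin[a])
      ovy <- pmin(plots$ymax[b], plots$ymax[a]) - pmax(plots$ymin[b], plots$ymin[a])
      if (any(ovx > 1e-9 & ovy > 1e-9)) {
        stop("layout error: overlapping plot polygons", call. = FALSE)
      }
    }
  }
  structure(list(origin = as.numeric(origin),
                 field_width = field_width, field_height = field_height,
                 plots = as.data.frame(plots),
                 crs_note = "local projected Cartesian frame, meters"),
            class = "field_layout")
}

#' @export
print.field_layout <- function(x, ...) {
  cat(sprintf("<field_layout> %g x %g m field, %d plots (%s)\n",
              x$field_width, x$field_height, nrow(x$plots),
              paste(sprintf("%s: %d", names(table(x$plots$role)),
                            as.integer(table(x$plots$role))), collapse = ", ")))
  invisible(x)
}

#' Plot areas in square meters
#' @param layout a \code{field_layout}.
#' @return Numeric vector named by plot id.
#' @export
plot_areas <- function(layout) {
  stopifnot(inherits(layout, "field_layout"))
  p <- layout$plots
  stats::setNames((p$xmax - p$xmin) * (p$ymax - p$ymin), p$plot_id)
}

# rectangle geometry for a regular plot arrangement: `rows` rows of
# `per_row` plots, separated by `corridor` and centered in the field
arrange_plots <- function(field_width, field_height, rows, per_row,
                          plot_w, plot_h, corridor) {
  block_w <- per_row * plot_w + (per_row - 1) * corridor
  block_h <- rows * plot_h + (rows - 1) * corridor
  if (block_w > field_width + 1e-9 || block_h > field_height + 1e-9) {
    stop("layout error: plots with corridors exceed field bounds", call. = FALSE)
  }
  mx <- (field_width - block_w) / 2
  my <- (field_height - block_h) / 2
  g <- expand.grid(col = seq_len(per_row), row = seq_len(rows))
  data.frame(
    plot_id = sprintf("P%02d", seq_len(nrow(g))),
    row_id = sprintf("R%d", g$row),
    xmin = mx + (g$col - 1) * (plot_w + corridor),
    ymin = my + (g$row - 1) * (plot_h + corridor),
    stringsAsFactors = FALSE
  ) |>
    transform(xmax = xmin + plot_w, ymax = ymin + plot_h)
}

#' Build the analysis grid over a field
#'
#' Tiles the field bounding box with square half-open cells
#' \code{[x, x+s) x [y, y+s)}, anchored at the bounding-box minimum
#' corner. Column and row counts use the ceiling rule so the grid always
#' covers the box.
#'
#' @param layout a \code{field_layout} (or a numeric
#'   \code{c(xmin, ymin, xmax, ymax)} extent).
#' @param cell_size_m cell edge length, meters; the conventional choice
#'   for a cereal canopy is 0.25 m, about one plant's footprint.
#' @return A \code{field_grid}: list with \code{origin},
#'   \code{cell_size}, \code{n_cols}, \code{n_rows}, \code{n_cells}.
#' @examples
#' g <- build_grid(c(0, 0, 1, 1), cell_size_m = 0.25)
#' g$n_cells  # 16
#' @export
build_grid <- function(layout, cell_size_m = 0.25) {
  stop_if_not_scalar_pos(cell_size_m, "cell_size_m")
  if (inherits(layout, "field_layout")) {
    ext <- c(layout$origin, layout$origin + c(layout$field_width, layout$field_height))
  } else {
    ext <- as.numeric(layout)
    if (length(ext) != 4 || ext[3] <= ext[1] || ext[4] <= ext[2]) {
      stop("degenerate field extent", call. = FALSE)
    }
  }
  w <- ext[3] - ext[1]; h <- ext[4] - ext[2]
  n_cols <- as.integer(ceiling(w / cell_size_m - 1e-9))
  n_rows <- as.integer(ceiling(h / cell_size_m - 1e-9))
  structure(list(origin = ext[1:2], cell_size = cell_size_m,
                 n_cols = n_cols, n_rows = n_rows,
                 n_cells = n_cols * n_rows),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid> %d x %d = %d cells of %g m (%.4f m^2 each)\n",
              x$n_rows, x$n_cols, x$n_cells, x$cell_size, x$cell_size^2))
  invisible(x)
}

#' Area of one grid cell, square meters
#' @param grid a \code{field_grid}.
#' @export
cell_area <- function(grid) {
  stopifnot(inherits(grid, "field_grid"))
  grid$cell_size^2
}

#' Classify grid cells against the plot layout
#'
#' Applies the cell elimination rules: a cell intersecting two or more
#' plots is eliminated (it mixes treatments); a cell touching exactly one
#' plot but not fully contained in it mixes plot and corridor and is
#' eliminated; a cell fully inside exactly one plot is retained and
#' assigned that plot; a cell touching no plot is outside. Intersection
#' is by positive overlap area; containment allows a 1e-9 m tolerance.
#'
#' @param grid a \code{field_grid}.
#' @param layout a \code{field_layout} sharing the grid's frame.
#' @return data.frame with one row per cell: \code{cell_i} (row),
#'   \code{cell_j} (column), \code{x0}, \code{y0} (lower-left corner),
#'   \code{status} in \code{retained}, \code{eliminated_two_plots},
#'   \code{eliminated_corridor_mix}, \code{outside}, and \code{plot_id}
#'   (non-NA iff retained).
#' @export
classify_cells <- function(grid, layout) {
  stopifnot(inherits(grid, "field_grid"), inherits(layout, "field_layout"))
  tol <- 1e-9
  s <- grid$cell_size; ox <- grid$origin[1]; oy <- grid$origin[2]
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  owner <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  contained <- matrix(FALSE, grid$n_rows, grid$n_cols)
  p <- layout$plots
  for (k in seq_len(nrow(p))) {
    jj <- which(ox + (seq_len(grid$n_cols) - 1) * s < p$xmax[k] - tol &
                ox + seq_len(grid$n_cols) * s > p$xmin[k] + tol)
    ii <- which(oy + (seq_len(grid$n_rows) - 1) * s < p$ymax[k] - tol &
                oy + seq_len(grid$n_rows) * s > p$ymin[k] + tol)
    if (!length(jj) || !length(ii)) next
    counts[ii, jj] <- counts[ii, jj] + 1L
    cj <- jj[ox + (jj - 1) * s >= p$xmin[k] - tol & ox + jj * s <= p$xmax[k] + tol]
    ci <- ii[oy + (ii - 1) * s >= p$ymin[k] - tol & oy + ii * s <= p$ymax[k] + tol]
    if (length(ci) && length(cj)) {
      owner[ci, cj] <- p$plot_id[k]
      contained[ci, cj] <- TRUE
    }
  }
  idx <- expand.grid(cell_i = seq_len(grid$n_rows), cell_j = seq_len(grid$n_cols))
  cnt <- counts[cbind(idx$cell_i, idx$cell_j)]
  cont <- contained[cbind(idx$cell_i, idx$cell_j)]
  status <- ifelse(cnt == 0L, "outside",
            ifelse(cnt >= 2L, "eliminated_two_plots",
            ifelse(cont, "retained", "eliminated_corridor_mix")))
  data.frame(
    cell_i = idx$cell_i, cell_j = idx$cell_j,
    x0 = ox + (idx$cell_j - 1) * s, y0 = oy + (idx$cell_i - 1) * s,
    status = status,
    plot_id = ifelse(status == "retained",
                     owner[cbind(idx$cell_i, idx$cell_j)], NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Mean index values over sample-point quadrats
#'
#' For each sample point, averages the unmasked pixels of every stack
#' layer whose centers fall in the half-open square quadrat centered on
#' the point. Quadrats with no unmasked pixel in some layer (including
#' quadrats outside the raster extent) are flagged rather than raising a
#' global failure.
#'
#' @param stack an \code{index_stack}.
#' @param points data.frame with columns \code{sample_id}, \code{x},
#'   \code{y} (quadrat centers, meters) and optionally \code{plot_id}.
#' @param quadrat_size_m quadrat edge length, meters (harvest quadrats
#'   are 1 m x 1 m).
#' @return data.frame: \code{sample_id}, one column per index (quadrat
#'   mean), \code{n_pixels} (smallest per-layer unmasked count) and
#'   \code{covariates_ok}. Per-layer pixel counts are attached as
#'   attribute \code{"pixel_counts"}.
#' @export
extract_point_covariates <- function(stack, points, quadrat_size_m = 1) {
  stopifnot(inherits(stack, "index_stack"))
  stop_if_not_scalar_pos(quadrat_size_m, "quadrat_size_m")
  if (anyDuplicated(points$sample_id)) {
    stop("duplicate sample ids in 'points'", call. = FALSE)
  }
  half <- quadrat_size_m / 2
  px <- stack$pixel_size; o <- stack$origin; dm <- stack$dim
  nm <- names(stack$layers)
  means <- matrix(NA_real_, nrow(points), stack$m, dimnames = list(NULL, nm))
  counts <- matrix(0L, nrow(points), stack$m, dimnames = list(NULL, nm))
  tol <- 1e-9
  for (q in seq_len(nrow(points))) {
    x0 <- points$x[q] - half; x1 <- points$x[q] + half
    y0 <- points$y[q] - half; y1 <- points$y[q] + half
    # pixel center (j - 0.5) * px + o lies in [x0, x1)
    j0 <- max(1L, as.integer(ceiling((x0 - o[1]) / px + 0.5 - tol)))
    j1 <- min(dm[2], as.integer(ceiling((x1 - o[1]) / px + 0.5 - tol)) - 1L)
    i0 <- max(1L, as.integer(ceiling((y0 - o[2]) / px + 0.5 - tol)))
    i1 <- min(dm[1], as.integer(ceiling((y1 - o[2]) / px + 0.5 - tol)) - 1L)
    if (j1 < j0 || i1 < i0) next
    for (l in seq_len(stack$m)) {
      v <- stack$layers[[l]]$values[i0:i1, j0:j1]
      v <- v[!is.na(v)]
      counts[q, l] <- length(v)
      if (length(v)) means[q, l] <- mean(v)
    }
  }
  out <- data.frame(sample_id = points$sample_id, stringsAsFactors = FALSE)
  for (l in nm) out[[l]] <- means[, l]
  out$n_pixels <- apply(counts, 1, min)
  out$covariates_ok <- out$n_pixels > 0L
  attr(out, "pixel_counts") <- counts
  out
}

#' Join covariate means with harvest measurements
#'
#' Inner join on sample id between the per-quadrat covariate table and
#' the hand-harvest table, after dropping an explicit exclusion list
#' (ids removed from modeling, logged via a message) and quadrats whose
#' covariates were flagged. Unmatched ids are reported in the
#' \code{"unmatched"} attribute.
#'
#' @param covariates output of \code{\link{extract_point_covariates}}.
#' @param harvest data.frame with \code{sample_id}, a response column
#'   (e.g. \code{ear_dry_weight_g}) and any auxiliary measures.
#' @param exclude_ids sample ids to drop before joining (default none).
#' @return data.frame of modeling rows.
#' @export
join_samples <- function(covariates, harvest, exclude_ids = character()) {
  if (anyDuplicated(covariates$sample_id) || anyDuplicated(harvest$sample_id)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (length(exclude_ids)) {
    message(sprintf("excluding %d sample id(s) from modeling: %s",
                    length(exclude_ids), paste(exclude_ids, collapse = ", ")))
    covariates <- covariates[!(covariates$sample_id %in% exclude_ids), , drop = FALSE]
    harvest <- harvest[!(harvest$sample_id %in% exclude_ids), , drop = FALSE]
  }
  if (!is.null(covariates$covariates_ok)) {
    bad <- covariates$sample_id[!covariates$covariates_ok]
    if (length(bad)) {
      message(sprintf("dropping %d quadrat(s) without usable pixels: %s",
                      length(bad), paste(bad, collapse = ", ")))
      covariates <- covariates[covariates$covariates_ok, , drop = FALSE]
    }
  }
  merged <- merge(covariates, harvest, by = "sample_id", sort = TRUE)
  unmatched <- c(setdiff(covariates$sample_id, merged$sample_id),
                 setdiff(harvest$sample_id, merged$sample_id))
  if (length(unmatched)) {
    message(sprintf("%d unmatched sample id(s): %s", length(unmatched),
                    paste(unmatched, collapse = ", ")))
  }
  attr(merged, "unmatched") <- unmatched
  merged
}
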