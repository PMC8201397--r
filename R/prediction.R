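#' Apply the selected model at every pixel
#'
#' Computes intercept + sum of slope * index value at each pixel where
#' all required covariate layers are unmasked; other pixels are masked.
#' Predictions are conditional means — residual noise is never added to
#' point predictions.
#'
#' @param fit a \code{gaussian_fit} (usually the best model of a
#'   selection).
#' @param stack an \code{index_stack} containing every layer in
#'   \code{fit$spec}.
#' @return A \code{field_raster} of predicted trait values on the
#'   stack's grid.
#' @export
predict_pixels <- function(fit, stack) {
  stopifnot(inherits(fit, "gaussian_fit"), inherits(stack, "index_stack"))
  miss <- setdiff(fit$spec, names(stack$layers))
  if (length(miss)) {
    stop("stack lacks covariate layer(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  b <- fit$coefficients
  v <- matrix(unname(b[1]), stack$dim[1], stack$dim[2])
  for (nm in fit$spec) {
    v <- v + unname(b[nm]) * stack$layers[[nm]]$values
  }
  field_raster(v, origin = stack$origin, pixel_size = stack$pixel_size,
               band = "index")
}

#' Aggregate pixel predictions into retained grid cells
#'
#' For every retained cell, the mean of the unmasked predicted pixels
#' whose centers fall in the half-open cell, with the contributing pixel
#' count. Cells left with zero unmasked pixels are dropped with a
#' warning. The identity
#' \code{sum(y_hat_cell * n_pixels) == sum(retained unmasked pixels)}
#' holds to numerical precision.
#'
#' @param map a \code{field_raster} of pixel predictions.
#' @param cells classified cell table (\code{\link{classify_cells}});
#'   only rows with status \code{"retained"} are aggregated.
#' @param grid the \code{field_grid} that produced \code{cells}.
#' @return data.frame: cell_i, cell_j, plot_id, y_hat, n_pixels.
#' @export
aggregate_cells <- function(map, cells, grid) {
  stopifnot(inherits(map, "field_raster"), inherits(grid, "field_grid"))
  keep <- cells[cells$status == "retained", , drop = FALSE]
  if (!nrow(keep)) stop("no retained cells to aggregate", call. = FALSE)
  px <- map$pixel_size; o <- map$origin; dm <- dim(map$values)
  s <- grid$cell_size
  tol <- 1e-9
  y_hat <- numeric(nrow(keep)); n_px <- integer(nrow(keep))
  for (q in seq_len(nrow(keep))) {
    x0 <- keep$x0[q]; y0 <- keep$y0[q]
    j0 <- max(1L, as.integer(ceiling((x0 - o[1]) / px + 0.5 - tol)))
    j1 <- min(dm[2], as.integer(ceiling((x0 + s - o[1]) / px + 0.5 - tol)) - 1L)
    i0 <- max(1L, as.integer(ceiling((y0 - o[2]) / px + 0.5 - tol)))
    i1 <- min(dm[1], as.integer(ceiling((y0 + s - o[2]) / px + 0.5 - tol)) - 1L)
    if (j1 < j0 || i1 < i0) next
    v <- map$values[i0:i1, j0:j1]
    v <- v[!is.na(v)]
    n_px[q] <- length(v)
    if (length(v)) y_hat[q] <- mean(v)
  }
  empty <- n_px == 0L
  if (any(empty)) {
    warning(sprintf("%d retained cell(s) had no unmasked pixels and were dropped",
                    sum(empty)), call. = FALSE)
  }
  data.frame(cell_i = keep$cell_i[!empty], cell_j = keep$cell_j[!empty],
             plot_id = keep$plot_id[!empty], y_hat = y_hat[!empty],
             n_pixels = n_px[!empty], stringsAsFactors = FALSE)
}

#' Compare per-plot predicted distributions with manual samples
#'
#' For each plot with at least one retained cell and a manual sample,
#' computes the median and 25/75% quartiles (linear-interpolation
#' quantile definition, \code{stats::quantile} type 7) of the cell
#' predictions and flags plots whose manual value falls outside
#' [q25, q75]. The percentage of flagged plots is reported to one
#' decimal place.
#'
#' @param cellpred output of \code{\link{aggregate_cells}}.
#' @param samples data.frame with \code{plot_id} and a manual value
#'   column.
#' @param value manual value column name (default
#'   \code{"ear_dry_weight_g"}).
#' @return A \code{plot_distribution_summary}: data.frame (plot_id,
#'   n_cells, q25, median, q75, manual, outside, direction) with the
#'   flagged percentage in attribute \code{"pct_outside"}.
#' @export
summarize_plots <- function(cellpred, samples, value = "ear_dry_weight_g") {
  plots <- sort(unique(cellpred$plot_id))
  manual <- samples[!is.na(samples$plot_id), c("plot_id", value)]
  rows <- list()
  for (p in plots) {
    yv <- cellpred$y_hat[cellpred$plot_id == p]
    mv <- manual[[value]][manual$plot_id == p]
    if (!length(mv)) {
      warning(sprintf("plot %s has no manual sample; skipped", p),
              call. = FALSE)
      next
    }
    q <- stats::quantile(yv, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    out <- mv[1] < q[1] | mv[1] > q[3]
    rows[[p]] <- data.frame(
      plot_id = p, n_cells = length(yv), q25 = q[1], median = q[2],
      q75 = q[3], manual = mv[1], outside = out,
      direction = if (!out) "inside" else if (mv[1] < q[1]) "below" else "above",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(plot_id = character(), n_cells = integer(),
                      q25 = numeric(), median = numeric(), q75 = numeric(),
                      manual = numeric(), outside = logical(),
                      direction = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  pct <- if (nrow(res)) round(100 * mean(res$outside), 1) else NA_real_
  attr(res, "pct_outside") <- pct
  class(res) <- c("plot_distribution_summary", "data.frame")
  res
}

#' @export
print.plot_distribution_summary <- function(x, ...) {
  n_out <- sum(x$outside)
  cat(sprintf("Manual value outside the predicted IQR in %.1f%% of plots (%d of %d)\n",
              attr(x, "pct_outside"), n_out, nrow(x)))
  cat(sprintf("  below q25: %d, above q75: %d\n",
              sum(x$direction == "below"), sum(x$direction == "above")))
  invisible(x)
}
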