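#' Calibrate a reflectance band against a reference panel
#'
#' Multispectral surveys bracket each flight with images of a panel of
#' known reflectance. The band is rescaled by the gain
#' \code{g = panel_known / mean(panel_observed_pre, panel_observed_post)}
#' and clipped to [0, 1]; the mask is preserved.
#'
#' @param band a \code{field_raster} with reflectance-like values.
#' @param panel_known true panel reflectance, in (0, 1].
#' @param panel_observed_pre,panel_observed_post observed panel values
#'   immediately before and after the flight; must be positive.
#' @return A calibrated \code{field_raster} with \code{"reflectance"}
#'   band semantics.
#' @examples
#' b <- field_raster(matrix(0.1, 2, 2), pixel_size = 1, band = "reflectance")
#' calibrate_reflectance(b, 0.5, 0.25, 0.25)$values[1, 1]  # 0.2
#' @export
calibrate_reflectance <- function(band, panel_known, panel_observed_pre,
                                  panel_observed_post) {
  stopifnot(inherits(band, "field_raster"))
  if (!is.finite(panel_known) || panel_known <= 0 || panel_known > 1) {
    stop("calibration error: 'panel_known' must lie in (0, 1]", call. = FALSE)
  }
  obs <- c(panel_observed_pre, panel_observed_post)
  if (any(!is.finite(obs)) || any(obs <= 0)) {
    stop("calibration error: panel observations must be positive", call. = FALSE)
  }
  g <- panel_known / mean(obs)
  v <- pmin(pmax(band$values * g, 0), 1)
  field_raster(v, origin = band$origin, pixel_size = band$pixel_size,
               band = "reflectance")
}

#' Normalized difference vegetation index
#'
#' NDVI = (NIR - Red) / (NIR + Red), computed per pixel on co-registered
#' reflectance layers. Pixels where the denominator is zero, or masked in
#' either input, are masked in the output. Values are bounded in [-1, 1]
#' by construction.
#'
#' @param red,nir co-registered \code{field_raster} reflectance layers.
#' @return A \code{field_raster} index layer.
#' @export
compute_ndvi <- function(red, nir) {
  check_coregistered(red, nir, "red and nir")
  denom <- nir$values + red$values
  v <- (nir$values - red$values) / denom
  v[!is.na(denom) & denom == 0] <- NA_real_
  field_raster(v, origin = red$origin, pixel_size = red$pixel_size,
               band = "index")
}

#' Segment vegetation from an RGB orthomosaic
#'
#' Scores each pixel with the excess-green index ExG = 2G - R - B and
#' labels it vegetation when ExG exceeds a threshold: 0 for
#' \code{method = "fixed_threshold"}, or a bimodal histogram split
#' (Otsu's criterion on 256 bins over the observed ExG range) for
#' \code{method = "automatic"}. The segmentation criterion is pluggable
#' by thresholding the returned score yourself if neither suits.
#'
#' @param red,green,blue co-registered \code{field_raster} layers with
#'   values in [0, 1].
#' @param method thresholding strategy.
#' @return A \code{field_raster} with \code{"cover"} semantics: 1 for
#'   vegetation, 0 for background, masked where any input is masked. The
#'   threshold used is attached as attribute \code{"threshold"}.
#' @export
segment_vegetation <- function(red, green, blue,
                               method = c("fixed_threshold", "automatic")) {
  method <- match.arg(method)
  check_coregistered(red, green, "red and green")
  check_coregistered(red, blue, "red and blue")
  exg <- 2 * green$values - red$values - blue$values
  obs <- exg[!is.na(exg)]
  if (!length(obs)) stop("empty image: all pixels masked", call. = FALSE)
  t <- if (method == "fixed_threshold") 0 else otsu_threshold(obs)
  v <- ifelse(exg > t, 1, 0)
  v[is.na(exg)] <- NA_real_
  out <- field_raster(v, origin = red$origin, pixel_size = red$pixel_size,
                      band = "cover")
  attr(out, "threshold") <- t
  out
}

# Otsu's between-class variance maximization on a fixed 256-bin histogram.
otsu_threshold <- function(x, bins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = bins)
  w <- cumsum(h)
  mids <- (br[-1] + br[-(bins + 1L)]) / 2
  m <- cumsum(h * mids)
  n <- w[bins]; mt <- m[bins]
  # between-class variance for a cut after bin k
  w0 <- w[-bins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, bins - 1L)
  bcv[valid] <- (mt * w0[valid] - n * m[-bins][valid])^2 /
    (w0[valid] * w1[valid])
  br[which.max(bcv) + 1L]
}

#' Canopy height from surface and ground elevation models
#'
#' Height = max(DSM - ground, 0) per pixel. Small negative differences
#' (sensor noise where the canopy is absent) are clamped to zero rather
#' than masked; the output mask is the union of the input masks.
#'
#' @param dsm digital surface model (\code{field_raster}, meters).
#' @param ground ground elevation model on the same grid.
#' @return A \code{field_raster} height layer (meters, >= 0).
#' @export
compute_height <- function(dsm, ground) {
  check_coregistered(dsm, ground, "dsm and ground")
  v <- pmax(dsm$values - ground$values, 0)
  field_raster(v, origin = dsm$origin, pixel_size = dsm$pixel_size,
               band = "index")
}

#' Assemble co-registered index layers into a stack
#'
#' Collects the per-date candidate covariate layers (cover, height, NDVI)
#' into a named stack after dropping excluded layers — e.g. an early
#' height layer too noisy to use. Layer names follow the
#' \code{<K>_<Mon.DD>} convention with K in C (cover), H (height),
#' N (NDVI).
#'
#' @param layers named list of co-registered \code{field_raster} objects.
#' @param exclude character vector of layer names to drop.
#' @return An \code{index_stack}: list with elements \code{layers}
#'   (named list), \code{m} (layer count), and the shared grid metadata.
#' @examples
#' r <- field_raster(matrix(0.5, 2, 2), pixel_size = 1)
#' s <- build_index_stack(list(C_Mar.14 = r, N_Apr.12 = r))
#' s$m  # 2
#' @export
build_index_stack <- function(layers, exclude = character()) {
  if (!length(layers) || is.null(names(layers)) || any(names(layers) == "")) {
    stop("'layers' must be a non-empty named list", call. = FALSE)
  }
  if (anyDuplicated(names(layers))) {
    stop("duplicate layer names: ",
         paste(unique(names(layers)[duplicated(names(layers))]), collapse = ", "),
         call. = FALSE)
  }
  layers <- layers[!(names(layers) %in% exclude)]
  if (!length(layers)) stop("all layers excluded", call. = FALSE)
  ref <- layers[[1]]
  for (nm in names(layers)) {
    check_coregistered(ref, layers[[nm]], sprintf("stack layers ('%s')", nm))
  }
  structure(list(layers = layers, m = length(layers), origin = ref$origin,
                 pixel_size = ref$pixel_size, dim = dim(ref$values)),
            class = "index_stack")
}

#' @export
print.index_stack <- function(x, ...) {
  cat(sprintf("<index_stack> m = %d layers, %d x %d pixels @ %g m\n",
              x$m, x$dim[1], x$dim[2], x$pixel_size))
  cat("  ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}
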