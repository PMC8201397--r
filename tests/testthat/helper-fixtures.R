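# Shared fixture builders and independent oracles. Everything is built
# in code at test time; no binary fixtures.

uniform_raster <- function(value, nr = 4, nc = 4, pixel_size = 0.5,
                           origin = c(0, 0), band = "index") {
  field_raster(matrix(value, nr, nc), origin = origin,
               pixel_size = pixel_size, band = band)
}

# independent least-squares oracle: normal equations, no QR
ols_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  beta <- solve(crossprod(X1), crossprod(X1, y))
  fitted <- drop(X1 %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  list(coef = drop(beta), rss = rss, r2 = 1 - rss / tss)
}

# two-plot toy layout: plots share the boundary x = 2.1 (off the 0.25-m
# cell lattice, so one cell column straddles both), inside a 6 x 4 field
touching_layout <- function() {
  field_layout(6, 4, data.frame(
    plot_id = c("A", "B"), row_id = "R1",
    cultivar = c("v1", "v2"), sowing_date = "d1", role = "cultivar",
    xmin = c(0.6, 2.1), ymin = 0.5, xmax = c(2.1, 3.6), ymax = 3.5,
    stringsAsFactors = FALSE))
}

# small balanced cell table with known structure, bypassing rasters
tiny_cells <- function(seed = 1, ...) {
  simulate_cell_observations(n_rows = 4, plots_per_row = 5,
                             cells_per_plot = 12, n_cultivars = 5,
                             seed = seed, ...)
}
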