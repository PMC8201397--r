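test_that("grid construction follows the ceiling rule", {
  expect_equal(build_grid(c(0, 0, 1, 1), 0.25)$n_cells, 16)
  g <- build_grid(c(0, 0, 40, 50), 0.25)
  expect_equal(g$n_cols, 160)
  expect_equal(g$n_rows, 200)
  expect_equal(g$n_cells, 32000)
  # non-divisible extent: 1.1 / 0.25 -> 5 columns; brute-force tiling oracle
  g2 <- build_grid(c(0, 0, 1.1, 1.0), 0.25)
  tiles_1d <- function(width) {
    n <- 0L; x <- 0
    while (x < width - 1e-12) { n <- n + 1L; x <- x + 0.25 }
    n
  }
  n_tiles <- tiles_1d(1.1) * tiles_1d(1.0)
  expect_equal(g2$n_cells, 20)
  expect_equal(g2$n_cells, n_tiles)
  expect_equal(cell_area(g2), 0.0625)
  expect_error(build_grid(c(0, 0, 0, 5), 0.25), "degenerate")
})

test_that("cell classification applies the elimination rules", {
  lay <- touching_layout()  # A [0.6,2.1] and B [2.1,3.6], shared edge 2.1
  g <- build_grid(lay, 0.25)
  cells <- classify_cells(g, lay)
  at <- function(x, y) cells[cells$x0 == x & cells$y0 == y, ]
  expect_equal(at(1.0, 1.0)$status, "retained")      # interior of A
  expect_equal(at(1.0, 1.0)$plot_id, "A")
  expect_equal(at(2.5, 1.0)$plot_id, "B")
  # the cell [2.0, 2.25) straddles the shared boundary: touches both plots
  expect_equal(at(2.0, 1.0)$status, "eliminated_two_plots")
  # cell partly in plot A, partly in corridor (A's left edge at x = 0.6)
  expect_equal(at(0.5, 1.0)$status, "eliminated_corridor_mix")
  expect_equal(at(5.5, 0.25)$status, "outside")
  # partition: every cell gets exactly one status and they sum to n_c
  expect_equal(sum(table(cells$status)), g$n_cells)
  expect_true(all(is.na(cells$plot_id[cells$status != "retained"])))
  expect_true(all(!is.na(cells$plot_id[cells$status == "retained"])))
})

test_that("shrinking a plot never increases its retained cells", {
  base <- data.frame(plot_id = "A", row_id = "R1", cultivar = "v1",
                     sowing_date = "d1", role = "cultivar",
                     xmin = 1.13, ymin = 0.9, xmax = 3.47, ymax = 4.1,
                     stringsAsFactors = FALSE)
  count <- function(shrink) {
    p <- base
    p$xmin <- p$xmin + shrink; p$xmax <- p$xmax - shrink
    p$ymin <- p$ymin + shrink; p$ymax <- p$ymax - shrink
    lay <- field_layout(6, 6, p)
    cells <- classify_cells(build_grid(lay, 0.25), lay)
    sum(cells$status == "retained")
  }
  counts <- vapply(seq(0, 0.5, by = 0.05), count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("overlapping plots are a layout error", {
  p <- data.frame(plot_id = c("A", "B"), row_id = "R1", cultivar = "v1",
                  sowing_date = "d1", role = "cultivar",
                  xmin = c(0.5, 1.0), ymin = 0.5, xmax = c(2, 2.5), ymax = 2,
                  stringsAsFactors = FALSE)
  expect_error(field_layout(6, 4, p), "overlapping")
  p2 <- p[1, ]; p2$xmax <- 10
  expect_error(field_layout(6, 4, p2), "inside the field")
})

test_that("full-scale layout matches the trial geometry", {
  exp <- generate_experiment(synthetic_config_field_preset(
    index_noise_sd = 0, pixel_noise_sd = 0, sample_noise_sd = 0))
  lay <- exp$layout
  expect_equal(nrow(lay$plots), 70)
  expect_equal(sum(lay$plots$role == "cultivar"), 56)
  expect_equal(sum(lay$plots$role == "weedy"), 4)
  expect_equal(sum(lay$plots$role == "sheet"), 4)
  expect_equal(sum(lay$plots$role == "destructive"), 6)
  expect_equal(unname(plot_areas(lay)), rep(10.08, 70), tolerance = 1e-12)
  expect_equal(nrow(exp$samples), 154)           # 70 in-plot + 84 adjacent
  expect_equal(sum(!is.na(exp$samples$plot_id)), 70)
  # retained cells per plot: bounded by the 9 x 16 full-cell envelope and
  # never far below it
  cells <- classify_cells(build_grid(lay, 0.25), lay)
  per_plot <- table(cells$plot_id[cells$status == "retained"])
  expect_equal(length(per_plot), 70)
  expect_true(all(per_plot <= floor(2.4 / 0.25) * floor(4.2 / 0.25)))
  expect_true(all(per_plot >= 100))
})

test_that("quadrat covariate means follow the pixel-enumeration oracle", {
  r <- uniform_raster(7, nr = 20, nc = 20, pixel_size = 0.25)
  s <- build_index_stack(list(A = r))
  pts <- data.frame(sample_id = c("p1", "p2"), x = c(2, 4.9), y = c(2, 4.9),
                    plot_id = NA)
  cov <- extract_point_covariates(s, pts)
  expect_equal(cov$A, c(7, 7))                        # uniform value
  expect_equal(cov$n_pixels, c(16, 4))                # edge quadrat clipped
  # quadrat straddling two half-planes of values a and b -> (a + b) / 2
  v <- matrix(rep(c(2, 10), each = 200), 20, 20)  # left half a, right b
  vr <- field_raster(v, pixel_size = 0.25)
  s2 <- build_index_stack(list(A = vr))
  cov2 <- extract_point_covariates(s2, data.frame(sample_id = "q",
                                                  x = 2.5, y = 2, plot_id = NA))
  # oracle by explicit enumeration of pixel centers in [2, 3) x [1.5, 2.5)
  xs <- (seq_len(20) - 0.5) * 0.25; ys <- xs
  sel <- outer(ys >= 1.5 & ys < 2.5, xs >= 2 & xs < 3, FUN = "&")
  expect_equal(cov2$A, mean(v[sel]))
  expect_equal(cov2$A, 6)                              # (2 + 10) / 2
  # quadrat fully outside the raster is flagged, not an error
  cov3 <- extract_point_covariates(s, data.frame(sample_id = "far",
                                                 x = 50, y = 50, plot_id = NA))
  expect_false(cov3$covariates_ok)
  expect_equal(cov3$n_pixels, 0)
})

test_that("masked pixels are excluded from quadrat means", {
  v <- matrix(5, 8, 8); v[1:4, 1:4] <- NA
  s <- build_index_stack(list(A = field_raster(v, pixel_size = 0.25)))
  cov <- extract_point_covariates(s, data.frame(sample_id = "m", x = 1, y = 1,
                                                plot_id = NA))
  expect_equal(cov$A, 5)
  expect_equal(cov$n_pixels, 12)  # 16 centers minus 4 masked
})

test_that("sample joining applies exclusions and reports unmatched ids", {
  ids <- sprintf("S%03d", 1:154)
  cov <- data.frame(sample_id = ids, A = rnorm(154), covariates_ok = TRUE,
                    stringsAsFactors = FALSE)
  harv <- data.frame(sample_id = ids, ear_dry_weight_g = runif(154, 100, 900),
                     stringsAsFactors = FALSE)
  out <- suppressMessages(join_samples(cov, harv,
                                       exclude_ids = ids[c(3, 10:19)]))
  expect_equal(nrow(out), 143)                   # 154 points, 11 excluded
  out2 <- join_samples(cov, harv)
  expect_equal(nrow(out2), 154)
  harv2 <- rbind(harv, data.frame(sample_id = "S999",
                                  ear_dry_weight_g = 500))
  out3 <- suppressMessages(join_samples(cov, harv2))
  expect_equal(attr(out3, "unmatched"), "S999")
  expect_error(join_samples(rbind(cov, cov[1, ]), harv), "duplicate")
})

test_that("layout and points survive a GeoJSON round trip", {
  exp <- generate_experiment(synthetic_config(n_adjacent_samples = 3))
  p <- withr::local_tempfile(fileext = ".geojson")
  write_layout_geojson(exp$layout, p)
  lay2 <- read_layout_geojson(p)
  expect_equal(lay2$plots[c("plot_id", "row_id", "cultivar", "role")],
               exp$layout$plots[c("plot_id", "row_id", "cultivar", "role")])
  expect_equal(lay2$plots$xmin, exp$layout$plots$xmin, tolerance = 1e-12)
  expect_equal(lay2$field_width, exp$layout$field_width)
  q <- withr::local_tempfile(fileext = ".geojson")
  write_points_geojson(exp$samples, q)
  pts2 <- read_points_geojson(q)
  expect_equal(pts2$sample_id, exp$samples$sample_id)
  expect_equal(pts2$x, exp$samples$x, tolerance = 1e-12)
  expect_identical(is.na(pts2$plot_id), is.na(exp$samples$plot_id))
})
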