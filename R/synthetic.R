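#' Configuration for a synthetic UAV field experiment
#'
#' Defines every knob of the simulated trial: field and plot geometry,
#' treatment structure, the latent yield surface (global mean, smooth
#' spatial fertility trend, row and plot random effects, treatment and
#' trait contributions, pixel noise), and how the candidate imagery
#' indices relate to that surface. Indices in \code{true_model_subset}
#' carry an equal share of the yield signal (scaled by their true
#' coefficient) plus an index-specific smooth pattern, so latent yield is
#' exactly linear in the true indices with coefficients
#' \code{true_coefficients}; the remaining candidates are pure noise.
#'
#' The default is a quarter-scale trial (20 m x 25 m, 20 plots of
#' 2.4 m x 4.2 m in 4 rows) that keeps full-pipeline runs fast;
#' \code{\link{synthetic_config_field_preset}} gives the full-scale
#' layout (40 m x 50 m, 70 plots, 14 cultivars, 154 sample points).
#'
#' @param field_width_m,field_height_m field extent, meters.
#' @param plot_rows,plots_per_row plot arrangement.
#' @param plot_width_m,plot_height_m plot rectangle size, meters.
#' @param corridor_m corridor width between adjacent plots, meters.
#' @param n_cultivars number of cultivar levels.
#' @param sowing_dates two sowing-date labels.
#' @param plot_roles optional character vector (length = number of
#'   plots) of roles in \code{cultivar}, \code{weedy}, \code{sheet},
#'   \code{destructive}; default all \code{cultivar}.
#' @param pixel_size_m raster resolution; must be at most 0.125 m so a
#'   0.25-m analysis cell always contains at least 4 pixel centers.
#' @param candidates candidate index layer names
#'   (\code{<K>_<Mon.DD>}, K in C/H/N).
#' @param true_model_subset names of the candidates that truly carry
#'   yield signal; must be a subset of \code{candidates}.
#' @param true_coefficients named vector, yield units per index unit,
#'   one entry per member of \code{true_model_subset}.
#' @param index_baselines named additive baselines, index units.
#' @param base_yield global mean latent yield, g per 1-m2 quadrat.
#' @param spatial_trend_amplitude amplitude of the smooth fertility
#'   trend (linear gradient + fixed-wavelength sinusoid), yield units.
#' @param index_pattern_amplitude amplitude of each true index's own
#'   smooth spatial pattern, expressed in yield units (divided by the
#'   index's coefficient to get index units).
#' @param row_effect_sd,plot_effect_sd SDs of row and plot random
#'   intercepts, yield units.
#' @param cultivar_effects vector of length \code{n_cultivars}, yield
#'   units (fixed cultivar contributions).
#' @param sowing_date_effect additive effect of the second sowing date,
#'   yield units.
#' @param trait_effect_spec named numeric of coefficients on centered
#'   plot traits and their pairwise interactions (names like
#'   \code{"stem_dw"} or \code{"stem_dw:above_dw"}); contributions enter
#'   the plot effect.
#' @param trait_base_means named positive means for \code{stem_dw},
#'   \code{seed_dw}, \code{above_dw}, \code{w100} (grams).
#' @param trait_cultivar_cv,trait_within_cv between-cultivar and
#'   within-cultivar coefficients of variation for traits.
#' @param index_noise_sd per-pixel index noise SD, index units.
#' @param pixel_noise_sd per-pixel latent yield noise SD, yield units.
#' @param sample_noise_sd per-quadrat harvest measurement noise SD,
#'   yield units.
#' @param n_adjacent_samples extra 1-m2 sample points placed in the
#'   corridor/adjacent area outside plots.
#' @param random_seed integer root seed; every generation stage draws
#'   from its own child stream.
#' @return A validated \code{synthetic_config} list.
#' @export
synthetic_config <- function(field_width_m = 20, field_height_m = 25,
                             plot_rows = 4, plots_per_row = 5,
                             plot_width_m = 2.4, plot_height_m = 4.2,
                             corridor_m = 0.8,
                             n_cultivars = 5,
                             sowing_dates = c("Jun.20", "Jul.20"),
                             plot_roles = NULL,
                             pixel_size_m = 0.0625,
                             candidates = c("C_Feb.15", "C_Mar.14", "C_Apr.12",
                                            "H_Mar.14", "H_Apr.12",
                                            "N_Mar.14", "N_Apr.12"),
                             true_model_subset = c("C_Mar.14", "H_Mar.14",
                                                   "C_Apr.12", "N_Apr.12"),
                             true_coefficients = c(C_Mar.14 = 400, H_Mar.14 = 1000,
                                                   C_Apr.12 = 450, N_Apr.12 = 800),
                             index_baselines = c(C_Feb.15 = 0.15, C_Mar.14 = 0.35,
                                                 C_Apr.12 = 0.75, H_Mar.14 = 0.25,
                                                 H_Apr.12 = 0.65, N_Mar.14 = 0.55,
                                                 N_Apr.12 = 0.70),
                             base_yield = 500,
                             spatial_trend_amplitude = 40,
                             index_pattern_amplitude = 30,
                             row_effect_sd = 10, plot_effect_sd = 10,
                             cultivar_effects = seq(-20, 20,
                                                    length.out = n_cultivars),
                             sowing_date_effect = 0,
                             trait_effect_spec = numeric(),
                             trait_base_means = c(stem_dw = 400, seed_dw = 500,
                                                  above_dw = 1100, w100 = 25),
                             trait_cultivar_cv = 0.15, trait_within_cv = 0.05,
                             index_noise_sd = 0.01, pixel_noise_sd = 20,
                             sample_noise_sd = 25,
                             n_adjacent_samples = 12,
                             random_seed = 42L) {
  cfg <- list(field_width_m = field_width_m, field_height_m = field_height_m,
              plot_rows = plot_rows, plots_per_row = plots_per_row,
              plot_width_m = plot_width_m, plot_height_m = plot_height_m,
              corridor_m = corridor_m, n_cultivars = n_cultivars,
              sowing_dates = sowing_dates, plot_roles = plot_roles,
              pixel_size_m = pixel_size_m, candidates = candidates,
              true_model_subset = true_model_subset,
              true_coefficients = true_coefficients,
              index_baselines = index_baselines, base_yield = base_yield,
              spatial_trend_amplitude = spatial_trend_amplitude,
              index_pattern_amplitude = index_pattern_amplitude,
              row_effect_sd = row_effect_sd, plot_effect_sd = plot_effect_sd,
              cultivar_effects = cultivar_effects,
              sowing_date_effect = sowing_date_effect,
              trait_effect_spec = trait_effect_spec,
              trait_base_means = trait_base_means,
              trait_cultivar_cv = trait_cultivar_cv,
              trait_within_cv = trait_within_cv,
              index_noise_sd = index_noise_sd,
              pixel_noise_sd = pixel_noise_sd,
              sample_noise_sd = sample_noise_sd,
              n_adjacent_samples = n_adjacent_samples,
              random_seed = as.integer(random_seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  for (f in c("field_width_m", "field_height_m", "plot_width_m",
              "plot_height_m", "pixel_size_m")) {
    stop_if_not_scalar_pos(cfg[[f]], f)
  }
  if (cfg$pixel_size_m > 0.25 / 2 + 1e-12) {
    stop("pixel_size_m must be <= 0.125 m so every 0.25-m cell holds >= 4 pixel centers",
         call. = FALSE)
  }
  if (length(cfg$sowing_dates) != 2L) {
    stop("exactly two sowing dates are required", call. = FALSE)
  }
  if (!all(cfg$true_model_subset %in% cfg$candidates)) {
    stop("true_model_subset must be a subset of candidates", call. = FALSE)
  }
  if (!all(cfg$true_model_subset %in% names(cfg$true_coefficients))) {
    stop("true_coefficients must name every member of true_model_subset",
         call. = FALSE)
  }
  if (any(cfg$true_coefficients[cfg$true_model_subset] == 0)) {
    stop("true coefficients must be non-zero", call. = FALSE)
  }
  if (length(cfg$cultivar_effects) != cfg$n_cultivars) {
    stop("cultivar_effects must have length n_cultivars", call. = FALSE)
  }
  n_plots <- cfg$plot_rows * cfg$plots_per_row
  if (!is.null(cfg$plot_roles) && length(cfg$plot_roles) != n_plots) {
    stop("plot_roles must have one entry per plot", call. = FALSE)
  }
  if (any(cfg$trait_base_means <= 0)) {
    stop("trait means must be positive", call. = FALSE)
  }
  with(cfg, {
    extra <- trait_base_means["above_dw"] - trait_base_means["stem_dw"] -
      trait_base_means["seed_dw"]
    if (extra <= 0) {
      stop("above_dw mean must exceed stem_dw + seed_dw means", call. = FALSE)
    }
  })
  # arrange_plots() errors if the block with corridors exceeds the field
  arrange_plots(cfg$field_width_m, cfg$field_height_m, cfg$plot_rows,
                cfg$plots_per_row, cfg$plot_width_m, cfg$plot_height_m,
                cfg$corridor_m)
  invisible(cfg)
}

#' Full-scale synthetic field preset
#'
#' The full trial layout: 40 m x 50 m field, 70 plots of 2.4 m x 4.2 m
#' in 7 rows of 10, 14 cultivars on 56 plots plus 4 weedy, 4 sheet-covered
#' and 6 destructive-sampling plots, two sowing dates, and 154 harvest
#' quadrats (one per plot + 84 in the adjacent area).
#'
#' @param ... overrides passed on to \code{\link{synthetic_config}}.
#' @export
synthetic_config_field_preset <- function(...) {
  roles <- rep("cultivar", 70)
  roles[c(31, 32, 33, 66, 67, 68)] <- "destructive"
  roles[c(7, 17, 47, 57)] <- "weedy"
  roles[c(4, 24, 44, 64)] <- "sheet"
  defaults <- list(field_width_m = 40, field_height_m = 50,
                   plot_rows = 7, plots_per_row = 10,
                   corridor_m = 1.2, n_cultivars = 14,
                   plot_roles = roles, pixel_size_m = 0.125,
                   cultivar_effects = seq(-26, 26, length.out = 14),
                   n_adjacent_samples = 84)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

#' Detection-study synthetic preset
#'
#' The preset used for end-to-end power and specificity studies of the
#' cultivar analysis: 80 plots (8 rows x 10) of 2.4 m x 4.2 m on a
#' 32 m x 44 m field, 5 cultivars with 16 plots each (plenty of
#' plot-level replication, so the chi-square reference of the
#' likelihood-ratio test is accurate), coarser 0.125-m pixels for speed,
#' gentle spatial structure (trend 10, row SD 5, plot SD 5 g) and
#' realistic per-pixel index noise (0.08), which after cell averaging
#' leaves a cell-level residual SD around 25-30 g. All cultivar effects
#' default to zero (the null); pass \code{cultivar_effects} to elevate
#' one.
#'
#' @param random_seed integer seed.
#' @param cultivar_effects length-5 effect vector (yield units).
#' @param ... further overrides for \code{\link{synthetic_config}}.
#' @export
synthetic_config_detection_preset <- function(random_seed = 42L,
                                              cultivar_effects = rep(0, 5),
                                              ...) {
  synthetic_config(
    field_width_m = 32, field_height_m = 44,
    plot_rows = 8, plots_per_row = 10, corridor_m = 0.6,
    n_cultivars = 5, cultivar_effects = cultivar_effects,
    pixel_size_m = 0.125,
    spatial_trend_amplitude = 10, index_pattern_amplitude = 5,
    index_noise_sd = 0.08, plot_effect_sd = 5, row_effect_sd = 5,
    n_adjacent_samples = 20, random_seed = random_seed, ...)
}

#' A fully deterministic (noise-free) variant of a configuration
#'
#' Sets every noise SD, random-effect SD and the sowing/cultivar/trait
#' effects that are random in origin to zero, leaving only the global
#' mean, the smooth trend and the index patterns. Under this
#' configuration downstream model selection must recover exactly the
#' true index subset with zero prediction error.
#'
#' @param config a \code{synthetic_config}.
#' @export
synthetic_config_noiseless <- function(config = synthetic_config()) {
  config$index_noise_sd <- 0
  config$pixel_noise_sd <- 0
  config$sample_noise_sd <- 0
  config$row_effect_sd <- 0
  config$plot_effect_sd <- 0
  config
}

# deterministic smooth pattern field, unit amplitude, keyed by layer name
index_pattern <- function(name, seed, X, Y, W, H) {
  par <- with_seed(child_seed(seed, paste0("pattern_", name)), {
    list(a = sample(1:3, 1), b = sample(1:3, 1),
         phi = stats::runif(1, 0, 2 * pi))
  })
  sin(2 * pi * (par$a * X / W + par$b * Y / H) + par$phi)
}

# smooth fertility trend: linear gradient plus fixed 12.5-m sinusoid
spatial_trend <- function(X, Y, W, H, amplitude) {
  amplitude * ((X / W - 0.5) + (Y / H - 0.5)) +
    0.4 * amplitude * sin(2 * pi * X / 12.5)
}

#' Per-plot soybean trait table
#'
#' Draws the four measured soybean traits (stem dry weight, seed dry
#' weight, whole-plant above-ground dry weight, 100-seed weight; grams)
#' per plot around cultivar-specific means. Above-ground weight is built
#' as stem + seed + residual biomass with a positive residual mean, so
#' \code{above_dw >= stem_dw} holds row-wise by construction. Plots
#' without a cultivar label (weedy/sheet/destructive roles) get NA
#' traits.
#'
#' @param config a \code{synthetic_config}.
#' @param cultivar per-plot cultivar labels (NA allowed), one per plot.
#' @param plot_id optional plot ids (default \code{P01, P02, ...}).
#' @return data.frame: plot_id, cultivar, stem_dw, seed_dw, above_dw,
#'   w100.
#' @export
generate_trait_table <- function(config, cultivar, plot_id = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(config$trait_base_means <= 0)) {
    stop("trait means must be positive", call. = FALSE)
  }
  n <- length(cultivar)
  plot_id <- plot_id %||% sprintf("P%02d", seq_len(n))
  levs <- sort(unique(cultivar[!is.na(cultivar)]))
  bm <- config$trait_base_means
  parts <- c(stem_dw = unname(bm["stem_dw"]), seed_dw = unname(bm["seed_dw"]),
             other_dw = unname(bm["above_dw"] - bm["stem_dw"] - bm["seed_dw"]),
             w100 = unname(bm["w100"]))
  cult_means <- with_seed(child_seed(config$random_seed, "trait_cultivar_means"), {
    z <- matrix(stats::rnorm(length(levs) * length(parts)), length(levs),
                dimnames = list(levs, names(parts)))
    sweep(1 + config$trait_cultivar_cv * z, 2, parts, `*`)
  })
  draws <- with_seed(child_seed(config$random_seed, "trait_within"), {
    matrix(stats::rnorm(n * length(parts)), n,
           dimnames = list(NULL, names(parts)))
  })
  out <- data.frame(plot_id = plot_id, cultivar = cultivar,
                    stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, n, length(parts), dimnames = list(NULL, names(parts)))
  has <- !is.na(cultivar)
  for (tn in names(parts)) {
    mu <- cult_means[match(cultivar[has], levs), tn]
    # floor at 2% of the part mean keeps all biomass parts positive
    vals[has, tn] <- pmax(mu * (1 + config$trait_within_cv * draws[has, tn]),
                          0.02 * parts[tn])
  }
  out$stem_dw <- vals[, "stem_dw"]
  out$seed_dw <- vals[, "seed_dw"]
  out$above_dw <- vals[, "stem_dw"] + vals[, "seed_dw"] + vals[, "other_dw"]
  out$w100 <- vals[, "w100"]
  out
}

# plot-level yield contribution of the traits under a named effect spec;
# terms are centered (and products of centered mains re-centered) so the
# spec does not shift the overall mean
trait_contribution <- function(traits, spec) {
  n <- nrow(traits)
  if (!length(spec)) return(numeric(n))
  mains <- c("stem_dw", "seed_dw", "above_dw", "w100")
  has <- !is.na(traits$cultivar)
  z <- sapply(mains, function(v) {
    x <- traits[[v]]
    x[has] <- x[has] - mean(x[has])
    x[!has] <- 0
    x
  })
  out <- numeric(n)
  for (term in names(spec)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% mains)) {
      stop("unknown trait term in trait_effect_spec: ", term, call. = FALSE)
    }
    col <- apply(z[, parts, drop = FALSE], 1, prod)
    if (length(parts) > 1) col[has] <- col[has] - mean(col[has])
    out <- out + spec[[term]] * col
  }
  out
}

#' Generate a complete synthetic experiment
#'
#' Builds the layout, the latent yield surface, the per-date candidate
#' index rasters, the quadrat harvest samples and the ground truth, all
#' reproducibly from \code{config$random_seed}. The latent yield at a
#' pixel is
#' global mean + smooth trend + row effect + plot effect (cultivar +
#' sowing date + trait contributions + plot noise) + pixel noise;
#' true-subset index layers are exact linear carriers of that surface
#' (see \code{\link{synthetic_config}}), the other candidates pure noise.
#' Harvest samples are the quadrat means of the latent surface plus
#' measurement noise, at one point per plot plus
#' \code{n_adjacent_samples} points outside the plots.
#'
#' @param config a \code{synthetic_config}.
#' @return A \code{synthetic_experiment} list: \code{layout}
#'   (\code{\link{field_layout}}), \code{stack}
#'   (\code{\link{build_index_stack}}), \code{samples} (harvest table
#'   with point coordinates), \code{traits}, and \code{truth} (latent
#'   raster, true subset and fixed effects, realized row/plot effects).
#' @export
generate_experiment <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- config$random_seed
  n_plots <- config$plot_rows * config$plots_per_row
  geom <- arrange_plots(config$field_width_m, config$field_height_m,
                        config$plot_rows, config$plots_per_row,
                        config$plot_width_m, config$plot_height_m,
                        config$corridor_m)
  roles <- config$plot_roles %||% rep("cultivar", n_plots)
  cultivar_levels <- sprintf("v%02d", seq_len(config$n_cultivars))
  idx_c <- which(roles == "cultivar")
  assignment <- with_seed(child_seed(seed, "assignment"), {
    pool <- rep_len(cultivar_levels, length(idx_c))
    list(cultivar = sample(pool),
         sowing = sample(rep_len(config$sowing_dates, n_plots)))
  })
  cultivar <- rep(NA_character_, n_plots)
  cultivar[idx_c] <- assignment$cultivar
  plots <- data.frame(geom, cultivar = cultivar,
                      sowing_date = assignment$sowing, role = roles,
                      stringsAsFactors = FALSE)
  layout <- field_layout(config$field_width_m, config$field_height_m, plots)

  traits <- generate_trait_table(config, cultivar, plot_id = plots$plot_id)

  row_levels <- unique(plots$row_id)
  row_eff <- with_seed(child_seed(seed, "row_effects"),
                       stats::rnorm(length(row_levels), 0, config$row_effect_sd))
  names(row_eff) <- row_levels
  plot_re <- with_seed(child_seed(seed, "plot_effects"),
                       stats::rnorm(n_plots, 0, config$plot_effect_sd))
  cult_eff <- stats::setNames(config$cultivar_effects, cultivar_levels)
  treat <- ifelse(is.na(cultivar), 0, cult_eff[cultivar]) +
    ifelse(plots$sowing_date == config$sowing_dates[2],
           config$sowing_date_effect, 0) +
    trait_contribution(traits, as.list(config$trait_effect_spec))
  plot_total <- plot_re + treat

  # pixel grids
  px <- config$pixel_size_m
  nc <- as.integer(round(config$field_width_m / px))
  nr <- as.integer(round(config$field_height_m / px))
  xs <- (seq_len(nc) - 0.5) * px
  ys <- (seq_len(nr) - 0.5) * px
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  W <- config$field_width_m; H <- config$field_height_m

  E <- spatial_trend(X, Y, W, H, config$spatial_trend_amplitude)
  # row effects apply to the row band (plots plus half a corridor)
  for (r in row_levels) {
    pr <- plots[plots$row_id == r, ]
    y0 <- min(pr$ymin) - config$corridor_m / 2
    y1 <- max(pr$ymax) + config$corridor_m / 2
    E[ys >= y0 & ys < y1, ] <- E[ys >= y0 & ys < y1, ] + row_eff[r]
  }
  for (k in seq_len(n_plots)) {
    ii <- which(ys >= plots$ymin[k] & ys < plots$ymax[k])
    jj <- which(xs >= plots$xmin[k] & xs < plots$xmax[k])
    E[ii, jj] <- E[ii, jj] + plot_total[k]
  }

  subset_names <- config$true_model_subset
  beta <- config$true_coefficients[subset_names]
  m_s <- length(subset_names)
  patterns <- lapply(subset_names,
                     function(nm) index_pattern(nm, seed, X, Y, W, H))
  names(patterns) <- subset_names

  latent <- config$base_yield + E
  layers <- vector("list", length(config$candidates))
  names(layers) <- config$candidates
  for (nm in config$candidates) {
    b0 <- unname(config$index_baselines[nm] %||% 0)
    if (is.na(b0)) b0 <- 0
    noise <- if (config$index_noise_sd > 0) {
      with_seed(child_seed(seed, paste0("index_noise_", nm)),
                matrix(stats::rnorm(nr * nc, 0, config$index_noise_sd), nr, nc))
    } else 0
    if (nm %in% subset_names) {
      own <- (config$index_pattern_amplitude / beta[nm]) * patterns[[nm]]
      v <- b0 + E / (m_s * beta[nm]) + own + noise
      latent <- latent + beta[nm] * own
    } else {
      v <- b0 + noise + 0 * E
    }
    layers[[nm]] <- field_raster(v, origin = c(0, 0), pixel_size = px,
                                 band = "index")
  }
  if (config$pixel_noise_sd > 0) {
    latent <- latent + with_seed(child_seed(seed, "pixel_noise"),
                                 matrix(stats::rnorm(nr * nc, 0,
                                                     config$pixel_noise_sd),
                                        nr, nc))
  }
  latent_r <- field_raster(latent, origin = c(0, 0), pixel_size = px,
                           band = "index")
  stack <- build_index_stack(layers)

  # sample points: one per plot center, plus adjacent points whose 1-m
  # quadrats avoid all plots
  pts <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_plots)),
    x = (plots$xmin + plots$xmax) / 2,
    y = (plots$ymin + plots$ymax) / 2,
    plot_id = plots$plot_id, stringsAsFactors = FALSE)
  n_adj <- config$n_adjacent_samples
  if (n_adj > 0) {
    adj <- with_seed(child_seed(seed, "adjacent_points"), {
      found <- matrix(numeric(0), ncol = 2)
      tries <- 0L
      while (nrow(found) < n_adj && tries < 50000L) {
        tries <- tries + 1L
        cx <- stats::runif(1, 0.5, W - 0.5)
        cy <- stats::runif(1, 0.5, H - 0.5)
        clear <- !any(cx + 0.5 > plots$xmin - 1e-9 & cx - 0.5 < plots$xmax + 1e-9 &
                      cy + 0.5 > plots$ymin - 1e-9 & cy - 0.5 < plots$ymax + 1e-9)
        far <- !nrow(found) ||
          min((found[, 1] - cx)^2 + (found[, 2] - cy)^2) > 1
        if (clear && far) found <- rbind(found, c(cx, cy))
      }
      if (nrow(found) < n_adj) {
        stop("could not place the requested adjacent sample points; ",
             "reduce n_adjacent_samples or widen corridors", call. = FALSE)
      }
      found
    })
    pts <- rbind(pts, data.frame(
      sample_id = sprintf("S%03d", n_plots + seq_len(n_adj)),
      x = adj[, 1], y = adj[, 2], plot_id = NA_character_,
      stringsAsFactors = FALSE))
  }

  latent_stack <- build_index_stack(list(latent = latent_r))
  qm <- extract_point_covariates(latent_stack, pts, quadrat_size_m = 1)
  y_true <- qm$latent
  noise_s <- if (config$sample_noise_sd > 0) {
    with_seed(child_seed(seed, "sample_noise"),
              stats::rnorm(nrow(pts), 0, config$sample_noise_sd))
  } else 0
  straw_noise <- with_seed(child_seed(seed, "straw"),
                           stats::rnorm(nrow(pts), 0, 10))
  samples <- data.frame(
    pts,
    ear_dry_weight_g = y_true + noise_s,
    straw_dry_weight_g = pmax(0.8 * y_true + straw_noise, 0),
    mature_ear_count = pmax(1L, as.integer(round(y_true / 1.7))),
    stringsAsFactors = FALSE)

  true_intercept <- config$base_yield -
    sum(beta * vapply(subset_names, function(nm) {
      b0 <- unname(config$index_baselines[nm] %||% 0)
      if (is.na(b0)) 0 else b0
    }, numeric(1)))
  truth <- list(
    latent = latent_r,
    true_model_subset = subset_names,
    true_fixed_effects = c("(Intercept)" = unname(true_intercept), beta),
    row_effects = row_eff,
    plot_effects = data.frame(plots[c("plot_id", "row_id", "cultivar",
                                      "sowing_date", "role")],
                              random_intercept = plot_re,
                              treatment_effect = treat,
                              total_effect = plot_total,
                              stringsAsFactors = FALSE),
    cultivar_effects = cult_eff)
  structure(list(layout = layout, stack = stack, samples = samples,
                 traits = traits, truth = truth, config = config),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("<synthetic_experiment> %g x %g m, %d plots, %d sample points, m = %d indices\n",
              x$config$field_width_m, x$config$field_height_m,
              nrow(x$layout$plots), nrow(x$samples), x$stack$m))
  cat(sprintf("  true subset: %s\n", paste(x$truth$true_model_subset,
                                           collapse = ", ")))
  invisible(x)
}

#' Simulate cell-level observations for mixed-model studies
#'
#' Direct generator of the cell-level analysis table (skipping rasters):
#' yield of cell in plot j of row r = intercept + cultivar effect +
#' sowing-date effect + trait contribution + row effect + plot effect +
#' cell noise. Used for parameter-recovery, type-I-error and power
#' studies of the mixed-model stage at small cost.
#'
#' @param n_rows,plots_per_row,cells_per_plot design size.
#' @param n_cultivars cultivar levels, assigned to plots in balanced
#'   random order.
#' @param cultivar_effects fixed cultivar contributions (yield units);
#'   default all zero (the null).
#' @param sowing_date_effect additive effect of the second sowing date.
#' @param intercept grand mean.
#' @param sd_row,sd_plot,sd_cell SDs of the row intercept, the
#'   plot-within-row intercept, and the cell residual.
#' @param trait_effect_spec optional named coefficients on centered plot
#'   traits (see \code{\link{synthetic_config}}); when non-NULL the four
#'   trait columns are generated and contribute to plot effects.
#' @param balanced assign cultivars and sowing dates in a rotating
#'   balanced pattern (each cultivar equally often in every row, crossed
#'   with sowing date) instead of at random; balanced designs make the
#'   fixed-effect estimator independent of the variance components.
#' @param seed integer seed.
#' @return data.frame: cell_id, plot_id, row_id, cultivar, sowing_date,
#'   trait columns, yield.
#' @export
simulate_cell_observations <- function(n_rows = 8, plots_per_row = 10,
                                       cells_per_plot = 10, n_cultivars = 5,
                                       cultivar_effects = rep(0, n_cultivars),
                                       sowing_date_effect = 0,
                                       intercept = 500,
                                       sd_row = 10, sd_plot = 10, sd_cell = 30,
                                       trait_effect_spec = NULL,
                                       balanced = FALSE,
                                       seed = 1L) {
  stopifnot(length(cultivar_effects) == n_cultivars)
  n_plots <- n_rows * plots_per_row
  levs <- sprintf("v%02d", seq_len(n_cultivars))
  with_seed(seed, {
    if (balanced) {
      cult <- unlist(lapply(seq_len(n_rows) - 1L, function(r) {
        levs[(seq_len(plots_per_row) - 1L + r) %% n_cultivars + 1L]
      }))
      sow <- rep_len(c("d1", "d2"), n_plots)
    } else {
      cult <- sample(rep_len(levs, n_plots))
      sow <- sample(rep_len(c("d1", "d2"), n_plots))
    }
    row_id <- rep(sprintf("R%d", seq_len(n_rows)), each = plots_per_row)
    plot_id <- sprintf("P%02d", seq_len(n_plots))
    row_e <- stats::rnorm(n_rows, 0, sd_row)
    plot_e <- stats::rnorm(n_plots, 0, sd_plot)
    traits <- NULL
    trait_c <- numeric(n_plots)
    cfg <- synthetic_config(n_cultivars = n_cultivars,
                            cultivar_effects = rep(0, n_cultivars),
                            random_seed = seed)
    traits <- generate_trait_table(cfg, cult, plot_id = plot_id)
    if (!is.null(trait_effect_spec)) {
      trait_c <- trait_contribution(traits, as.list(trait_effect_spec))
    }
    plot_mean <- intercept +
      stats::setNames(cultivar_effects, levs)[cult] +
      ifelse(sow == "d2", sowing_date_effect, 0) +
      row_e[rep(seq_len(n_rows), each = plots_per_row)] + plot_e + trait_c
    n <- n_plots * cells_per_plot
    idx <- rep(seq_len(n_plots), each = cells_per_plot)
    data.frame(
      cell_id = sprintf("c%05d", seq_len(n)),
      plot_id = plot_id[idx], row_id = row_id[idx],
      cultivar = factor(cult[idx], levels = levs),
      sowing_date = factor(sow[idx]),
      stem_dw = traits$stem_dw[idx], seed_dw = traits$seed_dw[idx],
      above_dw = traits$above_dw[idx], w100 = traits$w100[idx],
      yield = plot_mean[idx] + stats::rnorm(n, 0, sd_cell),
      stringsAsFactors = FALSE)
  })
}
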