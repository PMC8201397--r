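test_that("with no group variance the mixed model collapses to least squares", {
  # balanced assignment: the GLS estimator coincides with OLS whatever
  # the (near-zero) variance components are estimated to be
  d <- simulate_cell_observations(sd_row = 0, sd_plot = 0, sd_cell = 25,
                                  cultivar_effects = c(0, 10, 20, 30, 40),
                                  balanced = TRUE, seed = 2)
  fit <- fit_cell_lmm(d, c("sowing_date", "cultivar"), "REML")
  ols <- lm(yield ~ sowing_date + cultivar, data = d)
  expect_equal(fit$fixed, coef(ols), tolerance = 1e-4)
  # spurious group variance stays a small fraction of the residual
  expect_lt(fit$varcomp["row"], 0.05 * fit$varcomp["residual"])
  expect_lt(fit$varcomp["plot"], 0.05 * fit$varcomp["residual"])
  # intercept-only fixed part with no variance components: the estimate
  # is the arithmetic mean
  d0 <- simulate_cell_observations(sd_row = 0, sd_plot = 0,
                                   balanced = TRUE, seed = 3)
  f0 <- fit_cell_lmm(d0, character(), "REML")
  expect_equal(unname(f0$fixed), mean(d0$yield), tolerance = 1e-3)
})

test_that("likelihood-ratio machinery handles edge cases", {
  d <- tiny_cells(seed = 4)
  same <- lrt_fixed_effect(d, c("sowing_date", "cultivar"),
                           c("cultivar", "sowing_date"))
  expect_equal(same$statistic, 0, tolerance = 1e-6)
  expect_equal(same$p.value, 1)
  expect_error(lrt_fixed_effect(d, "sowing_date", "cultivar"), "non-nested")
  # affine rescaling of a covariate leaves the LRT invariant
  d$x <- d$stem_dw
  a <- lrt_fixed_effect(d, c("sowing_date", "x"), "sowing_date")
  d$x <- 100 * d$stem_dw - 7000
  b <- lrt_fixed_effect(d, c("sowing_date", "x"), "sowing_date")
  expect_equal(a$statistic, b$statistic, tolerance = 1e-6)
})

test_that("REML and ML fixed effects agree on balanced data", {
  d <- simulate_cell_observations(cultivar_effects = c(0, 5, 10, 15, 20),
                                  balanced = TRUE, seed = 5)
  f_reml <- fit_cell_lmm(d, c("sowing_date", "cultivar"), "REML")
  f_ml <- fit_cell_lmm(d, c("sowing_date", "cultivar"), "ML")
  expect_equal(f_reml$fixed, f_ml$fixed, tolerance = 1e-3)
})

test_that("cultivar analysis recodes to the lowest level and contrasts the rest", {
  d <- simulate_cell_observations(
    n_rows = 4, plots_per_row = 7, cells_per_plot = 12, n_cultivars = 14,
    cultivar_effects = c(-40, rep(0, 12), 60), sd_plot = 5, seed = 11)
  res <- cultivar_analysis(d)
  expect_equal(nrow(res$contrasts), 13)            # k - 1 contrasts
  expect_equal(res$reference, "v01")               # the depressed cultivar
  expect_false(res$reference %in% res$contrasts$cultivar)
  # the strongly elevated cultivar is flagged at the ** level
  expect_equal(res$contrasts$signif[res$contrasts$cultivar == "v14"], "**")
  expect_lt(res$lrt_cultivar$p.value, 0.001)
  expect_s4_class(res$fit$model, "lmerMod")
  # explicit reference override is honoured
  res2 <- cultivar_analysis(d, reference = "v05")
  expect_equal(res2$reference, "v05")
  expect_equal(nrow(res2$contrasts), 13)
})

test_that("single-plot cultivars warn instead of erroring", {
  d <- simulate_cell_observations(n_rows = 4, plots_per_row = 4,
                                  cells_per_plot = 8, n_cultivars = 10,
                                  seed = 12)
  expect_warning(cultivar_analysis(d), "single plot")
})

test_that("trait analysis carries 11 fixed coefficients and finds a true interaction", {
  d <- simulate_cell_observations(
    trait_effect_spec = c("stem_dw:above_dw" = 0.002),
    sd_plot = 5, seed = 13)
  res <- trait_analysis(d)
  expect_length(res$fit$fixed, 11)                 # 1 + 4 + choose(4, 2)
  expect_equal(nrow(res$lrt), 10)
  p_int <- res$lrt$p.value[res$lrt$term == "stem_dw:above_dw"]
  expect_lt(p_int, 0.05)
  # constant traits across plots are a collinearity error
  d2 <- d; d2$w100 <- 25
  expect_error(trait_analysis(d2), "collinearity")
})

test_that("null interactions stay null across replicates", {
  # with an all-zero trait spec every deletion test is a null test; over
  # replicates the other interactions' p-values stay spread out
  ps <- vapply(1:25, function(i) {
    d <- simulate_cell_observations(n_rows = 5, plots_per_row = 8,
                                    cells_per_plot = 6, seed = 400 + i)
    res <- trait_analysis(d)
    stats::median(res$lrt$p.value[grepl(":", res$lrt$term)])
  }, numeric(1))
  expect_gt(stats::median(ps), 0.2)
})

test_that("marginal-effect surfaces follow the fitted closed form", {
  d <- simulate_cell_observations(
    trait_effect_spec = c("stem_dw" = -0.3, "stem_dw:above_dw" = 0.002),
    sd_plot = 5, seed = 14)
  # without the interaction the focal lines are parallel
  f_add <- fit_cell_lmm(d, c("stem_dw", "above_dw"), "REML")
  me <- marginal_effects(f_add, "stem_dw", "above_dw",
                         focal_values = c(300, 400),
                         moderator_values = c(900, 1100, 1300))
  slopes <- tapply(me$predicted, me$above_dw,
                   function(p) diff(p) / 100)
  expect_lt(max(abs(diff(unlist(slopes)))), 1e-10)
  # with the interaction the focal slope is beta_f + beta_int * moderator
  f_int <- fit_cell_lmm(d, c("stem_dw", "above_dw", "stem_dw:above_dw"),
                        "REML")
  b <- f_int$fixed
  me2 <- marginal_effects(f_int, "stem_dw", "above_dw",
                          focal_values = c(300, 400),
                          moderator_values = c(900, 1300))
  sl <- tapply(me2$predicted, me2$above_dw, function(p) diff(p) / 100)
  expect_equal(as.numeric(unlist(sl)),
               unname(b["stem_dw"] + b["stem_dw:above_dw"] * c(900, 1300)),
               tolerance = 1e-8)
  # the slope changes sign across a moderator range bracketing
  # -beta_focal / beta_interaction
  flip <- -b["stem_dw"] / b["stem_dw:above_dw"]
  me3 <- marginal_effects(f_int, "stem_dw", "above_dw",
                          focal_values = c(300, 400),
                          moderator_values = unname(c(flip - 200, flip + 200)))
  sl3 <- unlist(tapply(me3$predicted, me3$above_dw,
                       function(p) diff(p) / 100))
  expect_lt(sl3[1] * sl3[2], 0)
  # prediction with every covariate at its mean equals the mean linear
  # predictor of an additive model
  me4 <- marginal_effects(f_add, "stem_dw", "above_dw",
                          focal_values = mean(d$stem_dw),
                          moderator_values = mean(d$above_dw))
  expect_equal(me4$predicted,
               unname(b2 <- sum(f_add$fixed * c(1, mean(d$stem_dw),
                                                mean(d$above_dw)))),
               tolerance = 1e-9)
})
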