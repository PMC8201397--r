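test_that("least-squares fit matches hand examples and flags exact fits", {
  f <- fit_gaussian_glm(data.frame(x = 0:3), c(1, 3, 5, 7))
  expect_equal(unname(coef(f)), c(1, 2), tolerance = 1e-12)
  expect_equal(f$r.squared, 1)
  expect_true(f$degenerate)
  expect_error(model_aic(f), "degenerate")
  # intercept-only model
  f0 <- fit_gaussian_glm(data.frame(), c(1, 2, 3, 10))
  expect_equal(unname(coef(f0)), 4)
  expect_equal(f0$k, 2)
  expect_error(fit_gaussian_glm(data.frame(a = 1:4, b = 1:4), c(1, 3, 2, 5)),
               "singularity")
})

test_that("coefficients, RSS and R2 agree with a normal-equations oracle", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(8:50, 1)
    m <- sample(1:5, 1)
    X <- matrix(rnorm(n * m), n, m,
                dimnames = list(NULL, paste0("x", seq_len(m))))
    beta <- rnorm(m + 1, sd = 2)
    y <- drop(cbind(1, X) %*% beta) + rnorm(n)
    f <- fit_gaussian_glm(as.data.frame(X), y)
    o <- ols_oracle(X, y)
    expect_equal(unname(coef(f)), unname(o$coef), tolerance = 1e-8)
    expect_equal(f$rss, o$rss, tolerance = 1e-8)
    expect_equal(f$r.squared, o$r2, tolerance = 1e-8)
  }
})

test_that("AIC uses the full Gaussian likelihood and counts sigma^2", {
  # n = 20, RSS = 20, one predictor: logLik = -10 (log 2 pi + 1)
  set.seed(5)
  x <- rnorm(20)
  y <- rnorm(20)
  f <- fit_gaussian_glm(data.frame(x = x), y)
  scale <- sqrt(20 / f$rss)          # rescale residuals so RSS = 20
  y2 <- f$fitted.values + f$residuals * scale
  f2 <- fit_gaussian_glm(data.frame(x = x), y2)
  expect_equal(f2$rss, 20, tolerance = 1e-9)
  expect_equal(f2$logLik, -10 * (log(2 * pi) + 1), tolerance = 1e-9)
  expect_equal(model_aic(f2), 62.7576, tolerance = 1e-3)
  expect_equal(f2$k, 3)
  # a four-predictor model reports k = 6 (intercept + 4 slopes + sigma^2)
  X <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("x", 1:4)))
  f4 <- fit_gaussian_glm(as.data.frame(X), rnorm(30))
  expect_equal(f4$k, 6)
  # consistent with stats::AIC through the logLik method
  expect_equal(stats::AIC(f4), model_aic(f4))
})

test_that("subset enumeration is exhaustive, unique and guarded", {
  specs <- enumerate_models(paste0("v", 1:7))
  expect_length(specs, 128)
  expect_equal(anyDuplicated(vapply(specs, paste, "", collapse = "+")), 0L)
  expect_identical(specs[[1]], character())
  expect_length(enumerate_models("a"), 2)
  expect_error(enumerate_models(paste0("v", 1:21)), "force")
  expect_length(enumerate_models(paste0("v", 1:21), force = TRUE), 2^21)
  expect_error(enumerate_models(c("a", "a")), "unique")
})

test_that("ranking computes Akaike differences, weights and tie-breaks", {
  set.seed(6)
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  y <- 1 + X$a + rnorm(30)
  f1 <- fit_gaussian_glm(X["a"], y)
  f2 <- fit_gaussian_glm(X, y)
  tab <- rank_models(list(f2, f1))
  expect_equal(tab$delta_aic[1], 0)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(tab$weight) <= 0))
  # equal AIC -> equal weights 0.5
  tab2 <- rank_models(list(f1, f1))
  expect_equal(tab2$weight, c(0.5, 0.5), tolerance = 1e-12)
  # AIC tie with different k: smaller model wins rank 1
  g1 <- f1; g2 <- f2
  g2$aic <- g1$aic
  tab3 <- rank_models(list(g2, g1))
  expect_equal(tab3$df[1], g1$k)
  expect_equal(best_model(tab3)$spec, "a")
})

test_that("weight ratios reproduce the published selection-table rows", {
  # the published table prints AIC to 1 dp but its AIC differences to
  # 2 dp, so the differences column is the faithful anchor; with the
  # printed best-model weight, w_i = w_1 * exp(-delta_i / 2) must give
  # back every printed weight (ranks 1-5 and 16-20) after 3-dp rounding
  printed_delta <- c(0, 0.03, 0.21, 0.23, 0.47, 1.66, 3.21, 3.5, 4.01, 4.74)
  aic <- 2375.4 + printed_delta
  printed_weight <- c(0.082, 0.081, 0.074, 0.073, 0.065,
                      0.036, 0.016, 0.014, 0.011, 0.008)
  aw <- akaike_weights(aic)
  expect_equal(aw$delta, printed_delta, tolerance = 1e-9)
  rel <- aw$weight / aw$weight[1]           # exp(-delta/2), denominator-free
  expect_equal(rel, exp(-aw$delta / 2), tolerance = 1e-12)
  expect_equal(round(printed_weight[1] * rel, 3), printed_weight)
})

test_that("the all-subsets search recovers the generating subset without noise", {
  cfg <- synthetic_config_noiseless()
  exp <- generate_experiment(cfg)
  cov <- extract_point_covariates(exp$stack, exp$samples)
  md <- join_samples(cov, exp$samples[c("sample_id", "ear_dry_weight_g")])
  sel <- suppressMessages(select_yield_model(md))
  expect_setequal(sel$best$spec, exp$truth$true_model_subset)
  expect_equal(coef(sel$best)[names(exp$truth$true_fixed_effects)],
               exp$truth$true_fixed_effects, tolerance = 1e-6)
  # constant decoy layers make supersets containing them rank-deficient
  expect_equal(length(sel$dropped_specs), 128 - 2^4)
  # single-model table returns that model
  one <- rank_models(list(sel$best))
  expect_identical(best_model(one)$spec, sel$best$spec)
})

test_that("selection objects expose the standard modelling methods", {
  exp <- generate_experiment(synthetic_config())
  res <- analyze_experiment(exp)
  sel <- res$selection
  expect_s3_class(sel, "yield_model_selection")
  expect_equal(nrow(sel$table), 128)
  expect_named(coef(sel)[1], "(Intercept)")
  expect_equal(length(fitted(sel)), sel$n)
  expect_equal(fitted(sel) + residuals(sel), sel$data$ear_dry_weight_g,
               tolerance = 1e-9, ignore_attr = TRUE)
  nd <- sel$data[1:3, sel$best$spec]
  expect_equal(unname(predict(sel, nd)), unname(fitted(sel)[1:3]),
               tolerance = 1e-9)
  expect_output(print(sel), "Best model coefficients")
  expect_output(print(summary(sel)), "Selection over 128 models")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(sel))
})

test_that("best models survive the plain-text serialization round trip", {
  exp <- generate_experiment(synthetic_config())
  res <- analyze_experiment(exp)
  p <- withr::local_tempfile(fileext = ".txt")
  write_best_model(res$selection$best, p)
  back <- read_best_model(p)
  expect_equal(back$spec, res$selection$best$spec)
  expect_equal(back$coefficients, res$selection$best$coefficients,
               tolerance = 1e-12)
  map1 <- predict_pixels(res$selection$best, exp$stack)
  map2 <- predict_pixels(back, exp$stack)
  expect_equal(map1$values, map2$values, tolerance = 1e-10)
})
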