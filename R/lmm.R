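# Statistical testing stage: Gaussian identity-link mixed models on the
# dense cell-level predictions. "GLMM with Gaussian distribution and
# identity link" is a linear mixed model, and is fitted as such with
# lme4. The random structure is always a row intercept plus a plot
# intercept nested in row: repeated cells from one plot are correlated,
# and omitting the plot intercept would treat them as independent
# replicates (pseudo-replication), inflating type-I error — see the
# package vignette for the simulation demonstrating this.

lmm_formula <- function(fixed, response = "yield", include_plot = TRUE) {
  re <- if (include_plot) {
    c("(1 | row_id)", "(1 | row_id:plot_id)")
  } else {
    "(1 | row_id)"
  }
  rhs <- c(if (length(fixed)) fixed else "1", re)
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Fit the cell-level linear mixed model
#'
#' Fits \code{response ~ fixed terms + (1 | row) + (1 | plot-in-row)} by
#' ML or REML. Variance components may be estimated at the zero
#' boundary; that is reported, not an error.
#'
#' @param data cell observation table with columns \code{row_id},
#'   \code{plot_id}, the fixed-effect columns and the response.
#' @param fixed character vector of fixed-effect terms (e.g.
#'   \code{c("sowing_date", "cultivar")}); empty for intercept-only.
#' @param criterion \code{"REML"} (coefficient reporting) or \code{"ML"}
#'   (likelihood-ratio testing).
#' @param response response column name.
#' @param include_plot keep the plot-within-row random intercept
#'   (default TRUE; set FALSE only to demonstrate pseudo-replication).
#' @return A \code{cell_lmm}: fixed-effect estimates and standard
#'   errors, variance components (row, plot, residual), log-likelihood,
#'   the underlying \code{lmerMod} in \code{$model}, and the model frame
#'   in \code{$data}.
#' @export
fit_cell_lmm <- function(data, fixed = character(),
                         criterion = c("REML", "ML"), response = "yield",
                         include_plot = TRUE) {
  criterion <- match.arg(criterion)
  data <- droplevels(as.data.frame(data))
  if (length(unique(data$row_id)) < 2) {
    stop("need at least 2 rows (blocks) for the row random effect",
         call. = FALSE)
  }
  f <- lmm_formula(fixed, response, include_plot)
  ctrl <- lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
    check.scaleX = "ignore")
  m <- tryCatch(
    suppressMessages(lme4::lmer(f, data = data, REML = criterion == "REML",
                                control = ctrl)),
    error = function(e) {
      if (grepl("rank deficient|is computationally singular|dropping", conditionMessage(e))) {
        stop("singularity error: collinear fixed effects", call. = FALSE)
      }
      stop(e)
    })
  if (!is.null(m@optinfo$conv$opt) && m@optinfo$conv$opt != 0) {
    stop("mixed-model optimizer failed to converge: ",
         paste(unlist(m@optinfo$conv$lme4$messages), collapse = "; "),
         call. = FALSE)
  }
  vc <- as.data.frame(lme4::VarCorr(m))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[1] else 0
  }
  structure(list(
    model = m, formula = f, criterion = criterion, fixed_terms = fixed,
    response = response, include_plot = include_plot,
    fixed = lme4::fixef(m),
    se = sqrt(diag(as.matrix(stats::vcov(m)))),
    varcomp = c(row = getv("row_id"),
                plot = if (include_plot) getv("row_id:plot_id") else NA_real_,
                residual = getv("Residual")),
    logLik = as.numeric(stats::logLik(m)),
    n = nrow(data), data = data), class = "cell_lmm")
}

#' @export
print.cell_lmm <- function(x, ...) {
  cat(sprintf("<cell_lmm> %s (%s), n = %d\n", deparse(x$formula),
              x$criterion, x$n))
  tab <- data.frame(estimate = x$fixed, se = x$se)
  print(round(tab, 4))
  cat("variance components:\n")
  print(round(x$varcomp, 4))
  invisible(x)
}

#' @export
coef.cell_lmm <- function(object, ...) object$fixed

#' @export
logLik.cell_lmm <- function(object, ...) stats::logLik(object$model)

#' Likelihood-ratio test between nested fixed-effect structures
#'
#' Both models are fitted by ML (REML likelihoods are not comparable
#' across fixed structures); the statistic \code{2 * (logLik_full -
#' logLik_reduced)} is clamped at 0 and referred to a chi-square with
#' df = the difference in fixed-effect coefficient count.
#'
#' @param data cell observation table.
#' @param full,reduced character vectors of fixed-effect terms;
#'   \code{reduced} must be a subset of \code{full}.
#' @inheritParams fit_cell_lmm
#' @return An \code{lrt_result}: statistic, df, p.value.
#' @export
lrt_fixed_effect <- function(data, full, reduced, response = "yield",
                             include_plot = TRUE) {
  if (!all(reduced %in% full)) {
    stop("non-nested models: 'reduced' must be a subset of 'full'",
         call. = FALSE)
  }
  mf <- fit_cell_lmm(data, full, "ML", response, include_plot)
  mr <- fit_cell_lmm(data, reduced, "ML", response, include_plot)
  df <- length(mf$fixed) - length(mr$fixed)
  if (identical(sort(full), sort(reduced))) df <- max(df, 0L)
  stat <- max(0, 2 * (mf$logLik - mr$logLik))
  p <- if (df >= 1) stats::pchisq(stat, df, lower.tail = FALSE) else 1
  structure(list(statistic = stat, df = df, p.value = p,
                 full = full, reduced = reduced),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT [%s] vs [%s]: chisq = %.3f, df = %d, p = %.4g\n",
              paste(x$full, collapse = " + "),
              if (length(x$reduced)) paste(x$reduced, collapse = " + ")
              else "1",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

p_stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

#' Cultivar analysis of predicted cell yields
#'
#' The first statistical-testing analysis: fits
#' \code{yield ~ sowing_date + cultivar} with row and plot-in-row random
#' intercepts, likelihood-ratio tests for both fixed terms, then recodes
#' the cultivar factor so the level with the lowest estimated marginal
#' mean (averaged over sowing dates) is the reference and reports Wald z
#' contrasts of every other level against it. Significance marks follow
#' the raw, uncorrected convention (* p < 0.05, ** p < 0.01); pass the
#' result through \code{stats::p.adjust} yourself if a correction is
#' wanted.
#'
#' @param data cell observation table (rows with NA cultivar are
#'   dropped).
#' @param reference optional cultivar level to use as reference instead
#'   of the estimated-lowest.
#' @inheritParams fit_cell_lmm
#' @return A \code{cultivar_test}: REML fit, \code{lrt_cultivar},
#'   \code{lrt_sowing}, estimated marginal means, reference level and
#'   the contrast table.
#' @export
cultivar_analysis <- function(data, reference = NULL, response = "yield",
                              include_plot = TRUE) {
  data <- as.data.frame(data)
  data <- droplevels(data[!is.na(data$cultivar), , drop = FALSE])
  data$cultivar <- factor(data$cultivar)
  data$sowing_date <- factor(data$sowing_date)
  if (nlevels(data$cultivar) < 2) {
    stop("need at least 2 cultivar levels", call. = FALSE)
  }
  plots_per_cult <- tapply(data$plot_id, data$cultivar,
                           function(p) length(unique(p)))
  if (any(plots_per_cult < 2)) {
    warning("cultivar(s) with a single plot: ",
            paste(names(plots_per_cult)[plots_per_cult < 2], collapse = ", "),
            " (contrast SEs will be inflated)", call. = FALSE)
  }
  full <- c("sowing_date", "cultivar")
  lrt_c <- lrt_fixed_effect(data, full, "sowing_date", response, include_plot)
  lrt_s <- lrt_fixed_effect(data, full, "cultivar", response, include_plot)
  fit0 <- fit_cell_lmm(data, full, "REML", response, include_plot)
  # estimated marginal means: predictions on the cultivar x sowing grid,
  # averaged over sowing dates with equal weight, random effects at 0
  grid <- expand.grid(sowing_date = levels(data$sowing_date),
                      cultivar = levels(data$cultivar))
  X <- stats::model.matrix(~ sowing_date + cultivar, grid)
  # guard against coefficients dropped for rank deficiency
  X <- X[, names(fit0$fixed), drop = FALSE]
  pred <- drop(X %*% fit0$fixed)
  emm <- tapply(pred, grid$cultivar, mean)
  reference <- reference %||% names(which.min(emm))
  if (!reference %in% levels(data$cultivar)) {
    stop("unknown reference cultivar: ", reference, call. = FALSE)
  }
  data$cultivar <- stats::relevel(data$cultivar, ref = reference)
  fit <- fit_cell_lmm(data, full, "REML", response, include_plot)
  cn <- names(fit$fixed)
  is_c <- startsWith(cn, "cultivar")
  est <- fit$fixed[is_c]; se <- fit$se[is_c]
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  contrasts <- data.frame(
    cultivar = sub("^cultivar", "", cn[is_c]),
    estimate = unname(est), se = unname(se), z = unname(z),
    p.value = unname(p), signif = p_stars(p), stringsAsFactors = FALSE)
  structure(list(fit = fit, lrt_cultivar = lrt_c, lrt_sowing = lrt_s,
                 emm = emm, reference = reference, contrasts = contrasts),
            class = "cultivar_test")
}

#' @export
print.cultivar_test <- function(x, ...) {
  cat("Cultivar effects on predicted cell yields\n")
  cat(sprintf("  LRT cultivar: chisq = %.2f, df = %d, p = %.4g\n",
              x$lrt_cultivar$statistic, x$lrt_cultivar$df,
              x$lrt_cultivar$p.value))
  cat(sprintf("  LRT sowing date: chisq = %.2f, df = %d, p = %.4g\n",
              x$lrt_sowing$statistic, x$lrt_sowing$df, x$lrt_sowing$p.value))
  cat(sprintf("  reference (lowest marginal mean): %s\n", x$reference))
  cat("  contrasts vs reference (Wald z, uncorrected):\n")
  print(format(x$contrasts, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Trait analysis of predicted cell yields
#'
#' The second statistical-testing analysis: fixed effects are the four
#' plot-level soybean traits (stem, seed and above-ground dry weight,
#' 100-seed weight) and all six pairwise interactions — 11 coefficients
#' with the intercept — over the same nested random structure. Each term
#' is tested by a single-term-deletion likelihood-ratio test under ML.
#'
#' @param data cell observation table with trait columns
#'   \code{stem_dw}, \code{seed_dw}, \code{above_dw}, \code{w100} (rows
#'   with NA traits are dropped).
#' @inheritParams fit_cell_lmm
#' @return A \code{trait_test}: REML fit and the per-term LRT table.
#' @export
trait_analysis <- function(data, response = "yield", include_plot = TRUE) {
  traits <- c("stem_dw", "seed_dw", "above_dw", "w100")
  data <- as.data.frame(data)
  data <- data[stats::complete.cases(data[traits]), , drop = FALSE]
  for (tr in traits) {
    if (stats::var(tapply(data[[tr]], data$plot_id, mean)) < 1e-12) {
      stop("collinearity error: trait '", tr,
           "' is constant across plots", call. = FALSE)
    }
  }
  f <- stats::as.formula(paste("~ (", paste(traits, collapse = " + "), ")^2"))
  terms_all <- attr(stats::terms(f), "term.labels")  # 4 mains + 6 interactions
  fit <- fit_cell_lmm(data, terms_all, "REML", response, include_plot)
  lrt <- lapply(terms_all, function(tm) {
    lrt_fixed_effect(data, terms_all, setdiff(terms_all, tm), response,
                     include_plot)
  })
  lrt_tab <- data.frame(
    term = terms_all,
    statistic = vapply(lrt, `[[`, numeric(1), "statistic"),
    df = vapply(lrt, `[[`, numeric(1), "df"),
    p.value = vapply(lrt, `[[`, numeric(1), "p.value"),
    stringsAsFactors = FALSE)
  lrt_tab$signif <- p_stars(lrt_tab$p.value)
  structure(list(fit = fit, lrt = lrt_tab, terms = terms_all),
            class = "trait_test")
}

#' @export
print.trait_test <- function(x, ...) {
  cat("Soybean trait effects on predicted cell yields\n")
  cat("  fixed coefficients (REML):\n")
  print(round(x$fit$fixed, 4))
  cat("  single-term-deletion LRTs (ML):\n")
  print(format(x$lrt, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Marginal-effect surface of a focal trait across a moderator
#'
#' Predictions from the fixed part of a fitted cell model over the
#' Cartesian grid of focal x moderator values, with every other
#' covariate held at its data mean and random effects at zero. For a
#' model with a focal-by-moderator interaction the focal slope at
#' moderator value m is beta_focal + beta_interaction * m, so the lines
#' fan out; without the interaction they are parallel.
#'
#' @param fit a \code{cell_lmm} whose fixed part contains both terms.
#' @param focal,moderator covariate names.
#' @param focal_values,moderator_values numeric grids; defaults span the
#'   observed range (11 and 5 points). Values outside the observed range
#'   trigger an extrapolation warning.
#' @return data.frame with the grid and \code{predicted}.
#' @export
marginal_effects <- function(fit, focal, moderator,
                             focal_values = NULL, moderator_values = NULL) {
  stopifnot(inherits(fit, "cell_lmm"))
  vars <- all.vars(stats::reformulate(fit$fixed_terms))
  if (!all(c(focal, moderator) %in% vars)) {
    stop("focal and moderator must appear in the fixed part", call. = FALSE)
  }
  dat <- fit$data
  rng_f <- range(dat[[focal]]); rng_m <- range(dat[[moderator]])
  focal_values <- focal_values %||% seq(rng_f[1], rng_f[2], length.out = 11)
  moderator_values <- moderator_values %||%
    seq(rng_m[1], rng_m[2], length.out = 5)
  if (any(focal_values < rng_f[1] - diff(rng_f) | focal_values > rng_f[2] + diff(rng_f)) ||
      any(moderator_values < rng_m[1] - diff(rng_m) |
          moderator_values > rng_m[2] + diff(rng_m))) {
    warning("grid values far outside the data range: extrapolating",
            call. = FALSE)
  }
  grid <- expand.grid(focal = focal_values, moderator = moderator_values)
  newdata <- as.data.frame(lapply(dat[setdiff(vars, c(focal, moderator))],
                                  function(col) {
    if (is.numeric(col)) mean(col) else factor(levels(factor(col))[1],
                                               levels = levels(factor(col)))
  }))
  newdata <- if (ncol(newdata)) newdata[rep(1, nrow(grid)), , drop = FALSE]
             else data.frame(row.names = seq_len(nrow(grid)))
  newdata[[focal]] <- grid$focal
  newdata[[moderator]] <- grid$moderator
  X <- stats::model.matrix(stats::reformulate(fit$fixed_terms), newdata)
  out <- data.frame(grid$focal, grid$moderator,
                    predicted = drop(X %*% fit$fixed))
  names(out)[1:2] <- c(focal, moderator)
  rownames(out) <- NULL
  out
}
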