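#' Fit a Gaussian identity-link model by least squares
#'
#' Ordinary least squares of the response on the given covariate columns
#' (intercept always included), via a QR solve. Log-likelihood uses the
#' full Gaussian form with the ML variance estimate,
#' \code{-(n/2) * (log(2*pi) + log(RSS/n) + 1)}, and the parameter count
#' \code{k} counts the intercept, every slope and the residual variance:
#' \code{k = ncol(design) + 2}. An exact fit (RSS numerically zero) has
#' unbounded likelihood and is flagged \code{degenerate}; such fits
#' cannot be scored by AIC but still rank ahead of all scored fits.
#'
#' @param design data.frame or matrix of covariates (no intercept
#'   column); zero columns give the intercept-only model.
#' @param y numeric response vector.
#' @return A \code{gaussian_fit}: coefficients, rss, tss, n, k, logLik,
#'   aic, r.squared, sigma2 (ML residual variance), degenerate flag,
#'   fitted values and the model spec (covariate names).
#' @examples
#' f <- fit_gaussian_glm(data.frame(x = c(0, 1, 2, 3)), c(1.1, 2.9, 5.2, 6.8))
#' coef(f)
#' @export
fit_gaussian_glm <- function(design, y) {
  X <- as.matrix(as.data.frame(design))
  if (nrow(X) == 0 && length(y)) X <- matrix(numeric(0), length(y), 0)
  n <- length(y)
  if (!is.numeric(y) || any(!is.finite(y))) {
    stop("response must be finite numeric", call. = FALSE)
  }
  if (ncol(X) && any(!is.finite(X))) {
    stop("design must be finite; drop flagged quadrats first", call. = FALSE)
  }
  p <- ncol(X)
  k <- p + 2L
  if (n <= p + 1L) stop("need n > number of coefficients", call. = FALSE)
  Xi <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    stop("singularity error: rank-deficient design (collinear predictors)",
         call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(Xi %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  degenerate <- rss <= max(1e-10 * tss, 1e-12)
  ll <- if (degenerate) Inf else -(n / 2) * (log(2 * pi) + log(rss / n) + 1)
  structure(list(
    spec = colnames(X) %||% character(),
    coefficients = beta, rss = rss, tss = tss, n = n, k = k,
    logLik = ll, aic = if (degenerate) NA_real_ else -2 * ll + 2 * k,
    r.squared = if (tss > 0) 1 - rss / tss else 0,
    sigma2 = rss / n, degenerate = degenerate, fitted.values = fitted,
    residuals = y - fitted), class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> %s\n",
              if (length(x$spec)) paste(x$spec, collapse = " + ")
              else "(intercept only)"))
  print(round(x$coefficients, 6))
  cat(sprintf("  n = %d, k = %d, R^2 = %.4f, %s\n", x$n, x$k, x$r.squared,
              if (x$degenerate) "degenerate (RSS = 0)"
              else sprintf("AIC = %.4f", x$aic)))
  invisible(x)
}

#' @export
coef.gaussian_fit <- function(object, ...) object$coefficients

#' @export
logLik.gaussian_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' AIC of a Gaussian least-squares fit
#'
#' \code{AIC = -2 logLik + 2k} with \code{k} counting intercept, slopes
#' and the residual variance (a 4-predictor model has \code{k = 6}).
#' Degenerate (exact) fits raise an error since their likelihood is
#' unbounded.
#'
#' @param fit a \code{gaussian_fit}.
#' @export
model_aic <- function(fit) {
  stopifnot(inherits(fit, "gaussian_fit"))
  if (fit$degenerate) {
    stop("degenerate fit (RSS = 0): AIC undefined", call. = FALSE)
  }
  fit$aic
}

#' Enumerate all candidate-index subsets
#'
#' All \code{2^m} subsets of the candidate names, including the empty
#' (intercept-only) model, ordered by subset size then by candidate
#' order. Refuses more than \code{max_candidates} candidates unless
#' \code{force = TRUE}, as the search is exhaustive.
#'
#' @param candidates character vector of index names.
#' @param max_candidates combinatorial guard (default 20).
#' @param force set TRUE to override the guard.
#' @return List of character vectors (model specs).
#' @export
enumerate_models <- function(candidates, max_candidates = 20L, force = FALSE) {
  if (!length(candidates) || anyDuplicated(candidates)) {
    stop("'candidates' must be non-empty and unique", call. = FALSE)
  }
  m <- length(candidates)
  if (m > max_candidates && !force) {
    stop(sprintf("%d candidates imply %s models; set force = TRUE to proceed",
                 m, format(2^m, big.mark = ",")), call. = FALSE)
  }
  specs <- list(character())
  for (size in seq_len(m)) {
    cmb <- utils::combn(candidates, size, simplify = FALSE)
    specs <- c(specs, cmb)
  }
  specs
}

#' Akaike differences and weights
#'
#' \code{delta_i = AIC_i - min(AIC)};
#' \code{w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)}. The weights
#' are normalized over the supplied model set, so restricting the set
#' changes absolute weights but never the ratios
#' \code{w_i / w_j = exp(-(delta_i - delta_j) / 2)}.
#'
#' @param aic numeric vector of AIC values.
#' @return list with \code{delta} and \code{weight}.
#' @export
akaike_weights <- function(aic) {
  stopifnot(is.numeric(aic), length(aic) >= 1)
  delta <- aic - min(aic)
  rel <- exp(-delta / 2)
  list(delta = delta, weight = rel / sum(rel))
}

#' Rank fitted models by AIC into a selection table
#'
#' Sorts ascending by AIC with ties broken by smaller parameter count
#' then lexicographic spec, and attaches Akaike differences and weights.
#' Degenerate (exact) fits precede all scored fits; when present they
#' absorb the full weight mass in equal shares and the scored fits get
#' weight 0 and NA differences.
#'
#' @param fits list of \code{gaussian_fit} objects.
#' @return A \code{selection_table} data.frame (rank, spec,
#'   n_predictors, df, r_squared, aic, delta_aic, weight) with the
#'   ordered fits in attribute \code{"fits"}.
#' @export
rank_models <- function(fits) {
  if (!length(fits)) stop("no fits to rank", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "gaussian_fit")))
  spec_str <- vapply(fits, function(f) {
    if (length(f$spec)) paste(f$spec, collapse = "+") else "(intercept)"
  }, character(1))
  aic <- vapply(fits, function(f) f$aic %||% NA_real_, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  degen <- vapply(fits, function(f) f$degenerate, logical(1))
  ord <- order(ifelse(degen, -Inf, aic), k, spec_str)
  fits <- fits[ord]; spec_str <- spec_str[ord]; aic <- aic[ord]
  k <- k[ord]; degen <- degen[ord]
  if (any(degen)) {
    weight <- ifelse(degen, 1 / sum(degen), 0)
    delta <- rep(NA_real_, length(fits))
  } else {
    aw <- akaike_weights(aic)
    delta <- aw$delta; weight <- aw$weight
  }
  tab <- data.frame(
    rank = seq_along(fits), spec = spec_str, n_predictors = k - 2L,
    df = as.integer(k),
    r_squared = vapply(fits, function(f) f$r.squared, numeric(1)),
    aic = aic, delta_aic = delta, weight = weight, degenerate = degen,
    stringsAsFactors = FALSE)
  attr(tab, "fits") <- fits
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' Best model of a selection table
#'
#' The rank-1 fit (lowest AIC; ties already resolved toward fewer
#' parameters).
#'
#' @param table a \code{selection_table}.
#' @return The winning \code{gaussian_fit}.
#' @export
best_model <- function(table) {
  stopifnot(inherits(table, "selection_table"))
  attr(table, "fits")[[1]]
}

#' All-subsets AIC search for the index-to-trait prediction model
#'
#' The model-development stage: every subset of the candidate imagery
#' indices is fitted to the harvested trait by Gaussian identity-link
#' least squares, scored by AIC (full likelihood; the residual variance
#' counts as a parameter), and ranked with Akaike weights. The rank-1
#' model is frozen as the predictive model used for field-wide mapping.
#'
#' Subsets whose design is rank-deficient on the given data (e.g. a
#' constant index) are dropped from the ranking and recorded in
#' \code{dropped_specs}.
#'
#' @param data modeling table, e.g. from \code{\link{join_samples}}:
#'   one row per quadrat with index covariate columns and the response.
#' @param response response column name (default
#'   \code{"ear_dry_weight_g"}).
#' @param candidates candidate column names; default every column
#'   matching the \code{<K>_<date>} layer convention (\code{^[CHN]_}).
#' @param exclude candidate names to drop before the search.
#' @param max_candidates,force combinatorial guard, see
#'   \code{\link{enumerate_models}}.
#' @return A \code{yield_model_selection} object with methods
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{fitted}, \code{residuals} and \code{plot}.
#' @seealso \code{\link{predict_pixels}} to map the best model over an
#'   index stack.
#' @export
select_yield_model <- function(data, response = "ear_dry_weight_g",
                               candidates = NULL, exclude = character(),
                               max_candidates = 20L, force = FALSE) {
  data <- as.data.frame(data)
  if (!response %in% names(data)) {
    stop(sprintf("response column '%s' not found", response), call. = FALSE)
  }
  candidates <- candidates %||% grep("^[CHN]_", names(data), value = TRUE)
  candidates <- setdiff(candidates, exclude)
  if (!length(candidates)) stop("no candidate columns", call. = FALSE)
  keep <- stats::complete.cases(data[c(response, candidates)])
  if (!all(keep)) {
    message(sprintf("dropping %d row(s) with missing response/covariates",
                    sum(!keep)))
    data <- data[keep, , drop = FALSE]
  }
  y <- data[[response]]
  specs <- enumerate_models(candidates, max_candidates, force)
  fits <- vector("list", length(specs))
  dropped <- character()
  for (i in seq_along(specs)) {
    f <- tryCatch(fit_gaussian_glm(data[specs[[i]]], y), error = function(e) e)
    if (inherits(f, "error")) {
      dropped <- c(dropped, if (length(specs[[i]]))
        paste(specs[[i]], collapse = "+") else "(intercept)")
    } else {
      fits[[i]] <- f
    }
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) stop("every candidate model failed to fit", call. = FALSE)
  tab <- rank_models(fits)
  structure(list(table = tab, best = best_model(tab), response = response,
                 candidates = candidates, n = length(y),
                 dropped_specs = dropped, data = data,
                 call = match.call()),
            class = "yield_model_selection")
}

#' @export
print.yield_model_selection <- function(x, n_show = 5, ...) {
  cat(sprintf("All-subsets Gaussian model selection: %s ~ %d candidates (%d models, n = %d)\n",
              x$response, length(x$candidates), nrow(x$table), x$n))
  if (length(x$dropped_specs)) {
    cat(sprintf("  %d rank-deficient subset(s) dropped\n",
                length(x$dropped_specs)))
  }
  cat("Top of the selection table:\n")
  print(format(utils::head(as.data.frame(x$table)[
    c("rank", "spec", "r_squared", "df", "aic", "delta_aic", "weight")],
    n_show), digits = 4), row.names = FALSE)
  cat("\nBest model coefficients:\n")
  print(round(coef(x$best), 4))
  invisible(x)
}

#' @export
summary.yield_model_selection <- function(object, ...) {
  structure(list(table = object$table, best = object$best,
                 response = object$response, n = object$n,
                 dropped = object$dropped_specs),
            class = "summary.yield_model_selection")
}

#' @export
print.summary.yield_model_selection <- function(x, ...) {
  cat(sprintf("Selection over %d models, n = %d, response %s\n",
              nrow(x$table), x$n, x$response))
  print(format(as.data.frame(x$table)[
    c("rank", "spec", "r_squared", "df", "aic", "delta_aic", "weight")],
    digits = 4), row.names = FALSE)
  if (length(x$dropped)) {
    cat("Dropped (rank-deficient):", paste(x$dropped, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
coef.yield_model_selection <- function(object, ...) coef(object$best)

#' @export
fitted.yield_model_selection <- function(object, ...) {
  object$best$fitted.values
}

#' @export
residuals.yield_model_selection <- function(object, ...) {
  object$best$residuals
}

#' Predict from the selected model
#'
#' With a data.frame, returns point predictions (conditional means;
#' residual error is never added). With an \code{index_stack}, maps the
#' model over every pixel via \code{\link{predict_pixels}}.
#'
#' @param object a \code{yield_model_selection}.
#' @param newdata data.frame with the best model's covariate columns, or
#'   an \code{index_stack}; omitted for fitted values.
#' @param ... unused.
#' @export
predict.yield_model_selection <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  if (inherits(newdata, "index_stack")) {
    return(predict_pixels(object$best, newdata))
  }
  b <- coef(object$best)
  spec <- object$best$spec
  miss <- setdiff(spec, names(newdata))
  if (length(miss)) {
    stop("newdata lacks covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- cbind(1, as.matrix(as.data.frame(newdata)[spec]))
  drop(X %*% b)
}

#' @export
plot.yield_model_selection <- function(x, ...) {
  obs <- x$data[[x$response]]
  graphics::plot(fitted(x), obs,
                 xlab = sprintf("predicted %s", x$response),
                 ylab = sprintf("observed %s", x$response),
                 main = sprintf("Best model (R² = %.3f)",
                                x$best$r.squared), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Serialize the best model as a plain-text key-value file
#'
#' @param fit a \code{gaussian_fit} (typically \code{object$best}).
#' @param path file path.
#' @export
write_best_model <- function(fit, path) {
  stopifnot(inherits(fit, "gaussian_fit"))
  b <- fit$coefficients
  writeLines(c(
    sprintf("spec: %s", paste(fit$spec, collapse = ",")),
    sprintf("intercept: %s", fmt_num(unname(b[1]), 15)),
    sprintf("coef.%s: %s", fit$spec, fmt_num(unname(b[-1]), 15)),
    sprintf("sigma2: %s", fmt_num(fit$sigma2, 15)),
    sprintf("n: %d", fit$n),
    sprintf("r_squared: %s", fmt_num(fit$r.squared, 15))
  ), path)
  invisible(path)
}

#' @rdname write_best_model
#' @export
read_best_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  spec <- if (nzchar(vals[["spec"]])) strsplit(vals[["spec"]], ",")[[1]]
          else character()
  beta <- c(`(Intercept)` = as.numeric(vals[["intercept"]]),
            stats::setNames(as.numeric(vals[paste0("coef.", spec)]), spec))
  structure(list(spec = spec, coefficients = beta,
                 sigma2 = as.numeric(vals[["sigma2"]]),
                 n = as.integer(vals[["n"]]),
                 r.squared = as.numeric(vals[["r_squared"]]),
                 k = length(spec) + 2L, degenerate = FALSE),
            class = "gaussian_fit")
}
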