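# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the global random-number stream set from
#' \code{seed}, then restores the caller's stream, so simulation helpers
#' never perturb user code that also draws random numbers.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Derive a reproducible child seed for a named simulation stage
#'
#' Each generation stage draws from its own stream keyed by
#' (root seed, stage label), so adding a stage never perturbs the draws
#' of earlier stages. Arithmetic stays below 2^31 and is exact in doubles.
#'
#' @param root integer root seed.
#' @param stage character label of the stage (e.g. \code{"row_effects"}).
#' @return An integer seed.
#' @keywords internal
child_seed <- function(root, stage) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(stage))
  s <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer(((root %% 100003) * 10007 + (s %% 999983) * 31 + 17) %% 2147483629)
}

# consistent number -> string formatting for plain-text artifacts
fmt_num <- function(x, digits = 10) formatC(x, digits = digits, format = "g")

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  }
  invisible(TRUE)
}
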