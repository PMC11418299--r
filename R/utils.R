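#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' that seeded simulation helpers never perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream unchanged.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Closed-form OLS of y on x: slope, intercept and r2 from centred sums.
# r2 of a zero-variance response is defined as 0 so that flat cycles fail
# the linearity gate instead of producing 0/0.
.ols_line <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to fit a slope", call. = FALSE)
  sxx <- stats::var(x) * (n - 1)
  if (sxx <= 0) stop("singular fit: predictor has zero variance", call. = FALSE)
  sxy <- stats::cov(x, y) * (n - 1)
  syy <- stats::var(y) * (n - 1)
  slope <- sxy / sxx
  r2 <- if (syy <= 0) 0 else (sxy * sxy) / (sxx * syy)
  list(slope = slope, intercept = mean(y) - slope * mean(x), r2 = r2, n = n)
}

.assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                           strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop(sprintf("`%s` = %g is outside its valid range", name, x), call. = FALSE)
  }
  invisible(x)
}
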