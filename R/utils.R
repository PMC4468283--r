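#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generators in the package are pure functions of their spec this way.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

voq_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "voq_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Slope/intercept/mean-squared-residual of y ~ t; degenerate inputs give a
# flat fit (slope 0, mse 0 for < 2 distinct points).
linfit <- function(t, y) {
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  n <- length(y)
  if (n == 0) return(list(slope = NA_real_, mse = NA_real_))
  if (n == 1 || stats::var(t) == 0) return(list(slope = 0, mse = 0))
  tm <- mean(t); ym <- mean(y)
  slope <- sum((t - tm) * (y - ym)) / sum((t - tm)^2)
  resid <- y - (ym + slope * (t - tm))
  list(slope = slope, mse = mean(resid^2))
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# Mean absolute successive difference relative to the mean: the common core
# of jitter, shimmer and CFx.
rel_perturbation <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) voq_stop("voq_undefined", "need at least 2 values")
  mean(abs(diff(x))) / mean(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic number formatting for report files (byte-identical reruns).
fmt_num <- function(x, digits = 12) {
  out <- ifelse(is.na(x), "", sprintf("%.*g", digits, x))
  out
}
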