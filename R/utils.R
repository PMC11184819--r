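#' @importFrom stats coef cor cor.test loess loess.control lm mad median
#'   p.adjust pnorm predict quantile residuals rbinom rlnorm rnbinom rnorm
#'   runif sd var wilcox.test IQR
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive independent child seeds from a single master seed
#'
#' All stochastic stages take explicit integer seeds; a study-level seed is
#' split into per-stage / per-dataset seeds with this helper so that stages
#' stay reproducible and statistically unentangled.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^30]`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  withr::with_seed(as.integer(seed), sample.int(2^30, n))
}

## tricube-weighted local regression wrapper: degree-2 loess with a lm
## fallback for inputs too small or too degenerate for loess to handle.
local_fit_residuals <- function(x, y, span = 0.75, degree = 2) {
  ok <- is.finite(x) & is.finite(y)
  res <- rep(NA_real_, length(x))
  if (sum(ok) < 2) {
    res[ok] <- 0
    return(res)
  }
  if (length(unique(x[ok])) < 4) {
    fit <- lm(y[ok] ~ x[ok])
    res[ok] <- residuals(fit)
    return(res)
  }
  fit <- tryCatch(
    loess(y ~ x, data = data.frame(x = x[ok], y = y[ok]), span = span,
          degree = degree, family = "gaussian",
          control = loess.control(surface = "direct")),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- lm(y[ok] ~ x[ok])
    res[ok] <- residuals(fit)
  } else {
    res[ok] <- residuals(fit)
  }
  res
}

## moment skewness (biased, n denominator) of a numeric vector
moment_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

stop_scperf <- function(...) stop(..., call. = FALSE)

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_scperf(sprintf("'%s' must be a single value in [0, 1]", name))
  invisible(x)
}
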