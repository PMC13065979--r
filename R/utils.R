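#' Clip probabilities away from 0 and 1
#'
#' Slider responses allow exact 0% and 100%, which make log-based quantities
#' (KL divergence, Bayes denominators) infinite or undefined. All internal
#' computations therefore clip to \code{[eps, 1 - eps]} first.
#'
#' @param p numeric vector of probabilities.
#' @param eps clipping bound, default \code{1e-6}.
#' @return `p` with every element forced into `[eps, 1 - eps]`.
#' @export
clip_prob <- function(p, eps = 1e-6) {
  stopifnot(is.numeric(p), eps >= 0, eps < 0.5)
  pmin(pmax(p, eps), 1 - eps)
}

# Truncated-normal draws on [0,1] by inverse-CDF; sd = 0 returns the mean.
# Vectorized over `mean`; consumes exactly length(mean) uniforms so that
# generated tables are byte-identical for a given seed.
rtnorm01 <- function(mean, sd) {
  if (any(sd < 0)) stop("sd must be >= 0")
  u <- stats::runif(length(mean))
  if (all(sd == 0)) return(mean)
  lo <- stats::pnorm((0 - mean) / sd)
  hi <- stats::pnorm((1 - mean) / sd)
  out <- stats::qnorm(lo + u * (hi - lo)) * sd + mean
  out[sd == 0] <- mean[sd == 0]
  pmin(pmax(out, 0), 1)
}

#' Round probabilities to the slider grid
#'
#' @param p numeric vector in `[0,1]`.
#' @param step slider increment; must divide 1 exactly.
#' @return `p` rounded to the nearest multiple of `step`, kept in `[0,1]`.
#' @export
round_grid <- function(p, step = 0.01) {
  stopifnot(step > 0, abs(1 / step - round(1 / step)) < 1e-8)
  pmin(pmax(round(p / step) * step, 0), 1)
}

# Internal: check a value is a single number in [0,1]
assert_prob <- function(p, name = deparse(substitute(p))) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(sprintf("'%s' must be numeric in [0, 1]", name), call. = FALSE)
  invisible(p)
}
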