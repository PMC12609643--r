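#' @keywords internal
"_PACKAGE"

# classed error helpers so callers can distinguish bad configuration from
# bad data
stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("pupilratio_domain_error", "error")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("pupilratio_config_error", "error")))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampler: exact, and consumes exactly one uniform deviate per
#' draw, which keeps the generator's RNG-stream contract simple.
#'
#' @param n number of draws
#' @param mean,sd mean and standard deviation of the parent normal
#' @param lo,hi truncation bounds (finite, `lo < hi`)
#' @return numeric vector of length `n` inside `[lo, hi]`
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  clamp(stats::qnorm(u, mean, sd), lo, hi)
}

# mean of a normal(mean, sd) truncated to [lo, hi]
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# E[clamp(c + eps, lo, hi)] for eps ~ N(0, s); closed form
clamped_noise_mean <- function(centre, s, lo, hi) {
  if (s == 0) return(clamp(centre, lo, hi))
  a <- (lo - centre) / s
  b <- (hi - centre) / s
  centre * (stats::pnorm(b) - stats::pnorm(a)) +
    s * (stats::dnorm(a) - stats::dnorm(b)) +
    lo * stats::pnorm(a) + hi * stats::pnorm(-b)
}

# evaluate f over the truncated-normal density of degeneration and integrate
integrate_over_truncnorm <- function(f, mean, sd, lo, hi) {
  a <- stats::pnorm(lo, mean, sd)
  b <- stats::pnorm(hi, mean, sd)
  z <- b - a
  stats::integrate(function(x) f(x) * stats::dnorm(x, mean, sd) / z,
                   lower = lo, upper = hi, rel.tol = 1e-9)$value
}

# run `expr` with the global RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so generation is a pure function of its arguments
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
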