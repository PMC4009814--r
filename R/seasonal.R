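#' Expected reproductive output as a function of arrival date
#'
#' The reproductive output `R(x) = R0 / (1 + exp((x - r) / sigma_R))` of an
#' individual arriving on day `x` in the best available territory: a
#' decreasing logistic, equal to `R0 / 2` at the food-peak date `r`. Late
#' arrival means breeding after the seasonal food peak and hence lower output;
#' sufficiently late arrival gives reproductive failure.
#'
#' @param x Arrival date(s), days. Vectorised.
#' @param sp A [seasonal_params()] object.
#' @return Expected reproductive output, in `[0, R0]`.
#' @export
#' @examples
#' sp <- seasonal_params(R0 = 1, r = 1, sigma_R = 0.1)
#' reproductive_success(1, sp)  # 0.5
reproductive_success <- function(x, sp) {
  validate_seasonal_params(sp)
  check_scalar_finite(x, "arrival date x")
  sp$R0 / (1 + exp((x - sp$r) / sp$sigma_R))
}

#' Pre-breeding survival as a function of arrival date
#'
#' The probability `S(x) = S0 / (1 + exp(-(x - s) / sigma_S))` of surviving
#' migration and the pre-breeding period given arrival on day `x`: an
#' increasing logistic, equal to `S0 / 2` at the onset of spring `s`. Early
#' migration carries mortality costs (harsh conditions, low resources en
#' route), which relax as spring progresses.
#'
#' @inheritParams reproductive_success
#' @return Survival probability, in `[0, S0]`.
#' @export
#' @examples
#' sp <- seasonal_params(s = -1, sigma_S = 0.4)
#' prebreeding_survival(-1, sp)  # 0.5 when S0 = 1
prebreeding_survival <- function(x, sp) {
  validate_seasonal_params(sp)
  check_scalar_finite(x, "arrival date x")
  sp$S0 / (1 + exp(-(x - sp$s) / sp$sigma_S))
}

#' Uniform arrival-date density
#'
#' Arrival dates in the population are uniformly distributed on the window
#' `[mu - v/2, mu + v/2]` around the mean arrival date `mu`: the density is
#' `1/v` inside the (closed) window and 0 outside.
#'
#' @param x Arrival date(s), days. Vectorised.
#' @param mu Mean arrival date (days).
#' @param v Arrival-window length (days), positive.
#' @return Probability density per day.
#' @export
#' @examples
#' arrival_density(0, mu = 0, v = 0.5)  # 2
arrival_density <- function(x, mu, v) {
  check_scalar_finite(x, "arrival date x")
  check_scalar_finite(mu, "mu")
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
    stop("v must be a single positive number", call. = FALSE)
  }
  ifelse(x >= mu - v / 2 & x <= mu + v / 2, 1 / v, 0)
}

# Numerically stable softplus: log(1 + exp(z)) without overflow for large z.
softplus <- function(z) {
  out <- numeric(length(z))
  pos <- z > 0
  out[pos] <- z[pos] + log1p(exp(-z[pos]))
  out[!pos] <- log1p(exp(z[!pos]))
  out
}

#' Integral of the survival curve over a date interval
#'
#' Computes `integral_a^b S(u) du` in closed form from the logistic
#' antiderivative `S0 * sigma_S * log(1 + exp((u - s)/sigma_S))`. This is the
#' building block for the accumulated density of surviving arrivals within a
#' season.
#'
#' @param a,b Interval endpoints (days), `a <= b`. Vectorised in parallel.
#' @param sp A [seasonal_params()] object.
#' @return The integral, in probability-days (non-negative).
#' @export
#' @examples
#' sp <- seasonal_params()
#' survival_mass(sp$s - 20, sp$s, sp)  # ~ sigma_S * log(2) when S0 = 1
survival_mass <- function(a, b, sp) {
  validate_seasonal_params(sp)
  check_scalar_finite(a, "interval endpoint a")
  check_scalar_finite(b, "interval endpoint b")
  if (any(a > b)) stop("survival_mass requires a <= b", call. = FALSE)
  za <- (a - sp$s) / sp$sigma_S
  zb <- (b - sp$s) / sp$sigma_S
  sp$S0 * sp$sigma_S * (softplus(zb) - softplus(za))
}
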