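#' Seasonal environment parameters
#'
#' Bundles the six constants that define the seasonal environment on the
#' breeding grounds: a decreasing logistic curve for reproductive output and
#' an increasing logistic curve for pre-breeding survival, each with a
#' half-saturation date and a slope parameter.
#'
#' Reproductive output in the best territory is
#' \deqn{R(x) = R_0 / (1 + e^{(x - r)/\sigma_R}),}
#' a decreasing sigmoid of arrival date \eqn{x} with half-saturation at the
#' food-peak date \eqn{r}; pre-breeding survival is
#' \deqn{S(x) = S_0 / (1 + e^{-(x - s)/\sigma_S}),}
#' an increasing sigmoid with half-saturation at the onset of spring \eqn{s}.
#' Dates are in season time units ("days") on an axis conventionally centred
#' near 0, with \eqn{s = -1} and \eqn{r = 1} at the reference baseline.
#'
#' @param r Food-peak date: half-saturation date of the reproduction curve
#'   (days).
#' @param sigma_R Width of the resource distribution (days); small values give
#'   a narrow food peak (steep decline in reproductive output), large values a
#'   broad one. Must be positive.
#' @param R0 Maximal reproductive output (offspring per capita) for an early
#'   arriver in an undepleted territory. Must be positive.
#' @param s Onset-of-spring date: half-saturation date of the pre-breeding
#'   survival curve (days).
#' @param sigma_S Rate parameter of survival improvement (days); small values
#'   mean survival prospects improve quickly around `s`. Must be positive.
#' @param S0 Maximal pre-breeding survival probability, in (0, 1].
#'
#' @details No ordering between `r` and `s` is imposed: they represent
#'   environmental effects on different parts of the life cycle and may be
#'   shifted independently (see [shift_scenario()]).
#'
#' @return An object of class `seasonal_params` (a named list).
#' @seealso [demography_params()], [reproductive_success()],
#'   [prebreeding_survival()]
#' @export
#' @examples
#' sp <- seasonal_params()
#' reproductive_success(1, sp)  # half of R0 at the food peak
seasonal_params <- function(r = 1, sigma_R = 0.1, R0 = 3,
                            s = -1, sigma_S = 0.4, S0 = 1) {
  p <- list(r = r, sigma_R = sigma_R, R0 = R0,
            s = s, sigma_S = sigma_S, S0 = S0)
  validate_seasonal_params(p)
  structure(p, class = "seasonal_params")
}

validate_seasonal_params <- function(p) {
  for (nm in c("r", "sigma_R", "R0", "s", "sigma_S", "S0")) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("seasonal parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (p$sigma_R <= 0) stop("sigma_R must be > 0", call. = FALSE)
  if (p$sigma_S <= 0) stop("sigma_S must be > 0", call. = FALSE)
  if (p$R0 <= 0) stop("R0 must be > 0", call. = FALSE)
  if (p$S0 <= 0 || p$S0 > 1) stop("S0 must be in (0, 1]", call. = FALSE)
  invisible(p)
}

#' Demography and competition parameters
#'
#' Winter survival, the juvenile survival discount, the territory-quality
#' decline rate, and the width of the arrival window.
#'
#' @param s_A Adult winter survival probability, in (0, 1].
#' @param k Juvenile-to-adult winter-survival ratio; juvenile winter survival
#'   is `k * s_A` with `k < 1` (first-year migrants survive winter less well
#'   than adults).
#' @param q_c Territory-quality decline rate per unit of accumulated settled
#'   density; `q_c = 1` sets the (arbitrary) density scale at the reference
#'   baseline. Must be non-negative.
#' @param v Length of the arrival interval (days); arrival dates are uniform
#'   on `[mu - v/2, mu + v/2]` around the population mean arrival date `mu`.
#'
#' @return An object of class `demography_params` (a named list).
#' @seealso [seasonal_params()], [ecological_equilibrium()]
#' @export
#' @examples
#' dp <- demography_params()
#' dp$k * dp$s_A  # juvenile winter survival
demography_params <- function(s_A = 0.5, k = 0.5, q_c = 1, v = 0.5) {
  p <- list(s_A = s_A, k = k, q_c = q_c, v = v)
  validate_demography_params(p)
  structure(p, class = "demography_params")
}

validate_demography_params <- function(p) {
  for (nm in c("s_A", "k", "q_c", "v")) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("demography parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (p$s_A <= 0 || p$s_A > 1) stop("s_A must be in (0, 1]", call. = FALSE)
  if (p$k <= 0 || p$k >= 1) stop("k must be in (0, 1)", call. = FALSE)
  if (p$q_c < 0) stop("q_c must be >= 0", call. = FALSE)
  if (p$v <= 0) stop("v must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.seasonal_params <- function(x, ...) {
  cat("Seasonal environment parameters\n")
  cat(sprintf("  reproduction: R0 = %g, food peak r = %g, width sigma_R = %g\n",
              x$R0, x$r, x$sigma_R))
  cat(sprintf("  survival:     S0 = %g, onset of spring s = %g, rate sigma_S = %g\n",
              x$S0, x$s, x$sigma_S))
  invisible(x)
}

#' @export
print.demography_params <- function(x, ...) {
  cat("Demography parameters\n")
  cat(sprintf("  winter survival s_A = %g (juvenile ratio k = %g)\n", x$s_A, x$k))
  cat(sprintf("  territory decline q_c = %g, arrival window v = %g\n", x$q_c, x$v))
  invisible(x)
}

check_scalar_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(what, " must be finite numeric", call. = FALSE)
  }
  invisible(x)
}
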