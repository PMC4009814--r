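#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ecological-equilibrium result
#'
#' @param x An `arrivaldyn_eq` object from [ecological_equilibrium()].
#' @param ... Unused.
#' @return A one-row tibble with `mu`, `n_star`, `f_star`, `converged`,
#'   `extinct`, `iterations`.
#' @export
tidy.arrivaldyn_eq <- function(x, ...) {
  tibble::tibble(mu = x$mu, n_star = x$n_star, f_star = x$f_star,
                 converged = x$converged, extinct = x$extinct,
                 iterations = x$iterations)
}

#' Tidy an ESS result
#'
#' @param x An `arrivaldyn_ess` object from [ess_solve()].
#' @param ... Unused.
#' @return A one-row tibble with the ESS arrival date, its equilibrium
#'   density and age structure, and the stability diagnostics.
#' @export
tidy.arrivaldyn_ess <- function(x, ...) {
  tibble::tibble(
    mu_star = x$mu_star,
    n_star = if (is.null(x$equilibrium)) NA_real_ else x$equilibrium$n_star,
    f_star = if (is.null(x$equilibrium)) NA_real_ else x$equilibrium$f_star,
    gradient_residual = x$gradient_residual,
    convergence_stable = x$convergence_stable,
    invasion_resistant = x$invasion_resistant,
    status = x$status
  )
}

#' @rdname tidy.arrivaldyn_ess
#' @export
glance.arrivaldyn_ess <- function(x, ...) tidy(x, ...)

#' Tidy a scenario response
#'
#' @param x A `scenario_response` object from [run_scenario()].
#' @param ... Unused.
#' @return A one-row tibble with the shift magnitudes, the baseline ESS and
#'   equilibrium, and the post-shift gradient, density ratio, young ratio and
#'   extinction flag.
#' @export
tidy.scenario_response <- function(x, ...) {
  tibble::tibble(
    delta_s = x$delta_s, delta_r = x$delta_r, mu_star = x$mu_star,
    n1_star = x$n1_star, f1_star = x$f1_star,
    n2_star = x$n2_star, f2_star = x$f2_star,
    gradient_after = x$gradient_after, density_ratio = x$density_ratio,
    young_ratio = x$young_ratio, extinct_after = x$extinct_after
  )
}

#' Plot the seasonal trade-off curves
#'
#' Draws reproductive output and pre-breeding survival against arrival date,
#' the two opposing seasonal pressures whose balance (together with territory
#' competition) determines the ESS arrival date.
#'
#' @param sp A [seasonal_params()] object.
#' @param from,to Date range to draw (days).
#' @param n Number of evaluation points.
#' @return A ggplot object.
#' @export
plot_seasonal <- function(sp, from = sp$s - 2, to = sp$r + 2, n = 400) {
  xs <- seq(from, to, length.out = n)
  df <- tibble::tibble(
    x = rep(xs, 2),
    value = c(reproductive_success(xs, sp), prebreeding_survival(xs, sp)),
    curve = rep(c("reproductive output R(x)", "pre-breeding survival S(x)"),
                each = n)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(sp$s, sp$r), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "arrival date (season units)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Panel plot of a parameter sweep
#'
#' Shows, against the varied parameter, the baseline ESS arrival date,
#' equilibrium density and fraction of young, and the post-shift responses
#' (selection gradient, density ratio, young ratio) for each scenario.
#' Extinct rows are dropped from the response panels, so their lines are
#' discontinued.
#'
#' @param object An `arrivaldyn_sweep` tibble from [sweep_shifts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.arrivaldyn_sweep <- function(object, ...) {
  long <- object |>
    dplyr::filter(!.data$extinct_after | is.na(.data$extinct_after)) |>
    tidyr::pivot_longer(
      cols = c("gradient_after", "density_ratio", "young_ratio"),
      names_to = "response", values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$vary_value, y = .data$value,
                                     colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(x = unique(object$vary_param), y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
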