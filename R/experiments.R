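#' Define a sudden environmental shift
#'
#' A sudden-shift scenario changes the onset of spring `s` and/or the
#' food-peak date `r` by fixed amounts (negative = advance, i.e. earlier in
#' the season), applied instantaneously to a population sitting at its
#' historical ESS. The reference scenarios advance one or both dates by 0.5
#' season units.
#'
#' @param delta_s Shift applied to the onset of spring `s` (days).
#' @param delta_r Shift applied to the food-peak date `r` (days).
#' @return An object of class `shift_scenario`.
#' @seealso [run_scenario()], [reference_scenarios()]
#' @export
shift_scenario <- function(delta_s = 0, delta_r = 0) {
  check_scalar_finite(delta_s, "delta_s")
  check_scalar_finite(delta_r, "delta_r")
  structure(list(delta_s = delta_s, delta_r = delta_r),
            class = "shift_scenario")
}

#' The three reference shift scenarios
#'
#' Advance of the food peak only, of the onset of spring only, and of both
#' jointly, each by 0.5 season units.
#'
#' @return A named list of [shift_scenario()] objects
#'   (`advance_r`, `advance_s`, `advance_both`).
#' @export
reference_scenarios <- function() {
  list(advance_r = shift_scenario(0, -0.5),
       advance_s = shift_scenario(-0.5, 0),
       advance_both = shift_scenario(-0.5, -0.5))
}

apply_shift <- function(sp, scenario) {
  seasonal_params(r = sp$r + scenario$delta_r, sigma_R = sp$sigma_R,
                  R0 = sp$R0, s = sp$s + scenario$delta_s,
                  sigma_S = sp$sigma_S, S0 = sp$S0)
}

#' Demographic and selective response to a sudden environmental shift
#'
#' Runs the full experiment for one scenario: (1) solve the baseline ESS
#' `mu1*` and its equilibrium `(n1*, f1)`; (2) shift `s` and `r`; (3) holding
#' the arrival strategy fixed at `mu1*` (evolution is slow relative to
#' demography), let the population re-equilibrate to `(n2*, f2)`; (4) evaluate
#' the selection gradient at the old ESS under the new environment and new
#' equilibrium density. Reported are the new gradient, the density ratio
#' `n2*/n1*`, the fraction-of-young ratio `f2/f1`, and an extinction flag.
#'
#' @param sp Baseline [seasonal_params()].
#' @param dp [demography_params()].
#' @param scenario A [shift_scenario()].
#' @param ess Optional precomputed baseline `arrivaldyn_ess` (to avoid
#'   re-solving when running several scenarios from one baseline).
#' @return An object of class `scenario_response` with fields
#'   `gradient_after`, `density_ratio`, `young_ratio`, `extinct_after`,
#'   `mu_star`, `n1_star`, `f1_star`, `n2_star`, `f2_star`, `delta_s`,
#'   `delta_r`.
#' @export
#' @examples
#' run_scenario(seasonal_params(), demography_params(), shift_scenario(0, 0))
run_scenario <- function(sp, dp, scenario, ess = NULL) {
  stopifnot(inherits(scenario, "shift_scenario"))
  if (is.null(ess)) ess <- ess_solve(sp, dp)
  if (ess$status != "ok" || ess$equilibrium$extinct) {
    stop("baseline admits no viable ESS (status: ", ess$status, ")",
         call. = FALSE)
  }
  mu1 <- ess$mu_star
  n1 <- ess$equilibrium$n_star
  f1 <- ess$equilibrium$f_star
  sp2 <- apply_shift(sp, scenario)
  eq2 <- ecological_equilibrium(mu1, sp2, dp)
  if (eq2$extinct) {
    out <- list(gradient_after = NA_real_, density_ratio = 0,
                young_ratio = NA_real_, extinct_after = TRUE)
  } else {
    h2 <- selection_gradient(mu1, sp2, dp, n_star = eq2$n_star)
    out <- list(gradient_after = h2, density_ratio = eq2$n_star / n1,
                young_ratio = eq2$f_star / f1, extinct_after = FALSE)
  }
  structure(
    c(out, list(mu_star = mu1, n1_star = n1, f1_star = f1,
                n2_star = eq2$n_star,
                f2_star = if (eq2$extinct) NA_real_ else eq2$f_star,
                delta_s = scenario$delta_s, delta_r = scenario$delta_r)),
    class = "scenario_response"
  )
}

#' @export
print.scenario_response <- function(x, ...) {
  cat(sprintf("Sudden-shift scenario (delta_s = %g, delta_r = %g)\n",
              x$delta_s, x$delta_r))
  cat(sprintf("  baseline ESS mu* = %.6g, n1* = %.6g, f1 = %.6g\n",
              x$mu_star, x$n1_star, x$f1_star))
  if (x$extinct_after) {
    cat("  population extinct after the shift\n")
  } else {
    cat(sprintf("  selection gradient after shift: %.6g\n", x$gradient_after))
    cat(sprintf("  density ratio n2*/n1* = %.6g, young ratio f2/f1 = %.6g\n",
                x$density_ratio, x$young_ratio))
  }
  invisible(x)
}

#' Parameter sweep of baselines and shift responses
#'
#' For each value of one varied parameter (all others at their baseline), the
#' sweep solves the baseline ESS, its equilibrium density and fraction of
#' young, and then runs every requested shift scenario from that baseline.
#' This reproduces the panel structure of the model's characterisation: how
#' the evolutionary-ecological equilibrium and its climate-shift responses
#' depend on the onset of spring, winter survival, productivity, resource-peak
#' width and survival-improvement rate.
#'
#' @param sp Baseline [seasonal_params()].
#' @param dp Baseline [demography_params()].
#' @param vary Name of the parameter to vary: one of `"s"`, `"s_A"`, `"R0"`,
#'   `"sigma_R"`, `"sigma_S"`.
#' @param grid Numeric vector of values for the varied parameter.
#' @param scenarios List of [shift_scenario()] objects; defaults to
#'   [reference_scenarios()].
#' @return A tibble in long format with one row per (grid value, scenario):
#'   columns `vary_param`, `vary_value`, `mu_star`, `n_star`, `f_star`,
#'   `scenario`, `delta_s`, `delta_r`, `gradient_after`, `density_ratio`,
#'   `young_ratio`, `extinct_after`, `status`. Grid values with no viable
#'   baseline ESS are flagged in `status` and carry `NA` responses; rows where
#'   the shifted population goes extinct have `extinct_after = TRUE`.
#' @export
#' @examples
#' \donttest{
#' sweep_shifts(seasonal_params(), demography_params(),
#'              vary = "s_A", grid = c(0.4, 0.5, 0.6))
#' }
sweep_shifts <- function(sp, dp, vary = c("s", "s_A", "R0", "sigma_R", "sigma_S"),
                         grid, scenarios = reference_scenarios()) {
  vary <- match.arg(vary)
  check_scalar_finite(grid, "grid")
  if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  }
  rows <- purrr::map(grid, function(val) {
    sp_i <- sp
    dp_i <- dp
    if (vary %in% c("s", "R0", "sigma_R", "sigma_S")) {
      sp_i[[vary]] <- val
      sp_i <- do.call(seasonal_params, unclass(sp_i))
    } else {
      dp_i[[vary]] <- val
      dp_i <- do.call(demography_params, unclass(dp_i))
    }
    ess <- ess_solve(sp_i, dp_i)
    if (ess$status != "ok" || ess$equilibrium$extinct) {
      return(tibble::tibble(
        vary_param = vary, vary_value = val, mu_star = NA_real_,
        n_star = NA_real_, f_star = NA_real_,
        scenario = names(scenarios),
        delta_s = purrr::map_dbl(scenarios, "delta_s"),
        delta_r = purrr::map_dbl(scenarios, "delta_r"),
        gradient_after = NA_real_, density_ratio = NA_real_,
        young_ratio = NA_real_, extinct_after = NA,
        status = if (ess$status == "ok") "nonviable" else ess$status
      ))
    }
    purrr::imap(scenarios, function(sc, nm) {
      resp <- run_scenario(sp_i, dp_i, sc, ess = ess)
      tibble::tibble(
        vary_param = vary, vary_value = val, mu_star = ess$mu_star,
        n_star = ess$equilibrium$n_star, f_star = ess$equilibrium$f_star,
        scenario = nm, delta_s = sc$delta_s, delta_r = sc$delta_r,
        gradient_after = resp$gradient_after,
        density_ratio = resp$density_ratio,
        young_ratio = resp$young_ratio,
        extinct_after = resp$extinct_after,
        status = if (resp$extinct_after) "extinct" else "ok"
      )
    }) |> purrr::list_rbind()
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("arrivaldyn_sweep", class(out))
  out
}
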