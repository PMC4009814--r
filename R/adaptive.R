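#' Invasion fitness of a variant arrival strategy
#'
#' The annual per-capita growth factor `W(mu', mu)` of a rare variant with
#' mean arrival date `mu'` invading a resident population with mean arrival
#' date `mu` at its ecological equilibrium density `n*`:
#' \deqn{W = \frac{1}{v} \int_{\mu'-v/2}^{\mu'+v/2}
#'   S(x)\,[s_A + k\,s_A\,R(x)\,\hat{Q}(x)]\,dx,}
#' where `Q-hat` is the territory quality generated by the resident cohort at
#' `n*`, held at its boundary value outside the resident arrival window. The
#' variant is rare, so it exerts no density feedback of its own. `W = 1` is
#' neutral; the resident strategy itself satisfies `W(mu, mu) = 1` at its own
#' equilibrium.
#'
#' @param mu_variant Variant mean arrival date (days).
#' @param mu_resident Resident mean arrival date (days).
#' @param sp A [seasonal_params()] object.
#' @param dp A [demography_params()] object.
#' @param n_star Resident equilibrium density. If `NULL`, it is computed by
#'   [ecological_equilibrium()]; an extinct resident is an error since fitness
#'   against an empty environment is a different quantity (see
#'   `empty_environment_growth()`).
#' @return The growth factor `W >= 0`.
#' @seealso [selection_gradient()], [ess_solve()]
#' @export
invasion_fitness <- function(mu_variant, mu_resident, sp, dp, n_star = NULL) {
  validate_seasonal_params(sp)
  validate_demography_params(dp)
  check_scalar_finite(mu_variant, "mu_variant")
  check_scalar_finite(mu_resident, "mu_resident")
  if (is.null(n_star)) {
    eq <- ecological_equilibrium(mu_resident, sp, dp)
    if (eq$extinct) {
      stop("resident population is extinct; invasion fitness is undefined ",
           "(use empty_environment_growth() for growth into an empty habitat)",
           call. = FALSE)
    }
    n_star <- eq$n_star
  }
  lo <- mu_variant - dp$v / 2
  hi <- mu_variant + dp$v / 2
  integrand <- function(x) {
    Q <- territory_quality(x, n_star, mu_resident, sp, dp)
    prebreeding_survival(x, sp) * (dp$s_A + dp$k * dp$s_A *
                                     reproductive_success(x, sp) * Q)
  }
  # split at resident-window edges and at the quality kink, where Q-hat
  # changes analytic form
  cuts <- c(mu_resident - dp$v / 2, mu_resident + dp$v / 2)
  x0 <- quality_root(n_star, mu_resident, sp, dp)
  if (!is.null(x0)) cuts <- c(cuts, x0)
  pts <- sort(unique(c(lo, hi, cuts[cuts > lo & cuts < hi])))
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    total <- total + stats::integrate(integrand, pts[i], pts[i + 1L],
                                      rel.tol = 1e-12, abs.tol = 1e-14)$value
  }
  total / dp$v
}

#' Per-capita growth factor into an empty environment
#'
#' The annual growth factor of a strategy at vanishing density (all territory
#' qualities equal to 1). Values below 1 mean the strategy cannot sustain a
#' population at all.
#'
#' @inheritParams ecological_equilibrium
#' @return Growth factor at zero density.
#' @export
empty_environment_growth <- function(mu, sp, dp) {
  a <- mu - dp$v / 2
  b <- mu + dp$v / 2
  integrand <- function(x) {
    prebreeding_survival(x, sp) *
      (dp$s_A + dp$k * dp$s_A * reproductive_success(x, sp))
  }
  stats::integrate(integrand, a, b, rel.tol = 1e-12,
                   abs.tol = 1e-14)$value / dp$v
}

#' Selection gradient on mean arrival date
#'
#' The derivative of invasion fitness with respect to the variant trait,
#' evaluated at the resident strategy with the resident at its ecological
#' equilibrium. Because the fitness integral runs over the variant's arrival
#' window, the derivative takes the endpoint (Leibniz) form
#' \deqn{h(\mu) = \frac{1}{v}\left[F(\mu + v/2) - F(\mu - v/2)\right],
#'   \quad F(x) = S(x)\,[s_A + k\,s_A\,R(x)\,Q(x)],}
#' with `Q` the resident-generated territory quality. The left- and
#' right-hand derivatives of `W` coincide at `mu' = mu`, so `h` is
#' well-defined; the test suite verifies agreement with one-sided finite
#' differences from both sides.
#'
#' Sign convention: `h > 0` means selection favours *later* arrival (larger
#' `mu`); `h < 0` favours earlier arrival.
#'
#' @inheritParams ecological_equilibrium
#' @param n_star Resident equilibrium density; computed if `NULL`. `NA` is
#'   returned (with a warning) when the resident is extinct.
#' @return The selection gradient (per day), or `NA_real_` for an extinct
#'   resident.
#' @export
selection_gradient <- function(mu, sp, dp, n_star = NULL) {
  if (is.null(n_star)) {
    eq <- ecological_equilibrium(mu, sp, dp)
    if (eq$extinct) {
      warning("resident population is extinct; selection gradient undefined")
      return(NA_real_)
    }
    n_star <- eq$n_star
  }
  Fend <- function(x) {
    Q <- territory_quality(x, n_star, mu, sp, dp)
    prebreeding_survival(x, sp) * (dp$s_A + dp$k * dp$s_A *
                                     reproductive_success(x, sp) * Q)
  }
  (Fend(mu + dp$v / 2) - Fend(mu - dp$v / 2)) / dp$v
}

#' Solve for the evolutionarily stable mean arrival date
#'
#' Finds the root of the selection gradient `h(mu) = 0` over a bracket, with
#' every gradient evaluation recomputing the resident's ecological equilibrium
#' (the eco-evolutionary feedback: strategy determines density, density
#' determines competition, competition shapes selection). The bracket is first
#' scanned on a coarse grid to locate a sign change among viable (non-extinct)
#' strategies, then refined by bracketed root finding. The root is reported as
#' an ESS only together with its stability diagnostics from
#' [check_stability()].
#'
#' @param sp A [seasonal_params()] object.
#' @param dp A [demography_params()] object.
#' @param bracket Length-2 interval searched for the gradient root; defaults
#'   to `[s - 2, r + 2]`.
#' @param scan_points Number of coarse-scan points across the bracket.
#' @param tol Root tolerance on `mu`.
#' @return An object of class `arrivaldyn_ess` with fields `mu_star`,
#'   `equilibrium` (an `arrivaldyn_eq`), `convergence_stable`,
#'   `invasion_resistant`, `gradient_residual`, `status` (`"ok"`,
#'   `"no_sign_change"`, or `"nonviable"`).
#' @export
#' @examples
#' ess <- ess_solve(seasonal_params(), demography_params())
#' ess$mu_star
ess_solve <- function(sp, dp, bracket = c(sp$s - 2, sp$r + 2),
                      scan_points = 17, tol = 1e-8) {
  validate_seasonal_params(sp)
  validate_demography_params(dp)
  if (length(bracket) != 2L || bracket[1] >= bracket[2]) {
    stop("bracket must be an increasing length-2 interval", call. = FALSE)
  }
  grid <- seq(bracket[1], bracket[2], length.out = scan_points)
  h_at <- function(mu) {
    eq <- ecological_equilibrium(mu, sp, dp)
    if (eq$extinct) return(NA_real_)
    selection_gradient(mu, sp, dp, n_star = eq$n_star)
  }
  hv <- vapply(grid, h_at, numeric(1))
  if (all(is.na(hv))) {
    return(ess_result(NA_real_, NULL, NA, NA, NA_real_, "nonviable"))
  }
  # the gradient root can hide between the viability boundary (where the
  # resident goes extinct) and the first viable scan point, so augment the
  # scan with points just inside each boundary, located by bisection
  viable_at <- function(mu) !ecological_equilibrium(mu, sp, dp)$extinct
  aug_mu <- grid
  aug_h <- hv
  for (i in seq_len(length(grid) - 1L)) {
    if (is.na(hv[i]) == is.na(hv[i + 1L])) next
    lo_b <- grid[i]
    hi_b <- grid[i + 1L]
    lo_viable <- !is.na(hv[i])
    for (it in 1:40) {
      mid <- (lo_b + hi_b) / 2
      if (viable_at(mid) == lo_viable) lo_b <- mid else hi_b <- mid
    }
    inside <- if (lo_viable) lo_b else hi_b
    aug_mu <- c(aug_mu, inside)
    aug_h <- c(aug_h, h_at(inside))
  }
  ord <- order(aug_mu)
  aug_mu <- aug_mu[ord]
  aug_h <- aug_h[ord]
  # find adjacent viable points with a sign change
  lo <- hi <- NA_real_
  for (i in seq_len(length(aug_mu) - 1L)) {
    if (is.na(aug_h[i]) || is.na(aug_h[i + 1L])) next
    if (aug_h[i] == 0) { lo <- hi <- aug_mu[i]; break }
    if (sign(aug_h[i]) != sign(aug_h[i + 1L])) {
      lo <- aug_mu[i]; hi <- aug_mu[i + 1L]; break
    }
  }
  if (is.na(lo)) {
    return(ess_result(NA_real_, NULL, NA, NA, NA_real_, "no_sign_change"))
  }
  mu_star <- if (lo == hi) lo else {
    stats::uniroot(h_at, c(lo, hi), tol = tol)$root
  }
  eq <- ecological_equilibrium(mu_star, sp, dp)
  resid <- abs(selection_gradient(mu_star, sp, dp, n_star = eq$n_star))
  stab <- check_stability(mu_star, sp, dp)
  ess_result(mu_star, eq, stab$convergence_stable, stab$invasion_resistant,
             resid, "ok")
}

ess_result <- function(mu_star, equilibrium, cs, ir, resid, status) {
  structure(
    list(mu_star = mu_star, equilibrium = equilibrium,
         convergence_stable = cs, invasion_resistant = ir,
         gradient_residual = resid, status = status),
    class = "arrivaldyn_ess"
  )
}

#' Stability diagnostics for a singular arrival strategy
#'
#' Checks the two conditions that make a gradient root an ESS: convergence
#' stability (the gradient decreases through zero, `dh/dmu < 0`, evaluated by
#' a central finite difference with the ecological feedback recomputed at each
#' point) and resistance to invasion (`W(mu', mu_star) <= 1 + tol` for all
#' variants on a grid spanning `mu_star` plus or minus the arrival-window
#' length `v`).
#'
#' @param mu_star Candidate strategy (a root of the selection gradient; a
#'   warning is issued if the gradient there is visibly non-zero).
#' @inheritParams ess_solve
#' @param step Finite-difference step for `dh/dmu` (days).
#' @param grid_points Number of variant strategies scanned for invasion
#'   resistance.
#' @param tol Neutrality tolerance on `W <= 1 + tol`.
#' @return A list with logical fields `convergence_stable` and
#'   `invasion_resistant`.
#' @export
check_stability <- function(mu_star, sp, dp, step = 1e-4, grid_points = 201,
                            tol = 1e-6) {
  eq <- ecological_equilibrium(mu_star, sp, dp)
  if (eq$extinct) {
    stop("resident is extinct at mu_star; stability is undefined", call. = FALSE)
  }
  h0 <- selection_gradient(mu_star, sp, dp, n_star = eq$n_star)
  if (abs(h0) > 1e-4) {
    warning("mu_star does not look like a gradient root (|h| = ",
            format(abs(h0)), ")")
  }
  h_at <- function(mu) {
    e <- ecological_equilibrium(mu, sp, dp)
    if (e$extinct) return(NA_real_)
    selection_gradient(mu, sp, dp, n_star = e$n_star)
  }
  dh <- (h_at(mu_star + step) - h_at(mu_star - step)) / (2 * step)
  mu_grid <- seq(mu_star - dp$v, mu_star + dp$v, length.out = grid_points)
  W <- vapply(mu_grid, invasion_fitness, numeric(1),
              mu_resident = mu_star, sp = sp, dp = dp, n_star = eq$n_star)
  list(convergence_stable = isTRUE(dh < 0),
       invasion_resistant = all(W <= 1 + tol))
}

#' @export
print.arrivaldyn_ess <- function(x, ...) {
  cat("ESS arrival strategy\n")
  if (x$status != "ok") {
    cat("  status:", x$status, "\n")
    return(invisible(x))
  }
  cat(sprintf("  mu* = %.8g  (|h(mu*)| = %.3g)\n", x$mu_star, x$gradient_residual))
  cat(sprintf("  convergence stable: %s, invasion resistant: %s\n",
              x$convergence_stable, x$invasion_resistant))
  if (!is.null(x$equilibrium)) {
    cat(sprintf("  equilibrium density n* = %.6g, fraction young f* = %.6g\n",
                x$equilibrium$n_star, x$equilibrium$f_star))
  }
  invisible(x)
}
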