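---
title: "An eco-evolutionary model of arrival timing in migratory birds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An eco-evolutionary model of arrival timing in migratory birds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrivaldyn)
```

## The model

`arrivaldyn` models a population of long-distance migratory birds competing
for breeding territories. The evolving trait is the population mean arrival
date $\mu$ at the breeding grounds; individual arrival dates $x$ are spread
uniformly over a window $[\mu - v/2,\, \mu + v/2]$ of fixed length $v$,
representing environmental variability the birds do not control.

Arrival date trades off two seasonal pressures, each a logistic function of
$x$:

* **Reproduction.** Output in the best territory is
  $R(x) = R_0 / (1 + e^{(x - r)/\sigma_R})$: early arrivers exploit a
  temporally restricted food resource (e.g. an insect-larvae peak) for
  longer, so output declines with arrival date, passing $R_0/2$ at the
  food-peak date $r$. The width $\sigma_R$ is read as the breadth of the
  resource distribution.
* **Pre-breeding survival.** $S(x) = S_0 / (1 + e^{-(x - s)/\sigma_S})$:
  early migration is risky (harsh en-route and settlement conditions), and
  survival improves fastest around the onset of spring $s$, at rate set by
  $\sigma_S$.

Time is measured in dimensionless season units ("days") with the reference
baseline at $s = -1$, $r = 1$; the two dates act on different life-history
stages and are deliberately independent parameters.

Density dependence acts through territory competition under prior
residency. The accumulated density of settled survivors by day $x$ is
$n_S(x) = (n/v)\int_{\mu-v/2}^{x} S(u)\,du$, and the territory quality
available to an arriver on day $x$ declines linearly with it,
$Q(x) = \max(0,\, 1 - q_c\, n_S(x))$, a discount factor on reproduction.
Outside the resident arrival window $Q$ is frozen at its boundary value:
before the window no territory is taken, after it none is released.

A season maps this year's returning migrants $n_t$ to next year's:
$$n_{t+1} = s_A N_S + k\, s_A B, \qquad
  N_S = \tfrac{n_t}{v}\!\int S\,dx, \quad
  B = \tfrac{n_t}{v}\!\int S(x) R(x) Q(x)\,dx,$$
with adult winter survival $s_A$ and juvenile winter survival $s_J = k s_A$,
$k < 1$. The age-structure summary is the fraction of young among returning
migrants, $f = k B / (N_S + k B)$.

Evolution is analysed by adaptive dynamics. A rare variant with mean arrival
$\mu'$ invading a resident $\mu$ at its ecological equilibrium $n^*$ has
annual growth factor
$$W(\mu', \mu) = \frac{1}{v} \int_{\mu'-v/2}^{\mu'+v/2}
  S(x)\,\bigl[s_A + k\, s_A R(x) \hat{Q}(x)\bigr] dx,$$
where $\hat Q$ is the resident-generated quality. The selection gradient is
the derivative at $\mu' = \mu$, which by the Leibniz rule is the endpoint
form $h(\mu) = [F(\mu + v/2) - F(\mu - v/2)]/v$ with
$F(x) = S(x)[s_A + k s_A R(x) Q(x)]$. The package's sign convention —
stated here because the quantity is reported throughout — is that $h > 0$
selects for **later** arrival. An ESS candidate is a root of $h$ obtained
with full eco-evolutionary feedback: every gradient evaluation recomputes
the resident equilibrium, so strategy shapes density, density shapes
competition, and competition shapes selection.

## Parameters and defaults

All defaults reproduce the reference baseline: $s = -1$, $s_A = 0.5$,
$R_0 = 3$, $\sigma_R = 0.1$, $r = 1$, $S_0 = 1$, $q_c = 1$, $v = 0.5$,
$\sigma_S = 0.4$, $k = 0.5$. Density units are arbitrary; $q_c = 1$ fixes
the scale. At these values:

```{r baseline}
ess <- ess_solve(seasonal_params(), demography_params())
tidy(ess)
```

The ESS mean arrival date is about $-0.23$ — between the onset of spring
and the season origin, well before the food peak — with a positive
equilibrium density and roughly 57% first-year birds among returning
migrants.

## Numerical choices

* **Integrals.** The survival integral has a closed form via the logistic
  antiderivative (`survival_mass()`, a numerically stable softplus); all
  other within-season integrals use adaptive quadrature at relative
  tolerance `1e-12`. Where $Q$ reaches 0 inside the window the integrand has
  a kink; the kink location is found by bracketed root finding and the
  integral is split there, because adaptive rules lose accuracy silently
  across kinks.
* **Equilibria.** The between-year map is iterated (cap 1000 iterations)
  from initial density 1 until $|\Delta n| < 10^{-10}$. While $Q > 0$ across
  the window the map is exactly linear-quadratic in $n$ with coefficients
  from three precomputed integrals, so iterations cost arithmetic only; the
  general quadrature path takes over when the kink activates, and the two
  are cross-checked in the test suite. Independence from the starting
  density is a tested property, not an assumption.
* **Extinction.** Near the viability boundary the map decays geometrically
  and no finite threshold is crossed quickly, so extinction is decided by
  the low-density growth factor $A = s_A (\int S + k \int S R)/v$: the
  empty state is the only attractor when $A \le 1$. A density below
  $10^{-12}$ during iteration is also treated as extinct.
* **ESS search.** The gradient root is bracketed on a coarse scan of
  $[s - 2,\, r + 2]$ and refined by Brent's method to $10^{-8}$. Because the
  gradient can be positive only on a thin sliver between the viability
  boundary and the first viable scan point, the solver also bisects each
  extinct/viable boundary and scans just inside it.
* **Stability.** Convergence stability is a central finite difference of
  $h$ (step $10^{-4}$) with the feedback recomputed at each point; invasion
  resistance scans 201 variants across $\mu^* \pm v$ against
  $W \le 1 + 10^{-6}$.

## Design decisions worth knowing

* **Growth factor, not log fitness.** $W$ is the annual per-capita growth
  factor with neutral value 1, so the resident's fixed-point identity
  $W(\mu, \mu) = 1$ is directly testable; the ESS condition is invariant to
  taking logarithms.
* **Season bounds.** The arrival density vanishes outside the window, so all
  integrals run over the window itself; explicit season start and end dates
  would be redundant parameters.
* **Local versus global invasion resistance.** At the baseline the singular
  strategy is convergence stable and a strict local fitness maximum, but the
  full $\pm v$ scan reports non-resistance: variants arriving well after the
  resident window keep the frozen boundary quality $Q(\mu + v/2) \approx
  0.74$ while gaining survival and losing almost no reproduction (the food
  peak is still far ahead), giving $W \approx 1.02$. This is a structural
  consequence of quality clamping at the window edge, not a numerical
  artifact; `check_stability()` reports it honestly, and the diagnostic
  distinguishes the local result from the global scan. Gradual evolution
  with small mutational steps still converges to and rests at this point.
* **Age structure is survival-side only.** At any positive equilibrium,
  $f^* = 1 - s_A \int S \, dx / v$: the reproduction side ($r$, $\sigma_R$,
  $R_0$, $q_c$) affects the equilibrium fraction of young only through the
  ESS arrival date. A food-peak shift with arrival held fixed therefore
  leaves $f^*$ exactly unchanged — the corresponding response ratio is
  identically 1 — while shifts to the survival season change it with real
  margin.

## Climate-shift experiments

A sudden-shift scenario advances $s$ and/or $r$ (reference magnitude 0.5
units) for a population at its historical ESS. Evolution is assumed slow
relative to demography: the arrival strategy stays at the old ESS, the
population re-equilibrates, and the package records the new selection
gradient at the old ESS, the density ratio $n_2^*/n_1^*$, the
fraction-of-young ratio $f_2/f_1$, and an extinction flag.

```{r scenarios}
sp <- seasonal_params()
dp <- demography_params()
base <- ess_solve(sp, dp)
tidy(run_scenario(sp, dp, shift_scenario(-0.5, 0), ess = base))
tidy(run_scenario(sp, dp, shift_scenario(0, -0.5), ess = base))
```

An earlier spring raises survival at every arrival date, so density grows
(ratio about 1.9) and the proportion of adults rises (young ratio about
0.92), with strong selection for earlier arrival. An earlier food peak
alone shrinks the population slightly at the baseline; at low winter
survival or productivity the same shift collapses the population entirely,
and with a broad resource peak it can even select for *later* arrival: the
shift depresses density, competition relaxes, and the survival advantage of
late arrival wins — selection running counter to the direction of the
environmental change, a signature of the closed feedback loop.

`sweep_shifts()` tabulates baselines and all three reference scenarios along
a grid of one parameter (tidy long format; `autoplot()` draws the panels).
Default sweep ranges span the baseline: $s \in [-3, 1]$,
$s_A \in [0.2, 0.9]$, $R_0 \in [1, 6]$, $\sigma_R \in [0.05, 0.8]$,
$\sigma_S \in [0.1, 1.2]$. Grid points whose baseline cannot sustain a
population are flagged `nonviable`; post-shift collapses are flagged
`extinct`, and plotted lines are discontinued there.

## What the tests do and do not show

The test suite verifies structural identities (resident neutrality
$W(\mu,\mu)=1$, the endpoint gradient against finite differences of $W$,
equilibrium fixed points, quadrature against brute-force Riemann sums),
the documented direction of every comparative static along the default
sweep ranges, and the scenario responses above. All of this concerns the
deterministic model at its reference conditions: it shows internal
correctness and the claimed qualitative behaviour, not that real
populations follow uniform arrival windows, logistic seasonal curves, or
linear territory depletion. Stochastic environments, age-structured detail
beyond the young fraction, non-uniform arrival distributions and gradual
(rather than sudden) environmental change are outside the model's scope.

## Known limitations

* Monomorphic, asexual inheritance of the mean arrival date; no genetic
  variance dynamics.
* The uniform arrival window makes the fitness landscape piecewise-smooth
  at window-alignment points; derivative coincidence at those points is
  verified numerically rather than assumed.
* Comparative statics near viability boundaries involve equilibrium
  densities at the edge of the extinction threshold; signs there are
  resolved by the low-density growth criterion, and sweep rows are flagged
  rather than silently dropped.
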