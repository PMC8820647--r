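---
title: "Modelling CAR T-cell therapy under dexamethasone: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CAR T-cell therapy under dexamethasone: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrtdex)
library(dplyr)
```

## The model

`carrtdex` models an *in vitro* cell-killing assay in which glioblastoma
tumor cells (prey) interact with chimeric antigen receptor (CAR) T-cells
(predator) in the presence of the glucocorticoid dexamethasone (Dex).
Populations are measured in cell index (CI), the impedance readout of the
assay platform (1 CI is roughly 10,000 adherent cells); Dex concentration
is in µg/ml; all rates are per day.

The three-species autonomous formulation is a mass-action system

$$
\begin{aligned}
\dot x &= \rho x - \tfrac{\rho}{K}x^2 - \kappa_1 x y - c_0' D x,\\
\dot y &= \kappa_2 x y - \theta y - c_3' D y,\\
\dot D &= -\sigma D,
\end{aligned}
$$

with tumor net growth rate $\rho$, carrying capacity $K$, killing rate
$\kappa_1$, net CAR T-cell proliferation/exhaustion rate $\kappa_2$, CAR
T-cell death rate $\theta$, and Dex clearance rate $\sigma$. Because
$D(t) = D_0 e^{-\sigma t}$ in closed form, the system reduces to a
two-species *nonautonomous* model with effective rates

$$
\rho(t) = \rho - c_0 e^{-\sigma t},\qquad
K(t) = \frac{\rho(t)}{\rho}K,\qquad
\theta(t) = \theta + c_3 e^{-\sigma t},
$$

so that

$$
\dot x = \rho(t)\,x\Big(1-\frac{x}{K(t)}\Big) - \kappa_1 x y,\qquad
\dot y = \kappa_2 x y - \theta(t)\,y.
$$

This nonautonomous form is the package's canonical formulation: all
stability analysis and fitting are expressed in it. Two conventions are
worth stating explicitly.

**Rescaling of the Dex constants.** The interaction constants of the two
formulations differ by a factor of the initial dose. The package stores the
*rescaled* constants $c_0$, $c_3$ (units day$^{-1}$, $D_0$ absorbed), and
`unscaled_dex_constants()` provides $c' = c/D_0$ for the three-species
form. A consequence is that $c_0$ and $c_3$ are intrinsically
per-condition quantities: the same biological effect produces different
rescaled constants at different doses. This absorption convention is an
explicit design choice of the package, flagged here because the mapping
between formulations admits alternatives; every internal consumer of
$c_0$, $c_3$ uses the rescaled form consistently, and the two formulations
are cross-checked against each other in the test suite.

**Units.** All internal computation is in days (rates are day$^{-1}$);
data-facing interfaces (assay tables, trajectory and bifurcation exports)
use hours, converted only at the boundary. Mixing the two is the classic
silent bug in eigenvalue formulas, hence the hard split.

Signs of $c_0$ and $c_3$ are deliberately unconstrained: Dex can be anti-
or pro-proliferative to either population, and which regime holds is an
empirical question answered by fitting.

The clearance rate default is $\sigma = 5$/day, the value implied by a
plasma half-life of about 200 minutes
(`dex_clearance_rate(200)` $\approx 4.99$); $\sigma$ is never fitted.

## Simulation

`carrgo_simulate()` integrates either formulation with `deSolve::lsoda`
(adaptive, stiffness-switching) using compiled right-hand sides; a plain-R
engine exists for cross-checks. Defaults are `rtol = 1e-8`,
`atol = 1e-10` — tight enough that spiral structure near the coexistence
equilibrium is solver-noise-free. The logistic term is evaluated as
$\rho(t)x - (\rho/K)x^2$ using the exact identity
$\rho(t)/K(t) = \rho/K$, which keeps the vector field finite even at
instants where $K(t)$ crosses zero under strong Dex effects.

The vector field preserves the non-negative orthant from non-negative
starts, so the integrator is never clipped; outputs are floored at zero
only when reported, absorbing harmless sub-tolerance negative excursions.

`detect_outcome()` labels a trajectory *tumor death* when the tumor index
falls below an extinction threshold and stays below it to the end of the
record, else *tumor progression*. The default threshold is 0.01 CI
(about 100 cells): trajectories that spiral through a zero tumor
population terminate the dynamics in practice, but a strict numerical zero
is unreachable, so a small positive cut stands in for it. A transient dip
below the cut that recovers is not death.

Time zero is treatment time (CAR T-cells and Dex added together, 24 h
after tumor plating); pre-treatment growth exists only inside the
synthetic generator.

## Time-resolved stability

Because the Dex forcing $e^{-\sigma t}$ is bounded and continuously
differentiable and decays to zero, stable solutions of the nonautonomous
system converge to those of the limiting autonomous system, and the
frozen-time equilibria and Jacobian eigenvalues govern the transient: time
itself acts as the bifurcation parameter. The three instantaneous
equilibria are death $(0,0)$, tumor proliferation $(K(t), 0)$, and
coexistence

$$
P_3(t) = \left(\frac{\theta(t)}{\kappa_2},\;
\frac{\rho(t)\,(K(t)\kappa_2 - \theta(t))}{K(t)\kappa_1\kappa_2}\right),
$$

whose eigenvalue pair has the closed form

$$
\lambda_\pm(t) = \frac{\rho(t)\theta(t)}{2\kappa_2 K(t)}
\left\{-1 \pm \left[1 + \frac{4\kappa_2 K(t)}{\rho(t)}
\Big(1 - \frac{\kappa_2 K(t)}{\theta(t)}\Big)\right]^{1/2}\right\}.
$$

Notable structure, all enforced by property tests against a numeric
Jacobian oracle: $\kappa_1$ cancels (the killing rate moves the
equilibrium, not its spectrum); the bracketed discriminant is negative
exactly when the state oscillates; and for $\theta(t) > 0$ every
oscillatory state is damped, so once Dex has cleared any spiral is stable.
If Dex is strongly pro-proliferative to CAR T-cells, $c_3 < -\theta$,
then $\theta(t) < 0$ early on, at least one eigenvalue is positive, and
the equilibrium is unstable until the drug clears — the mechanism behind
dose-dependent destabilisation. The restabilisation is a Hopf bifurcation
in time, and for this mechanism its instant is analytic:
$\theta(t^*) = 0$ at $t^* = \log(-c_3/\theta)/\sigma$, which the
bracketing + bisection root-finder in `hopf_times()` reproduces to
$10^{-6}$ day.

Numerical choices: the discriminant formula divides by $\theta(t)$, so at
the singular point $\theta(t) = 0$ the implementation falls back to an
eigen-decomposition of the analytic $2\times 2$ Jacobian. Stability labels
(`stable_spiral`, `unstable_spiral`, `stable_node`, `unstable`) use a
$10^{-10}$/day tolerance around zero real part; a grid point within the
tolerance is labelled `limit_cycle_crossing`. Hopf localisation brackets
sign changes of $\max\mathrm{Re}\,\lambda_\pm$ on a 1000-interval grid and
refines by bisection — the real part is piecewise smooth over a clearance
transient, so a uniform grid at this resolution cannot straddle two
crossings.

`autonomous_coexistence_eigenvalues()` evaluates the $3\times3$ Jacobian
of the autonomous form at the frozen-$D$ coexistence point. Its spectrum
is exactly the two-species pair plus $-\sigma$ (the Dex row couples only
to itself), which the tests verify both at $D = 0$ and along
$D = D_0e^{-\sigma t}$.

## Parameter estimation

The objective for one condition is the weighted sum of squares over the
dense tumor series plus the two CAR T-cell endpoint measurements (the
T-cells are non-adherent, so the assay sees them only at the initial and
final times; intermediate CAR T-cell values are model inferences, reported
as predictions and never treated as data). With roughly 600 tumor points
against 2 endpoints, unweighted least squares would let the tumor series
drown out the endpoints entirely, so the default endpoint weight is
$w_y = w_x\,n_{\text{tumor}}/n_{\text{cart}}$, making the two species
contribute comparably; both weights are configurable. Initial conditions
are fixed to the measured values rather than estimated as nuisance
parameters — with duplicate-averaged data at 15-minute resolution the
first sample pins them far more tightly than the fit would. Duplicates are
averaged before fitting; the replicate spread is kept for display only.

Optimization is global-then-local: particle swarm (gbest topology,
inertia 0.729, accelerations 1.49, the conventional constriction values;
50 particles × 200 iterations by default, all configurable) inside the
parameter box, then bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on
the residual vector. Two robustness measures matter in practice: LM is
restarted from the several best distinct swarm positions, not only the
global best (`lm_starts`, default 5), and the parameter values handed into
the fit — in the staged protocol, the previous stage's estimates — are
included as a warm start. Integration failures inside the objective return
a large finite penalty ($10^{10}$) so the swarm can route around
pathological parameter combinations. Every stochastic operation takes an
explicit seed and records it.

The parameter box defaults to the observed ranges of this assay system
($\rho \in [0.5, 12]$, $K \in [1, 20]$, $\kappa_1 \in [0.8, 90]$,
$\kappa_2 \in [0.1, 2]$, $\theta \in [10^{-12}, 3]$, $c_0 \in [-10, 4]$,
$c_3 \in [-11, 11]$). The $\theta$ lower bound is kept at $10^{-12}$
rather than zero so the eigenvalue formula stays regular throughout the
search.

**Staging.** The experimental design makes the eight-parameter model
practically identifiable by decomposing it:

1. tumor-only, no Dex → $\rho, K$ (pure logistic);
2. tumor-only, with Dex → rescaled $c_0$ per Dex level, $\rho, K$ fixed;
3. tumor + CAR T-cells, no Dex → $\kappa_1, \kappa_2, \theta$ per E:T
   ratio;
4. tumor + CAR T-cells, with Dex → $\kappa_1, \kappa_2, \theta, c_3$ per
   condition, with $\rho, K, c_0$ fixed from stages 1–2.

Stage 4 refits the interaction rates per condition rather than holding
them at stage-3 values because the killing, proliferation/exhaustion and
death rates demonstrably shift between Dex and Dex-free conditions — that
shift *is* the exhaustion signal of interest. Missing condition types
cause dependent stages to be skipped and flagged rather than to error.
Identifiability is verified operationally: on noise-free synthetic data
the staged protocol returns the generating parameters (to well under 1%),
and perturbing any single free parameter away from the truth strictly
increases the objective.

## The synthetic assay generator

`generate_assay()` emulates the experimental layout so that every pipeline
stage is testable without external data: the full design grid (tumor-only
wells at each Dex level plus E:T ∈ {1:4, 1:8, 1:20} × Dex ∈ {0, 10⁻⁴,
10⁻³, 10⁻², 10⁻¹, 1} µg/ml), duplicates, seeding at 1–2 CI drawn
uniformly per cell line (the seeding density within the 10K–20K range is
otherwise unspecified, so one draw per line under the seed), 24 h
drug-free lead growth, treatment at $t = 0$, 15-minute tumor sampling over
144 h, and CAR T-cell measurements at the two endpoint times only.

The default generating truth encodes one success and one failure regime,
chosen once to mirror the observed dose response and not revisited:

* shared tumor biology: $\rho = 1$/day, $K = 5$ CI, $\kappa_1 = 2$
  /day/CI, and a mild pro-tumor Dex effect $c_0 = -0.5$/day;
* success (Dex $< 0.1$ µg/ml): $\kappa_2 = 1$, $\theta = 0.25$
  ($\theta/\kappa_2 = 0.25$ CI, below threshold), $c_3 = 0.3$ — Dex
  raises CAR T-cell turnover but the drug clears before the therapy
  fails;
* failure (Dex $\ge 0.1$ µg/ml): exhaustion — $\kappa_2$ drops to 0.8,
  $\theta$ rises to 0.6 ($\theta/\kappa_2 = 0.75$ CI), and $c_3 = -2.4$,
  i.e. $c_3 < -\theta$, so the coexistence equilibrium is destabilised
  until $\log(-c_3/\theta)/\sigma$ — exactly two Dex half-lives
  (≈ 6.7 h), matching the observed duration of the destabilised window
  in the high-dose regime. The sign flip of $c_3$ between success and
  failure matches the fitted pattern reported for all three assayed cell
  lines.

Measurement noise defaults to multiplicative lognormal with CV 0.05,
floored at zero: cell index is a positive, signal-proportional impedance
measure, so proportional noise is the natural first model, and a 5%
CV visually matches the small duplicate ranges of the real assay. The
lognormal's `sdlog` is set so the CV is exact, and the mean is
bias-corrected. An additive Gaussian alternative and a zero-noise setting
exist for tests.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real data: the loss of the cell-index/cell-number
correlation at high Dex doses without CAR T-cells (the real analysis
excludes those wells; the generator simply produces faithful tumor-only
curves), plate-position and edge effects, cell-line heterogeneity beyond
the two planted regimes, and any temporal structure in CAR T-cell
measurement error (only two endpoints exist). Recovery results on
synthetic data certify the estimation machinery, not the biology.

## Outcome classification

After clearance the effective rates revert to $\theta$ and $\kappa_2$, so
the predicted final tumor burden is the post-clearance ratio
$\theta/\kappa_2$ — time-dependent $\theta(t)$ plays no role in the
classifier, only in the transient. `classify_outcome()` predicts death
below the threshold, progression above it, and flags an exact tie as
indeterminate rather than forcing a side. The reference threshold is
0.4 CI.

`estimate_threshold()` recovers a threshold from a set of fitted
conditions with observed outcomes. The empirical threshold is only ever
observed as a gap between clusters, with no canonical estimator, so the
package adopts the simplest rule consistent with a separable scatter: the
midpoint of the separating gap. For non-separable inputs it falls back to
the cut minimising misclassifications (ties resolved toward the lower
threshold), verified in tests against an exhaustive scan. Whether
particular condition groups enter the ensemble is the caller's choice:
`outcome_records()` builds records from whatever fit it is given.

## Problem sizes used in the shipped tests and acceptance script

The test-suite and acceptance-script experiments are sized for a single
CPU: staged-fit recovery runs on a design-grid subset (one E:T ratio, one
or two Dex levels, 144 h at 15-minute sampling — the full four condition
types of the staged protocol, with all seven free parameters exercised),
with an economical swarm (20 particles × 30 iterations) whose output the
multi-start LM polishes to the same optimum as the full-size default; the
Monte-Carlo noise study uses 20 seeds; eigenvalue-structure properties use
10⁴ random parameter draws. These sizes are the package's own test-design
choices; the user-facing defaults remain as documented above.

## Known limitations

* The model is a well-mixed, two-population caricature: no spatial
  structure, no additional immune compartments, no Holling-type
  saturation of the killing interaction, no delay terms.
* $\sigma$ is treated as known and fixed; patient-level variation in Dex
  clearance is out of scope.
* The rescaled $c_0$, $c_3$ are per-dose quantities; comparing them
  across doses requires converting through $c/D_0$.
* CAR T-cell dynamics are constrained by two data points per condition;
  between the endpoints the CAR T-cell curve is model inference.
* The threshold estimator is a separating rule, not a probabilistic
  classifier; it reports separability honestly but makes no uncertainty
  statement.
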