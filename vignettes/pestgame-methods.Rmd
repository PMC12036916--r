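---
title: "Methods: the three-mode pest-management differential game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the three-mode pest-management differential game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestgame)
```

## The model

Two players — a government and an enterprise — choose effort levels
$F_1(t), F_2(t) \ge 0$ against forest pests and diseases, in one of three
cooperation modes: individual action (A), scarce-resource sharing (S) or
information sharing (I). Each player's reputation $x_i(t)$ is a
Nerlove–Arrow goodwill stock,
$$\dot x_i = a_i F_i - \delta x_i,$$
and each player maximises a discounted infinite-horizon payoff whose
integrand is linear in its own effort's gain, quadratic in its cost,
and linear in its reputation:
$$J_i = \int_0^\infty e^{-\rho t}\Big[(w\, b_i + u_0) F_i
  - \tfrac{c_{\mathrm{eff}}}{2} F_i^2 + k + l\, x_i\Big]\,dt .$$

The modes only re-weight this canonical form (`reduce_mode()`):

* **A**: $w = 1$, $u_0 = 0$, own cost $c_i$, own reputation gain $a_i$;
  the carbon offset is a pure transfer flow, $k = -C_O$ for the
  government and $+C_O$ for the enterprise.
* **S**: the government carries the sharing cost in its effort cost,
  $c_{\mathrm{eff}} = c_1 + c_S$, and earns extra reputation,
  $a_{\mathrm{eff}} = a_1 + a_S$; the enterprise's marginal gain is
  scaled by $\ln(e + \beta_S) > 1$ ($e$ is Euler's number, so the factor
  degrades to 1 as $\beta_S \to 0$). The scaling multiplies the *gain
  parameter*, not the effort inside the logarithm — this is the reading
  consistent with the linear-in-effort first-order condition and the
  closed-form effort it produces.
* **I**: both players' gains shift additively, $u_0 = b_I$, and both pay
  the information-sharing *flow* $-C_I$. Both $C_O$ and $C_I$ are
  modelled as flows per unit time (not lump sums): they sit inside the
  discounted integral and consequently contribute $k/\rho$ to the values.

Two structural facts do all the work. First, the two players are
*decoupled within a mode*: neither's state or control enters the other's
payoff, so each (mode, player) pair is an independent optimal-control
problem and the feedback equilibrium of the game is just the pair of
individually optimal policies. Second, payoff and dynamics are *linear in
the state*, so the stationary HJB equation
$$\rho V(x) = \max_F\Big[(w b + u_0)F - \tfrac{c_{\mathrm{eff}}}{2}F^2
  + k + l x + V'(x)\,(a_{\mathrm{eff}} F - \delta x)\Big]$$
is solved exactly by a value function **linear** in $x$,
$V = m x + n$. No quadratic-in-$x$ term is carried: matching the $x$
coefficients gives $\rho m = l - m\delta$, i.e.
$m = l/(\rho + \delta)$ for every mode and player, and the maximand is
strictly concave in $F$ (coefficient $-c_{\mathrm{eff}}/2 < 0$), so the
optimal effort
$$F^* = \frac{w b + u_0}{c_{\mathrm{eff}}}
  + \frac{a_{\mathrm{eff}}\, l}{c_{\mathrm{eff}}(\rho + \delta)}$$
is the unique maximiser and is state-independent (a constant policy).
Where the information-mode government value is sometimes written with an
unreduced value-gradient factor, the package always evaluates that
gradient with the ansatz, $\partial V/\partial x = l/(\rho+\delta)$ —
the same substitution the other modes use; the reproduced baseline
constant ($-13.444$) confirms the reading.

`solve_value()` additionally reports the value as a quadratic in the
player's own gain parameter,
$$V = K + Q\,(w b + u)^2,\qquad K = m x + k/\rho,\quad
  Q = \frac{1}{2\rho c_{\mathrm{eff}}},\quad
  u = u_0 + \frac{a_{\mathrm{eff}} l}{\rho + \delta},$$
which is the display form of the model's numerical analysis and the
natural object for mode comparison: the difference of two mode values is
a quadratic in $b$, so crossovers come from the quadratic formula.

## Parameters

| parameter | meaning | baseline | units |
|---|---|---|---|
| `rho` | discount rate | 0.9 | 1/time |
| `delta` | reputation decay | 0.1 | 1/time |
| `l` | marginal benefit of reputation | 1 | utility/(reputation·time) |
| `b1`, `b2` | per-unit-effort gains | swept | utility/(effort·time) |
| `c1`, `c2` | quadratic cost coefficients | 2 or 4 | utility/(effort²·time) |
| `CO` | carbon-offset flow (gov → ent) | 10 | utility/time |
| `a1`, `a2` | reputation gains per unit effort | 2 | reputation/(effort·time) |
| `cS` | extra sharing cost (gov, mode S) | 3 | utility/(effort²·time) |
| `betaS` | resource helpfulness (ent, mode S) | 1.5 | dimensionless |
| `aS` | extra reputation gain (gov, mode S) | 1.2 | reputation/(effort·time) |
| `bI` | information gain increment (mode I) | 2.5 | utility/(effort·time) |
| `CI` | information-sharing cost flow | 3 | utility/time |
| `x0_gov`, `x0_ent` | initial reputations | 1 | reputation |

All are positive by assumption; `validate_parameters()` enforces the sign
constraints and reports *every* violation at once. The discount rate is
nominally bounded by 1; since every value contains $1/\rho$ factors,
$\rho > 0$ is a hard constraint while $\rho > 1$ only warns (discounted
integrals still converge, the model is merely stated on $(0,1]$). The
baseline motivates $b_I < C_I$ (shared information under-delivers
relative to its cost) but never imposes it, so the scenario generator
annotates violations (`bI_exceeds_CI`) instead of rejecting them.

## The numerical oracle

Every closed form is checked against arithmetic that does not know the
closed forms. Under constant effort the state ODE has the explicit
solution $x(t) = a_{\mathrm{eff}}F/\delta + (x_0 -
a_{\mathrm{eff}}F/\delta)e^{-\delta t}$ (`reputation_trajectory()`,
itself tested against a fixed-step RK4 integrator written in the test
helpers). `discounted_payoff()` then integrates
$e^{-\rho t}\,[\text{payoff}]$ by composite trapezoid on a uniform grid.
Because the trapezoid rule is linear and the integrand is affine in the
two basis functions $e^{-\rho t}$ and $e^{-(\rho+\delta)t}$, the rule is
applied to those bases once and recombined — bitwise-equivalent to the
pointwise rule (a test asserts agreement with a pointwise implementation
to 1e−10 relative) and cheap enough to sweep hundreds of candidate
efforts. Defaults: horizon $T = 50/\rho$ (tail factor
$e^{-\rho T} \approx 2\times 10^{-22}$), step $dt = 10^{-3}$, both
configurable; the discarded tail is bounded by
$(|gF| + |k| + l x_{\max})\,e^{-\rho T}/\rho$ and reported as an
attribute. `best_constant_effort_grid()` searches constant policies on
$[0, 2F^*]$ (201 points by default). Only constant policies are
searched — a deliberate restriction, justified because the HJB solution
itself is state-independent; the oracle therefore confirms optimality
within that class, and the HJB residuals (`hjb_residual()`) carry the
optimality argument for arbitrary feedback policies.

## What the scenario generator emulates

`generate_scenarios()` draws each parameter uniformly and independently
from half to double its baseline value (the discount rate capped at 1),
under a fixed recorded seed. This emulates the *stated world* of the
model's numerical analysis — parameter uncertainty around a single
published calibration — and nothing more: real pest outbreaks have
shocks to reputation and effectiveness, correlated parameters (costlier
regions also gain more reputation), time-varying carbon prices and more
than two actors, none of which the generator produces. A green
property-test therefore establishes that the *algebra* (closed forms,
monotonicity signs, crossover roots) is correct across the positive
orthant around the baseline, not that the model describes any actual
forest or carbon market.

## Numerical choices

* Printed-coefficient comparison rounds half away from zero to 3
  decimals (2 for the enterprise resource-sharing multiplier 1.44),
  matching the display precision of the reference table; internal
  computation is full precision.
* Crossovers are solved analytically from the quadratic difference of
  decompositions; each simple root is confirmed by bisection
  (`uniroot`, tolerance 1e−13) inside a bracket kept away from
  neighbouring roots. Negative-gain roots are discarded; tangencies
  (double roots) are reported with multiplicity 2 and skipped by the
  sign-change check. If two value functions coincide identically the
  result carries an `identical` attribute instead of fake roots.
* Exact ties in mode rankings (relative tolerance 1e−12) are reported as
  ties, never broken: at a tie the choice of mode is policy, not
  mathematics. The enterprise at $b_2 = 0$ is the canonical case — modes
  A and S coincide exactly there because $\ln(e+\beta_S)$ multiplies a
  zero gain.
* Comparative statics return closed-form derivatives cross-checked by
  central finite differences (relative step 1e−6); parameters absent
  from $F^*$ (the transfers, initial reputations, the rival's
  parameters) return 0 with an explicit `depends = FALSE` flag rather
  than a silent zero.
* The default gain grid for comparison tables is $b \in [0, 10]$ with
  101 points; the baseline crossovers (0.065 and 1.717 for the
  government's A-vs-S boundary at costs 2 and 4) fall well inside it.
* Cost sweeps follow the published convention of moving $c_1 = c_2$
  jointly (`--c`, `baseline_scenario(c_unit=)`); only the player's own
  cost enters its value, and `dominance_region()` applies the swept cost
  to the player's own parameter.

## Design choices where the design was open

* **JSON, not YAML, configuration.** The schema is strict (unknown keys
  rejected at both the scenario and parameter level); YAML support was
  dropped because a YAML parser is not part of the package's guaranteed
  dependency set and JSON loses nothing here.
* **Payoffs are per-player, not aggregated.** The objects are named
  player payoffs/values throughout; no welfare aggregation across
  players is computed, since the two payoffs are never summed in the
  model and the transfers would cancel misleadingly.
* **No symbolic-algebra route.** The closed forms are simple enough that
  a computer-algebra derivation would duplicate, not check, the algebra;
  independence is instead provided by the quadrature/grid oracle and by
  asserting the two distinct algebraic routes to the value intercept
  ($n$ from the HJB constant part and $n = c_{\mathrm{eff}}F^{*2}/(2\rho)
  + k/\rho$) against each other.
* **Reports are pure functions of (scenario, seed, version).** No
  timestamps enter report content; a report embedding a failed internal
  check (HJB residual or oracle mismatch) is marked `passed = FALSE` and
  the batch CLI exits nonzero.

## Known limitations

Deterministic dynamics only (no stochastic reputation shocks); two
players; time-invariant parameters; no Stackelberg or sequenced-move
variants; no empirical calibration — the baseline is a stylised
published scenario, and dominance conclusions are statements about that
region of parameter space, not about measured forests or carbon-market
prices. Effort is unbounded above; with all-positive parameters $F^*$ is
automatically positive, but nothing caps it at a feasible scale.
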