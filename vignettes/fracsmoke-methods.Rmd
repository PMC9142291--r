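---
title: "Methods: fractional-order dynamics of giving up smoking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractional-order dynamics of giving up smoking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracsmoke)
```

## The model

The population is split into five fractions: potential smokers $P$,
occasional (light) smokers $L$, heavy smokers $S$, temporary quitters
$Q$ and permanent quitters $R$. With death/renewal rate $a$, contact
rates $b$ (potential to occasional) and $c$ (occasional to heavy),
quitting rate $d$, permanent-quitting fraction $e$ and relapse rate
$f$, the classical system is

$$
\begin{aligned}
\dot P &= a(1-P) - bPS,\\
\dot L &= -aL + bPS - cLS,\\
\dot S &= -(a+d)S + cLS + fQ,\\
\dot Q &= -(a+f)Q + d(1-e)S,\\
\dot R &= -aR + edS.
\end{aligned}
$$

All six rates carry the reciprocal of whatever time unit the user's
rates imply; no unit is hard-coded. The baseline scenario shipped with
the package (`baseline_scenario()`, scenario name `"paper"`) uses $a=0.04$, $b=0.23$, $c=0.3$,
$d=0.2$, $e=0.4$, $f=0.25$ with initial fractions $(0.60301, 0.24,
0.10628, 0.0326, 0.01811)$, which sum to exactly one.

### The incidence variant

Some presentations of this model write the inflow into the
occasional-smoker class as $bPL$ rather than $bPS$. The two readings
are not interchangeable: only $bPS$ makes the componentwise sum of the
vector field equal $a(1-T)$ with $T = P+L+S+Q+R$, so that a population
starting on the unit simplex stays there, and only $bPS$ is consistent
with the Jacobian used in the stability analysis. `fracsmoke`
therefore uses the `PS` incidence everywhere by default and retains
`PL` as an explicit `variant` flag; the test suite demonstrates the
conservation failure under `PL` (the total drifts by order one over the
baseline horizon) as the documented reason for the default.

## Equilibria, threshold and stability

The smoking-free equilibrium is the parameter-free point
$E_0 = (1,0,0,0,0)$. The associated threshold quantity is

$$R_0 = \frac{d\,f\,(1-e)}{(a+d)(a+f)},$$

which evaluates to $0.431034$ at the baseline rates. Two structural
facts about this formula are worth recording, because they shape what
the package can honestly compute:

* it contains neither contact rate $b$ nor $c$; and
* it is strictly below one for every positive parameter set, since
  $d f (1-e) < (a+d)(a+f)$ holds termwise.

A property test asserts the second point over a thousand random
parameter draws. Because the formula can never exceed one, threshold
arguments alone cannot assert an endemic state; the package instead
exposes a *numeric* existence check. Writing the steady state in terms
of the heavy-smoker level $S^*$,

$$P^* = \frac{a}{a+bS^*},\qquad
L^* = \frac{abS^*}{(a+bS^*)(a+cS^*)},\qquad
Q^* = \frac{d(1-e)S^*}{a+f},\qquad
R^* = \frac{edS^*}{a},$$

the five equations reduce to one scalar residual in $S^*$,

$$g(S^*) = -(a+d) + cL^*(S^*) + \frac{fd(1-e)}{a+f},$$

which `endemic_equilibrium()` scans on a uniform grid of $10^4$
intervals over $(0, s_{\max}]$ ($s_{\max} = 1$ by default, the
population scale) and refines each sign change by bisection to machine
tolerance. Every root is composed back into a full state and kept only
if the maximum absolute component of the vector field there is below
$10^{-10}$; all roots found are returned, none privileged. A note on
the algebra: the form of $L^*$ above is the only one consistent with
$L^* = bP^*S^*/(a+cS^*)$ — a version without the leading $S^*$
circulates, but it is dimensionally inconsistent and does not
annihilate the vector field.

At the baseline rates the residual is negative over the whole scan
range (no endemic state), consistent with $R_0 < 1$. At artificially
high contact rates (for instance $b = c = 5$) the scan finds two
crossings, each verified to the $10^{-10}$ residual.

Local stability at $E_0$ is decided twice and cross-checked: three
closed-form eigenvalues
$$\lambda_1 = -a,\qquad
\lambda_{2,3} = \tfrac12\left(-2a-d-f \mp
\sqrt{d^2+2df-4def+f^2}\right)$$
(at the baseline the discriminant is $0.1225$, a perfect square, giving
$-0.04$, $-0.44$, $-0.09$), and the full numeric spectrum of the
$5\times5$ Jacobian at $E_0$, which adds $-a$ twice. Matching
tolerance is $10^{-8}$ — comfortable for a well-conditioned
$5\times5$ problem at unit scale. The verdict is `locally_stable` iff
every numeric eigenvalue has negative real part; a negative
discriminant would simply produce a complex pair, not an error.

### Lyapunov diagnostics

The Volterra-type function
$M = \sum_x \left(x - x^* - x^*\log(x/x^*)\right)$ is nonnegative and
vanishes only at the reference equilibrium; its derivative along the
flow is evaluated by the chain rule,
$\dot M = \sum_x \frac{x-x^*}{x}\,\dot x$, with $\dot x$ from the `PS`
vector field. We deliberately do not expand $\dot M$ into a
positive/negative split of algebraic terms: the chain-rule form is
exact, cheap, and testable against a finite difference of $M$ along a
short, accurately integrated flow segment (the suite checks agreement
to $10^{-6}$ at a half-step of $10^{-3}$).

One behavioural subtlety: a uniform positive perturbation of $E_0$
*raises* $M$ transiently, because the $bPS$ term moves mass from $P$
into $L$ faster than the smoking compartments drain. This is not a
contradiction of local stability — $M$ referenced at $E_0$ is not a
certified Lyapunov function for this equilibrium — so the package's
diagnostic value lies along trajectories: on the baseline flow, $M$
and $\dot M < 0$ are monotone over $t \in [0, 40]$, which is what the
suite asserts.

## The fractional formulation and its solver

The fractional variant replaces $d/dt$ with a derivative of order
$\sigma \in (0,1]$ whose kernel is a two-parameter Mittag-Leffler
function — nonsingular at the origin — normalised by
$AB(\sigma) = 1 - \sigma + \sigma/\Gamma(\sigma)$ (equal to one at
$\sigma = 1$, where the classical system is recovered).

### Mittag-Leffler evaluation

$E_{\sigma,\sigma_1}(z) = \sum_{k\ge0} z^k/\Gamma(\sigma k + \sigma_1)$
is evaluated by its power series with terms accumulated through
`lgamma` to avoid overflow. Stopping rule: the current term must fall
below $10^{-14}$ of the running sum on two consecutive terms (the
arguments arising here are negative, so the series alternates and one
small term is not proof of convergence); hard cap $10^4$ terms, and
reaching the cap is an error rather than a silent partial sum. The
evaluator is validated for $|z| \le 50$ — all solver oracles feed it
modest negative arguments — and refuses anything larger instead of
switching to an unvalidated algorithm.

### The two-step product-integration scheme

On the uniform grid $t_n = nh$ the update is

$$y_{n+1} = y_0 + \frac{1-\sigma}{AB(\sigma)} f(t_n, y_n)
+ \frac{\sigma}{AB(\sigma)}\sum_{j=0}^{n}
\frac{h^\sigma}{\Gamma(\sigma+2)}
\left[ f(t_j, y_j)\, w^{\mathrm{cur}}_{n-j}
     - f(t_{j-1}, y_{j-1})\, w^{\mathrm{lag}}_{n-j} \right],$$

with, for $k = n - j$,

$$w^{\mathrm{cur}}_k = (k+1)^\sigma (k+2+\sigma) - k^\sigma (k+2+2\sigma),
\qquad
w^{\mathrm{lag}}_k = (k+1)^{\sigma+1} - k^\sigma (k+1+\sigma).$$

Numerical choices, each of which the suite pins down:

* **Pre-history.** The $j=0$ summand references $y_{-1}$; we set
  $f_{-1} := f_0$, the standard bootstrap for two-step schemes. It
  affects only the first-step contribution.
* **Classical limit.** At $\sigma = 1$ both weights are constant
  ($w^{\mathrm{cur}} = 3$, $w^{\mathrm{lag}} = 1$ for every $k$), and
  after the $h/\Gamma(3) = h/2$ factor the update telescopes into the
  classical two-step Adams–Bashforth recursion. The suite verifies
  iterate-level agreement with an independently coded AB2 recursion to
  $10^{-10}$ over 1000 steps, and agreement with a classical RK4
  reference to below $10^{-3}$ at $h = 0.01$, improving under step
  halving.
* **Full memory.** No short-memory truncation: the history sum runs
  over all previous steps, every right-hand side is evaluated once and
  cached, and cost is quadratic in the step count. The baseline run
  ($h = 0.01$, horizon 30, i.e. 3000 steps) takes well under a second.
* **Uniform grids only,** starting at $t_0 = 0$: the weight algebra
  assumes equal spacing.
* **Initial jump.** The closed-form solution of the linear scalar
  equation $D^\sigma y = \lambda y$,
  $$y(t) = \frac{AB(\sigma)\,y_0}{AB(\sigma)-\lambda(1-\sigma)}
  \, E_{\sigma,1}\!\left(\frac{\sigma\lambda t^\sigma}
  {AB(\sigma)-\lambda(1-\sigma)}\right),$$
  does not equal $y_0$ at $t = 0$ for $\sigma < 1$ — an inherent
  feature of this formulation's integral form — while the stepping
  scheme enforces $y(0) = y_0$. Oracle comparisons are therefore made
  away from the origin (the suite compares at $t = 1$).
* **No clamping.** States are validated at entry points but never
  clamped mid-integration; a non-finite iterate aborts with its step
  index. Masking solver error would corrupt the convergence tests.

### Fractional-order sweeps

`run_sweep()` integrates one trajectory per order (default orders
$\{1.0, 0.95, 0.90, 0.85, 0.80\}$, default $h = 0.01$ and horizon 30 —
all configurable and recorded in the manifest), writes each as a CSV at
full double precision and a JSON manifest whose final-time compartment
values round-trip the CSV tail rows bit-exactly. Runs are
deterministic: repeated invocations are byte-identical.

Across orders the qualitative pattern is that lowering $\sigma$ slows
the approach to the smoking-free state: at a fixed evaluation time $P$
and $R$ sit lower, and $L$, $S$, $Q$ higher, the smaller $\sigma$ is.
The package fixes **$t = 10$** (mid-horizon) as the documented
reference time for this comparison. The choice matters: the ordering
in $R$ is not global in time, because $R$ eventually decays toward
zero and the faster classical dynamics crosses the slower fractional
curves late in the run (by $t = 30$ the $R$ ordering has already
broken). Mid-horizon, all five compartments order cleanly for
$\sigma \in \{1.0, 0.95, 0.85\}$, which is what the suite asserts.

## Scenarios, reproducibility and the random generator

Scenarios come either from the built-in name `"paper"` or from a flat
`key = value` text file (keys `a b c d e f P0 L0 S0 Q0 R0 sigma h
t_end variant orders`). Missing keys fall back to the baseline values
and every fallback is logged; unknown keys, non-numeric values and
invariant violations fail with single-line diagnostics naming the
offender. `run_sweep()` logs the order list, step and horizon at a
single message level — no silent defaults.

`random_fixture(seed)` generates property-test scenarios: rates drawn
log-uniformly in $[10^{-3}, 1]$ (a realistic span for per-unit-time
epidemiological rates at this scale), $e$ uniform in $[0,1]$, and a
strictly positive initial state rescaled to sum exactly to one. It
emulates the *structure* of plausible inputs — positive rates, simplex
initial data — not any observed smoking-prevalence series; passing
property tests therefore certify algebraic and numerical behaviour,
not fit to real data.

## Problem sizes used by the test suite

The suite integrates at $h = 0.01$ over horizons 10–30 (1000–3000
steps) for the solver checks, uses $10^5$-point scans for the endemic
residual oracle, 1000 random draws for the algebraic property tests,
and 200 draws for the eigenvalue-structure test; the full run
completes in well under a minute on a single core.

## Known limitations

* The threshold formula implemented is the printed final form; no
  next-generation matrix derivation is attempted, and since the
  formula is structurally $< 1$, endemic existence is decided only by
  the numeric scan.
* The sweep horizon, step and orders default to sensible values but
  are not adaptive; very small $\sigma$ with long horizons makes the
  quadratic-memory cost noticeable.
* Global stability is diagnosed numerically (values of $M$ and
  $\dot M$ along trajectories), not certified symbolically.
* No parameter estimation from data, demographic structure, or
  stochastic variants.
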