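---
title: "The sliding-window CME solver: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sliding-window CME solver: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swcme)
```

## The model

A well-mixed reaction system with $n$ species and $k$ reactions is a
continuous-time Markov chain on population vectors
$x \in \mathbb{Z}_{\ge 0}^n$. Reaction $R_m$ has a change vector $v^{(m)}$
and a propensity $\alpha_m(x)$; for mass-action kinetics
$\alpha_m(x) = c_m \prod_i \binom{x_i}{l_i}$, the rate constant times the
number of distinct reactant combinations. The probability row vector
$p^{(t)}$ solves the chemical master equation $\dot p = pQ$, with the
generator $Q$ assembled from the propensities and the exit rates
$\lambda_x = \sum_m \alpha_m(x)$ on the diagonal.

Two features make the direct solution hard: the reachable space is often
infinite (gene expression) or combinatorially large, and the generator is
stiff (the enzyme system's fastest exit rate is $10^5$ while product
formation proceeds at rate $\sim 10$). The sliding-window method replaces
one global solve by a sequence of solves restricted to a finite window
$W_j$ that follows the probability mass. Restriction is by masking: the
window generator keeps transition rates between window members and the
*full* exit rate on the diagonal, so it is substochastic and every unit of
probability that would leave the window is genuinely lost from the vector,
not redistributed. The total loss after the last step,
$\eta_r = 1 - \sum_x p_r(x)$, is therefore an auditable upper bound on the
approximation error, and `sw_solve()` reports it per step, split into the
thresholding loss (mass outside the new window when the old vector is
masked) and the leak loss (mass that escaped during the transient solve).

## Window construction

The window for a step is predicted by *continuous deterministic worst-case
iterations*. Over a short interval $\Delta$ the number of $R_m$ firings is
approximately Poisson with mean $\alpha_m(x)\Delta$; a **branch** fixes,
per reaction, whether the iteration assumes the mean plus one standard
deviation (`MORE`, $\alpha\Delta + \sqrt{\alpha\Delta}$), minus one
(`FEWER`, clamped at zero), or the mean (`AVG`). For a Poisson mean of 1
the one-standard-deviation interval $[0, 2]$ carries 91.97% of the mass,
which is the per-reaction, per-step confidence the bounds are built on.
Each branch trajectory moves by
$x \leftarrow x + \sum_m \kappa_m v^{(m)}$ (clamped at zero, real-valued
throughout; propensities extend to real states via the falling-factorial
form of the binomial coefficient), and the window bounds are the
per-dimension envelope over all branches and all intermediate states,
rounded outward to integers only at the end.

Branches default to a sign rule (maximise species $d$: `MORE` for
reactions producing $d$, `FEWER` for consumers, `AVG` otherwise; the
minimising branch is the reverse; duplicates removed). The rule cannot see
indirect effects — a reaction that consumes a species may be necessary to
produce it downstream — so curated branch lists attached to a network take
precedence; the packaged enzyme and gene-expression models carry the
hand-chosen four branches appropriate to their dynamics, and the model file
format accepts `branch` lines for the same purpose.

The membership of a window is the bounds box intersected with the
network's conservation laws (integer vectors orthogonal to every change
vector, found by exact fraction-free elimination), united with the current
significant set. On the enzyme system the two laws collapse the
4-dimensional box to the 2-dimensional parallelogram of reachable
(complex, product) combinations, roughly an 80-fold reduction in window
size; without them the window would mostly contain unreachable states.
A `use_laws = FALSE` flag exists for debugging only.

## Step lengths and thresholds

Two stepping modes exist. *Equidistant* splits the horizon into `n_steps`
equal steps. *Adaptive* (the default) runs the branch iterations forward —
with the step policy $\Delta = 1/\lambda_x$, one expected transition per
iteration step; an alternative policy shrinks $\Delta$ until every
reaction's one-standard-deviation interval covers at least 80% of its
Poisson mass — and stops as soon as the predicted window holds at least
$\max(\texttt{min\_window},\; 2\,|S_j|)$ states, where $S_j$ is the
significant set. The doubling condition makes consecutive significant
regions roughly adjacent rather than nested; the floor
(`min_window = 500` by default) prevents degenerate tiny windows. The two
conditions are combined with `max()` — both must hold. The elapsed
iteration time becomes the step length $\tau_j$, capped by the remaining
horizon; requested output times inside a step are hit exactly by splitting
the transient solve within the same window, never by interpolation. The
branch look-ahead advances all sampled trajectories in lockstep with a
shared $\Delta$ (the smallest over the trajectories), and the size
condition is evaluated on geometrically growing chunks of iteration rounds
so that its cost never dominates; the compiled mass-action fast path makes
a round linear in (trajectories × reactions).

The significance threshold $\delta$ is chosen per step from the decade
schedule $10^{-5}, 10^{-6}, \dots$ as the largest value whose discarded
mass stays within a budget of $10^{-5} \tau_j/(t_r - t_0)$; because the
adaptive $\tau_j$ is unknown at thresholding time, the previous step's
length is used (first step: 1% of the horizon). The budget is
self-correcting: losses are audited, never assumed. Bound iterations start
from at most 10 states sampled uniformly from $S_j$ (accuracy does not
improve with more); the sample uses a dedicated RNG stream derived from the
run seed, so the solver choice cannot perturb the step structure, and a
fixed seed reproduces the run bit-for-bit.

## Transient solvers

**Uniformization** writes $e^{Q\tau} = \sum_k \mathrm{Pois}(\lambda\tau; k)
P^k$ with $P = I + Q/\lambda$ and $\lambda$ the largest exit rate of the
window. Poisson weights and truncation points come from the stable base-R
pmf/quantile routines; tails are trimmed to $\epsilon/2$ per side and
widened until the retained mass reaches $1-\epsilon$, so the truncation
error is bounded a priori. The weighted sum is accumulated on the fly in a
compiled kernel (no power vectors are stored), with iterate entries below
$10^{-20}$ dropped to preserve sparsity. Because $\lambda$ is local to the
window, stiff systems need far fewer terms than a global solve, which must
use the global maximum exit rate.

**Krylov propagation** approximates $e^{tA}v$ (here $A = Q_j^\top$) by
stepping: each substep projects onto an $m$-dimensional Krylov subspace via
Arnoldi (modified Gram–Schmidt with one reorthogonalization pass;
"happy breakdown" — an invariant subspace before $m$ steps — makes the
substep exact, and with $m \ge N$ the solve is exact up to round-off), and
exponentiates the small upper-Hessenberg projection by scaling-and-squaring
with the degree-13 Padé approximant. The local error is estimated a
posteriori from the two correction terms of the augmented Hessenberg
exponential; a substep is rejected when the estimate exceeds 1.2 times its
proportional share of the budget, and step sizes update as
$\tau_{i+1} = 0.9\,\tau_i(\mathrm{budget}/\epsilon_i)^{1/m}$ clipped to
$[0.2\tau_i, 5\tau_i]$. The initial step comes from the classical
truncation bound evaluated with the generator's infinity norm. Defaults:
$m = 30$ (configurable; 20 is a common alternative), budget split
proportionally to substep length. A substep underflowing $10^{-14} t$
raises a stiffness-failure error rather than looping forever. Exact
printed forms of the per-step error estimator are not universal in the
literature; the implementation follows the established exponential-
propagation convention (documented here deliberately, since this is a
place where reasonable codes differ).

The per-step error budget of the driver is $\epsilon\,\tau_j/(t_r-t_0)$
with $\epsilon = 10^{-8}$ by default, so solver truncation error is an
order of magnitude below the window losses in typical runs. After a Krylov
substep tiny negative round-off entries are clamped and the vector is
scaled back only if its mass exceeded the pre-step mass (mass must never
grow; uniformization preserves this structurally).

## Reference solvers and metrics

`global_solve()` solves over the full reachable space by uniformization,
by the dense matrix exponential (guarded to 4000 states — beyond that the
dense matrix itself is the memory problem), or by Krylov propagation; the
three routes agree pairwise within their tolerances and serve as
independent cross-checks of the windowed solver. `compare_dist()` reports
the total variation distance and the maximal relative error over states
whose reference probability exceeds a floor ($10^{-5}$ by default —
relative error on smaller probabilities is dominated by the reference's
own truncation).

## What the tests do and do not show

The test suite exercises the solver on the packaged study systems:

* the enzyme-conversion system (parameter set a: $c=(1,1,0.1)$, 1000
  enzymes, 100 substrates, 5151 reachable states) run to $t = 70$, by
  which time the reference places over 90% of the mass on the fully
  converted state. Three seeds keep $\eta_r \le 10^{-4}$, and the relative
  error against global uniformization at $\epsilon = 10^{-8}$ stays below
  $10^{-4}$ on all states above the $10^{-5}$ floor;
* the gene-expression system, whose mRNA marginal is an immigration–death
  process with the closed-form Poisson law of mean
  $(c_1/c_3)(1-e^{-c_3 t})$ — an analytic oracle independent of any
  solver — matched to $10^{-6}$ total variation on a truncated space whose
  truncation mass is below $10^{-10}$;
* the bistable toggle switch seeded with a discretized Gaussian (the
  initial distribution's variance is a required user input, not a
  default), run over a short horizon;
* containment checks in which $10^4$ (enzyme; $2\times 10^3$ for the
  slower gene-expression and switch systems) directly sampled jump-process
  trajectories stay inside the predicted bounds except for under 5% of
  visited states. The sampler lives in the test helpers; it is a test
  oracle, not a solution method.

Oracle-equivalence and cross-solver checks run on scaled-down enzyme
instances (tens of states to a few hundred) so the dense exponential
remains available as the independent reference; the full-size runs above
are the end-to-end evidence. Synthetic fixtures emulate the study systems
exactly (exact rate constants and initial states); what they do not probe
is model misspecification, non-elementary kinetics beyond the packaged
Hill functions, or state spaces whose significant mass is itself
intractably large — the method's own stated limit.

## Ablations and degenerate behaviour

Two knobs deliberately weaken the window construction to confirm that the
worst-case bounds earn their keep:

* `avg_only = TRUE` replaces every branch mode by `AVG` and widens bounds
  over a doubled look-ahead interval, so windows track only the
  deterministic mean path;
* `window_shrink = 0.05` trims each dimension of the bounds box by 5%
  (2.5% per side) before enumeration.

Both inflate $\eta_r$ by far more than an order of magnitude on the enzyme
system. In this implementation they do not merely degrade but collapse
(losses approach 1 over the full horizon): the conservation laws pin the
distribution against the *boundary* of the box (e.g. all free substrate
sits at $S = 0$ once conversion is under way), so a symmetric trim or a
zero-margin mean tube cuts directly into the bulk of the mass, and once
mass is lost the significant set — and with it the next window — shrinks
further. The qualitative conclusion (bounds without the standard-deviation
margin, or shrunken windows, are unusable) is the point of the ablation;
the precise loss value depends on window geometry heuristics that differ
between implementations. When a production run's audited loss exceeds the
alert level, the remedy is `retry_scale > 1`, which widens every window
about its midpoint; the driver itself never silently recomputes.

## Numerical and design choices

* States are ordered lexicographically everywhere, so matrices, output
  tables and runs are reproducible; distribution tables are written with
  17 significant digits and round-trip bit-exactly.
* Window enumeration under conservation laws solves for pivot dimensions
  (chosen greedily as the widest-ranged independent columns) over an
  integer grid of the free dimensions, verifying integrality and the laws
  exactly in integer arithmetic; the window-size estimate inside the
  adaptive stopping rule uses the same count (a box-volume fallback covers
  the law-free case), which only needs to order candidate windows, not be
  exact.
* Propensity evaluation at real-valued states clamps the falling-factorial
  binomial at zero; custom propensity expressions are validated for
  non-negativity on a probe grid at parse time.
* The state cap (default $5\times 10^6$ window states) turns a runaway
  window into an error naming the step, never a silent truncation.
* Problem sizes in the test suite (toy enzyme instances, $10^4$/
  $2\times10^3$ sampled trajectories, horizon $t=70$ for the full enzyme
  run) were chosen once as representative of the study systems while
  keeping the default suite comfortably runnable.

## Limitations

A single box-shaped window (even law-constrained) cannot follow genuinely
multimodal mass that separates into distant modes; the bistable switch
remains solvable only because one window can still cover both modes.
Window splitting would be the natural extension. The automatic sign-rule
branches miss indirect effects (curated branch lists are the supported
mechanism). Uniformization degrades when a single window still contains a
very fast subregion; the Krylov backend is the fallback there. And the
method's memory is bounded by the significant mass region — systems whose
significant support is itself huge are out of reach, windows or not.
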