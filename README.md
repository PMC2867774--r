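# swcme: sliding-window numerical solution of the chemical master equation

Stochastic chemical kinetics describes a well-mixed reaction system as a
continuous-time Markov chain over population states: a state is the vector
`x` of molecule counts, reaction `R_m` fires at rate `α_m(x)` and shifts the
state by its change vector `v^(m)`. The probability vector `p(t)` obeys the
chemical master equation (CME)

    dp/dt = p Q,

where `Q` is the infinitesimal generator (`Q(x, x') = α_m(x)` for
`x' = x + v^(m)`, diagonal `-λ_x` with `λ_x = Σ_m α_m(x)` the exit rate).
Solving the CME directly gives the full transient distribution — not just
means and variances — but the reachable state space is huge or infinite for
most biologically interesting networks, and stiffness (rate constants
spanning orders of magnitude) cripples solvers that operate on the whole
space at once.

`swcme` implements a sliding-window solver for this problem, aimed at
modellers who need transient probability distributions of reaction networks
(gene expression, enzymatic conversion, genetic switches) that a global
solver cannot handle. Each step of the iteration:

1. thresholds the current distribution at a dynamically chosen significance
   level δ and samples a few significant states;
2. predicts per-species lower/upper population bounds `b⁻, b⁺` over the next
   interval by worst-case *continuous deterministic* branch iterations — for
   each reaction a branch assumes the Poisson mean number of firings `αΔ`
   plus one standard deviation (`MORE`), minus one (`FEWER`), or the mean
   (`AVG`);
3. enumerates the window: all states inside `[b⁻, b⁺]` that satisfy the
   network's conservation laws, united with the significant set;
4. restricts the generator to the window (full exit rates on the diagonal,
   so the matrix is substochastic and leakage is physical), and
5. propagates the distribution with either **uniformization** (a
   Poisson-weighted sum of powers of `P = I + Q/λ`, truncated to tolerance
   ε) or an adaptive **Krylov-subspace** matrix exponential.

Probability mass dropped by thresholding or leaked out of a window is never
renormalized away: the solution object carries a per-step loss ledger, and
the total loss `η_r = 1 − Σ_x p_r(x)` is a rigorous bound on the
approximation error. Adaptive step lengths are chosen so each window just
outgrows the currently significant region (at least `max(500, 2·|S_j|)`
states).

## Worked example

Enzyme-catalysed substrate conversion `E + S <-> ES -> E + P` with rate
constants `c = (1, 1, 0.1)`, 1000 enzymes and 100 substrates (5151 reachable
states, two conservation laws):

```r
library(swcme)
net <- cme_example("enzyme", "a")
rs  <- reachable_states(net)
rs$N
#> [1] 5151

sol <- sw_solve(net, t_end = 70, eps = 1e-8, seed = 1)
sol
#> Sliding-window CME solution: enzyme_a, t in [0, 70]
#>   solver uniformization, adaptive stepping, 1009 window step(s), seed 1
#>   final support 37 states; total probability loss eta_r = 1.02e-05
```

By `t = 70` the system is almost fully converted, and the audited total
loss `η_r ≈ 1.0e-05` bounds the error of every reported probability. The
average window held ~632 states — an 8-fold reduction against the 5151-state
global space, and the local uniformization rates are far below the global
maximum exit rate of 1e5, which is where the method wins on stiff systems.
Comparing against a global solve of the full space:

```r
ref <- global_solve(net, 70, eps = 1e-8, method = "uniformization")
compare_dist(ref, sol$dist[[2]])
#> <comparison: total variation 5.09e-06; max relative error 2.25e-05 over 5 states with reference > 1e-05>
```

Infinite state spaces work the same way — `sw_solve(cme_example(
"gene_expression", "a"), t_end = 50, ...)` tracks the growing mRNA/protein
distribution through a moving window that a global method cannot even
enumerate. Models can also be read from a small text format (see
`?read_model` and `inst/extdata/*.cme`), and `inst/cli/swcme.R` exposes
`solve`, `global-solve`, `compare`, `reach` and `examples` subcommands for
shell use.

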