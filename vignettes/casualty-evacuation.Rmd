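---
title: "Models and methods for robust casualty evacuation planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for robust casualty evacuation planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The planning problem

After a major earthquake, casualties in a set of disaster areas $I$ must be
moved through a three-tier rescue chain: road vehicles carry them to
temporary field hospitals chosen from a candidate set $J$, where rapid
treatment (hemostasis, debridement, transfusion) stabilises them, and
helicopters then carry them onward to general hospitals chosen from a
candidate set $K$.  Casualties come in two triage classes $s \in \{\alpha
(\text{serious}), \beta (\text{moderate})\}$, each with an urgency weight
$\omega_s$ and a per-hour deterioration rate $p_s$; the fixture uses
$\omega = (2, 1)$ and $p = (0.8, 0.2)$.  Field treatment slows
deterioration to a fraction of its pre-treatment rate (the
`post_treatment_factor`, default $0.2$).

The objective is the total weighted trauma-score deterioration accrued in
transit,

$$\min \; F_1 + F_2, \qquad
F_1 = \sum_{i,j,s} 2\, t_{ij}\, p_s\, \omega_s\, x_{ijs}, \qquad
F_2 = \sum_{j,k,s} 2\, t_{jk} \cdot 0.2\, p_s\, \omega_s\, y_{jks},$$

where $x$ and $y$ are integer casualty flows on road and air arcs, $t$ are
one-way travel hours, and the factor 2 is carried exactly as the source
model states it (a vehicle round trip is the natural reading).  Constraints
cover pooled temporary-hospital capacity $C$, per-severity general-hospital
capacities $Q_{ks}$, fleet sizes and per-tool carrying capacities
($e_g = 6$ per vehicle, $e_h = 12$ per helicopter), no-empty-vehicle and
dispatch-only-from-open rules, full demand satisfaction, and road/air flow
conservation at every temporary hospital.

# Two formulations of one model

The model as originally stated indexes a binary per (arc, vehicle), which
creates massive symmetry at realistic fleet sizes (hundreds of identical
vehicles).  Because vehicles are interchangeable and no objective term
distinguishes them, the package's default **aggregated** formulation
replaces the per-vehicle binaries with an integer arc count $n_{ij}$
(helicopters: $m_{jk}$) under

$$\textstyle\sum_s x_{ijs} \le e_g n_{ij}, \quad n_{ij} \le \sum_s x_{ijs},
\quad n_{ij} \le \gamma U_j, \quad \sum_{ij} n_{ij} \le \gamma, \quad
\sum_i n_{ij} \ge U_j,$$

which preserves the optimal objective exactly.  The `per_vehicle`
formulation is retained verbatim and the equality of the two optima is a
standing test on seeded synthetic instances with small fleets
(`formulation = "per_vehicle"` is impractical above a dozen tools, which is
also why the aggregated form is the default).  The big-M in the
dispatch-from-open constraint is the fleet size itself, the tightest valid
bound, never an arbitrary constant.

# Fixture consistency: the fleet quantities

The published fleet table assigns 150 units to road vehicles and 280 to
helicopters.  Taken literally, 150 vehicles with 6 seats can move at most
900 casualties in single trips, fewer than the 985 casualties of the case
study, which makes the stated static model infeasible — yet results for it
are reported.  With the two quantities interchanged (280 vehicles, 150
helicopters) every published headline number is reproduced to within
printing precision: the nominal optimum 1283.45 against the printed 1283,
every sensitivity cell, and the opened-hospital patterns including the
third general hospital opening exactly when the inflated moderate-casualty
total (851) exceeds the two-hospital capacity (850).  The embedded fixture
therefore uses 280 vehicles and 150 helicopters.  `lushan_instance()`
documents the same reasoning, and the builders accept any `fleet_spec` for
users who want the literal assignment.

# The robust counterpart

Casualty counts are interval-uncertain: $q_{is} \in [\bar q_{is} - \hat
q_{is}, \bar q_{is} + \hat q_{is}]$ with $\hat q_{is} = \delta \bar
q_{is}$ and a per-area protection budget $\Gamma_i \in [0, 1]$.  Since the
uncertainty enters only the demand right-hand side, the protection function
is maximised at the interval's upper endpoint and the robust counterpart
collapses to demand inflation with a relaxed sense:

$$\textstyle\sum_j x_{ijs} \ge \bar q_{is} +
\operatorname{round}(\hat q_{is}\, \Gamma_i).$$

The scaled-deviation dual variables of the intermediate derivation are
analytic and never materialised; `worst_case_oracle()` independently
validates the collapse by evaluating plans at the extreme realization.

**Rounding.**  The deviation term is generally fractional and the source
only says a rounding method is applied.  The package defaults to
**ceiling**, for two reasons.  First, it is the conservative reading: a
plan that protects against "11.8 casualties" should plan for 12.
Second, only ceiling reproduces the published sensitivity table: nearest
rounding gives, e.g., 1294 instead of 1327 at budget 0.2 / variability 5%,
and fails to open the third general hospital at budget 0.8 / variability
20% (inflated moderate total 846 $\le$ 850 under nearest, 851 under
ceiling).  `half_up` and `floor` remain available on
`uncertainty_spec()`.

Two structural properties follow from the closed form and are enforced as
tests: the optimum is non-decreasing in $\Gamma$ and in $\delta$, and any
two settings with equal product $\delta \Gamma$ produce identical inflated
demands and hence identical optima.

# The two-stage dynamic extension

The multi-period model re-opens hospital decisions per period $t = 1,
\dots, T$ and adds waiting deterioration: a casualty moved in period $t$
accrues $p_s((t-1)\Delta t + 2 t_{ij})$ before treatment and $0.2\,
p_s((t-1)\Delta t + 2 t_{jk})$ after.  Tools used in period $t$ return one
period later, giving the availability recursion
$\text{avail}_{t+1} = \text{avail}_t - \text{use}_t + \text{use}_{t-1}$.
The recursion is stated in the source with the per-tool seat capacity
multiplying both sides; the package tracks availability in seat units, so
the capacity cancels and `fleet_availability()` works directly on tool
counts.  Cumulative capacity caps bind across periods; per-period demand
caps bind within them.  Under the per-period robust variant the total
served must reach $\bar q + \hat q \Gamma'$ while each period may serve at
most $\bar q - \hat q \Gamma'$, with the asymmetric signs kept exactly as
stated; with one period the two families are contradictory, so the builder
rejects $T = 1$ with a positive budget with a named diagnostic rather than
returning a silently infeasible model.

Defaults are $T = 2$ periods of $\Delta t = 1$ hour.  The period length
behind the published two-period results is never stated, so their exact
objective values are not reproduction targets; the package's own dynamic
results are validated structurally (limit equivalence to the static model
at $T = 1$, conservation, caps, monotonicity in the budget).

# Generalized Benders decomposition

The decomposition assigns the road leg ($x$, temporary-hospital openings,
vehicle recursion, demand) to the master problem with a surrogate $\theta
\ge 0$ for the air-leg cost, and the air leg ($y$, general-hospital
openings, helicopter recursion) to the subproblem with the handover
$\sum_i x_{ijst}$ fixed.  The optimality cut is the constant bound $\theta
\ge F_2(y^*)$, exactly as the source algorithm prints it.  A constant cut
cannot trade first-stage decisions against $\theta$, so the loop closes its
bound gap immediately — in practice two iterations, matching the published
iteration counts — but it also means the scheme is only exact when the
air-leg optimum is insensitive to which first-stage optimum the master
picks.  The package therefore treats the monolithic two-stage model as the
correctness anchor: equality of the GBD objective and the monolithic
optimum is asserted on the fixture and on seeded synthetic instances.  On
all of them the equality holds (air travel times vary little between
temporary hospitals, so the road leg dominates the trade-off); instances
engineered with strongly heterogeneous air access could break it, which is
a limitation of the printed cut, not of the implementation.  Subproblem
infeasibility (never triggered on the fixture, whose general capacities
cover total demand) is handled by a no-good cut on the opening pattern
plus a warning, since the source gives no feasibility-cut recipe.
The convergence tolerance defaults to $10^{-6}$ absolute (unspecified in
the source) and the iteration cap to 50.

# Solver backends

No MILP solver is available as an R library in the package's dependency
set, so `solve_milp()` abstracts two backends behind one surface:

* **`highs`** (default): the HiGHS branch-and-cut engine, driven through
  SciPy's `milp()` interface in a `python` subprocess with the model and
  solution exchanged as JSON.  All acceptance-grade solves use this
  backend at a relative MIP gap of 0.
* **`bb`**: a pure-R branch-and-bound over dense LP relaxations solved
  with `boot::simplex()`, depth-first with best-bound pruning and
  most-fractional branching.  It is intended for small models (tens of
  variables) and gives the cross-backend agreement test a genuinely
  independent code path.

Integer values returned by either backend are rounded to clear solver
tolerance noise before the objective is recomputed; `
extract_static_solution()` additionally recomputes $F_1 + F_2$ from the
flows and refuses to return if it disagrees with the solver objective by
more than $10^{-4}$.

# Synthetic instances and what they do (and do not) show

`generate_instance()` draws casualty counts uniformly on integer ranges
mirroring the fixture's spread (serious 5–70, moderate 23–153 per area),
travel times uniformly at millihour precision (road 0.4–2.5 h, air
0.55–0.75 h), and sizes capacities and fleets from the drawn totals with a
1.2 slack factor so that the nominal instance is always feasible.  The
published scaled-up experiments state only the instance sizes, not the
sampling law, so these choices are documented assumptions, not a
reproduction; the corresponding published feasibility counts are
exercised directionally (robust plans cover more realizations than
deterministic ones) rather than numerically.  `perturb_realization()`
draws realizations uniformly on the full uncertainty interval.  Uniform
i.i.d. travel times carry no spatial structure, so passing tests on
synthetic instances demonstrate model correctness, not geographic realism.

Plan feasibility under a realization is judged in two modes:
`"recourse"` (default) allows full reallocation within the plan's opened
hospitals — which for these complete bipartite networks reduces exactly to
aggregate capacity and fleet-seat conditions — while `"frozen"` requires
the plan's own flows to cover the realization.  Recourse is the default
because the source counts a plan infeasible only when hospital capacities
are violated.

# Problem sizes used in the shipped tests

The default test suite solves the 9×5×3 fixture (135 route triples, about
190 variables in aggregated form) in well under a second per solve, and
uses 3×2×2 synthetic instances for the formulation-equivalence,
robust-collapse, and decomposition-equivalence batteries, chosen so that
the per-vehicle formulation (which grows with the fleet size) and the
pure-R backend stay fast.  The Monte-Carlo coverage check evaluates 1,000
seeded realizations analytically, without solver calls.

# Known limitations

* Travel times, capacities, and costs are certain; only casualty counts
  are uncertain (matching the source's scope).
* No within-tier routing: each tool serves one arc per period.
* Treatment time at temporary hospitals is not modelled.
* The constant Benders cut is exact only under the insensitivity condition
  discussed above; `solve_dynamic()` solves the monolithic model directly
  and is the recommended route for instances with strongly heterogeneous
  air access.
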