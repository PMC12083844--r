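# casevac

Robust hospital location and casualty evacuation planning for earthquake
response.

## The problem

After a destructive earthquake, casualties scattered over disaster areas
must be rescued through a three-tier chain: road vehicles carry them to
temporary field hospitals for rapid stabilising treatment, and helicopters
then move them to general hospitals.  Planners must decide **which
candidate hospitals to open**, **how to allocate casualties to them**, and
**how many vehicles and helicopters to commit to each route** — under
tight hospital capacities, limited fleets, and uncertainty in how many
casualties each area actually holds.

`casevac` implements this family of mixed-integer programs for emergency
logistics researchers and practitioners:

* a **deterministic location–allocation MILP** minimising the total
  weighted trauma-score deterioration accrued in transit,
  `F1 + F2` with `F1 = Σ 2·t_ij·p_s·ω_s·x_ijs` on the road leg and
  `F2 = Σ 2·t_jk·0.2·p_s·ω_s·y_jks` on the air leg (deterioration slows to
  20% after field treatment; serious casualties carry weight `ω = 2` and
  rate `p = 0.8`/h, moderate `ω = 1`, `p = 0.2`/h);
* its **budget-of-uncertainty robust counterpart** for interval-uncertain
  casualty counts, which for right-hand-side uncertainty collapses to
  demand inflation `coverage ≥ q + round(δ·q·Γ)`;
* a **two-stage dynamic extension** with per-period openings, waiting
  deterioration, and a fleet-return recursion;
* a **generalized Benders decomposition** solver for the two-stage model,
  with a monolithic cross-check;
* a seeded **synthetic instance generator**, sensitivity / capacity /
  feasibility **experiment drivers**, and an embedded case-study fixture
  (2013 Lushan earthquake: 9 disaster areas, 5 candidate temporary and 3
  candidate general hospitals, 985 casualties).

MILPs are solved through the bundled HiGHS bridge (SciPy's `milp()` in a
`python` subprocess) or a pure-R branch-and-bound for small models.

## Worked example

```r
library(casevac)

inst <- lushan_instance()
sol <- solve_static(inst)
print(sol)
#> static evacuation plan
#>   objective 1283.4464 = F1 1149.9600 (road) + F2 133.4864 (air)
#>   temporary hospitals opened: J2, J5
#>   general hospitals opened:   K1, K3
#>   vehicles used: 169, helicopters used: 83
```

At nominal casualty counts the optimum opens temporary hospitals J2 and J5
and general hospitals K1 and K3; the plan accrues 1149.96 weighted
trauma-score units on the road leg and 133.49 on the (slower-deteriorating)
air leg.  `route_table(sol)` lists each used arc with serious casualties,
moderate casualties, and tools deployed:

```r
head(route_table(sol), 4)
#>   from to serious moderate tools
#> 1   I1 J2      59       43    17
#> 2   I1 J5       0      100    17
#> 3   I2 J5      21       48    12
#> 4   I3 J5      23       71    16
```

Protecting against the worst case of ±20% casualty-count uncertainty
raises the cost and forces a third temporary and a third general hospital
open:

```r
rob <- solve_robust(inst, uncertainty_spec(variability = 0.20, budget = 1))
print(rob)
#> static evacuation plan
#>   objective 1563.1116 = F1 1400.9700 (road) + F2 162.1416 (air)
#>   temporary hospitals opened: J2, J4, J5
#>   general hospitals opened:   K1, K2, K3
#>   vehicles used: 203, helicopters used: 102
```

The sweep, dynamic, and decomposition layers follow the same pattern:

```r
sensitivity_sweep(inst, gammas = c(0, 0.5, 1), deltas = c(0.05, 0.20))
solve_dynamic(inst, period_spec(n_periods = 2, period_length = 1),
              uncertainty_spec(0.15, 0.6))
gbd_solve(inst, period_spec(2, 1))
```

A command-line front end ships in `inst/cli/casevac` (commands
`solve-static`, `solve-robust`, `solve-dynamic`, `gbd`, `sweep`,
`generate-instance`, `simulate-feasibility`, `capacity-sweep`,
`export-lp`).

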