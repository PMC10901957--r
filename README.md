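# planarcrn

Qualitative dynamics of planar mass-action systems with deficiency one.

## The problem

A planar reaction network is a directed graph whose vertices are complexes
`aX + bY`, identified with points `(a, b)` in exponent space; together with
positive rate constants it defines the mass-action differential equation

    dx/dt = sum over edges (i -> j) of (a_j - a_i) * k_ij * x^a_i * y^b_i
    dy/dt = sum over edges (i -> j) of (b_j - b_i) * k_ij * x^a_i * y^b_i

on the open positive quadrant.  The deficiency `delta = m - l - 2`
(m complexes, l connected components) organises the qualitative theory: at
deficiency zero the unique positive equilibrium is globally stable, while at
deficiency one the static theory (at most one positive equilibrium, regular
Jacobian) says nothing about dynamics.  This package provides the tools
needed to explore that gap for two species:

* structural analysis: deficiency, weak reversibility, terminal strong
  components (`deficiency()`, `structure_report()`);
* existence and computation of the positive equilibrium for quadrangle
  cycles, chains of three reactions and triples of independent reactions,
  with the exact sign/geometry criteria (`chain_equilibrium()`,
  `three_reaction_equilibrium()`, `quadrangle_equilibrium()`);
* scaling of the equilibrium to (1,1) and Jacobian reports with closed-form
  cross-checks (`scale_to_unit()`, `jacobian_report()`);
* focal values (Lyapunov quantities) L1..L4 at a fine focus, in the
  pi-carrying return-map normalization, plus a numerical return-map oracle
  (`focal_values()`, `return_map_displacement()`);
* center certificates: monomial Bendixson-Dulac test, time-reversal
  symmetry across the diagonal, and the Lienard composition criterion
  (`dulac_test_quadrangle()`, `reversible_center_three_reactions()`,
  `lienard_center_check()`);
* degenerate Andronov-Hopf searches (trace = L1 = L2 = 0, ...) and the
  perturbation schedules that bifurcate up to three small limit cycles
  (`hopf_locus()`, `degenerate_hopf_search()`, `perturbation_schedule()`);
* positivity-preserving integration (log coordinates, adaptive RK 5(4) in
  compiled code), Poincare return maps and limit-cycle witnesses
  (`integrate_orbit()`, `poincare_return()`, `count_limit_cycles()`).

Every worked example ships as a programmatic fixture (`paper_fixture()`),
including the zigzag network whose positive equilibrium exists only for
some rate constants.

## A worked example

The quadrangle cycle on (0,1), (1,0), (1,2), (0,3) is weakly reversible
with deficiency one, so a unique positive equilibrium exists for every
choice of rate constants and the system is permanent.  With rates
(64, 1, 1, 1) the equilibrium is repelling and a stable limit cycle must
exist:

```r
library(planarcrn)
sys <- paper_fixture("quadrangle_31", kappa = c(64, 1, 1, 1))
eq  <- quadrangle_equilibrium(sys)
eq$point
#>        x        y
#> 22.627417  2.828427
trace_sign_condition_quadrangle_31(c(64, 1, 1, 1))   # trace > 0 iff TRUE
#> [1] TRUE
sc <- scale_to_unit(sys, eq$point)
count_limit_cycles(sc, x_range = c(1.05, 4), n_grid = 40)[[1]][c("fixed_point", "stability")]
#> $fixed_point
#> [1] 1.207889
#> $stability
#> [1] "stable"
```

The second quadrangle family (vertices (0,1),(0,0),(1,2),(1,5)), scaled so
the equilibrium sits at (1,1), has trace zero along `gamma = 16 + 1/K`;
its first focal value vanishes at an isolated K0, where the second focal
value is positive — the degenerate Hopf point behind a three-limit-cycle
configuration:

```r
s <- degenerate_hopf_search("quadrangle_32", "L1")
s$root
#>          K
#> 0.06862184
s$L
#> [1] 5.153682e-16 1.293357e-02
```

The zigzag network (complexes X, Y, X+2Y, 3Y) has a positive equilibrium
`(1/sqrt(2-kappa), sqrt(2-kappa))` only for `kappa < 2`; the Hopf point at
`kappa = 9/5` is subcritical:

```r
hopf_classification("zigzag", kappa = 9/5)[c("verdict", "L")]
#> $verdict
#> [1] "subcritical"
#> $L
#> [1]   1.208305 -10.044916 120.327684
```

(the first focal value is `5*pi/13 = 1.2083...`).

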