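---
title: "Methods: planar deficiency-one mass-action dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planar deficiency-one mass-action dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planarcrn)
```

## The model

A planar reaction network is a finite directed graph whose vertices are
points $(a_i, b_i) \in \mathbb{R}^2$, read as complexes $a_i X + b_i Y$;
the reaction vectors $(a_j - a_i,\, b_j - b_i)$ over all edges are assumed
to span the plane.  A mass-action system attaches a positive rate constant
$\kappa_{ij}$ to each edge, and evolves concentrations on the open positive
quadrant by

$$\dot x = \sum_{(i,j) \in E} (a_j - a_i)\, \kappa_{ij}\, x^{a_i} y^{b_i},
\qquad
\dot y = \sum_{(i,j) \in E} (b_j - b_i)\, \kappa_{ij}\, x^{a_i} y^{b_i}.$$

Exponents may be arbitrary rationals (negative and fractional exponents
occur in several fixtures); the package stores them as exact rationals so
they survive serialization and so the chain geometry below is computed
without rounding.  Translating every vertex by $(\alpha, \beta)$ multiplies
the field by the positive monomial $x^\alpha y^\beta$, a time
reparametrization that preserves orbits; `translate_network()` implements
it and the test suite checks the covariance.

The deficiency is $\delta = m - \ell - 2$ for $m$ complexes and $\ell$
connected components.  `structure_report()` computes $\ell$, the number $t$
of terminal (absorbing) strong components, weak reversibility (every edge
on a directed cycle), and whether the deficiency-one hypotheses
($\delta = 1$, $\ell = t = 1$) hold.  The classical deficiency-zero and
deficiency-one statements are used as *checked preconditions* only — the
package asserts their hypotheses, never re-proves them.

## Equilibria of the three studied classes

**Chains of three reactions** $P_1 \to P_2 \to P_3 \to P_4$.  With
$\Delta(ijk) = \det(P_j - P_i, P_k - P_i)$ (twice the signed triangle
area), set $h_1 = \Delta(243)$, $h_2 = \Delta(134)$, $h_3 = \Delta(142)$,
$h_4 = \Delta(123)$; then $h_1 + h_2 + h_3 + h_4 = 0$ exactly.  A positive
equilibrium exists iff $h_1$, $h_1 + h_2$, $h_1 + h_2 + h_3$ share a
nonzero sign — independently of the rate constants — and is then the
unique solution of a binomial system, solved exactly as a $2 \times 2$
linear system in $(\log x, \log y)$.  The equivalent geometric test (the
outer vertices on the same side of the middle segment's line, with the two
inner angles summing below $180^\circ$) is implemented separately and
cross-checked on hundreds of random chains.

**Three independent reactions** with sources not on a line and vectors
$(c_i, d_i)$.  Existence is equivalent to the three cross products
$c_2 d_3 - c_3 d_2$, $c_3 d_1 - c_1 d_3$, $c_1 d_2 - c_2 d_1$ sharing a
nonzero sign, again rate-independent, and the point again solves a
binomial system.

**Quadrangle cycles** (weakly reversible, $\delta = 1$) always have a
unique positive equilibrium.  There is no binomial reduction, so the point
is found numerically: Levenberg–Marquardt on the field divided by the total
monomial mass $\sum_i \kappa_i x^{a_i} y^{b_i}$, in log coordinates, from a
small deterministic start grid.  The normalization matters: the raw field
vanishes along the boundary as all monomials decay, so an unnormalized
residual can fake convergence toward the axes (plain damped Newton does
exactly that on the first worked example); the mass-normalized residual
tends to a positive constant along boundary rays, which removes the trap.
Acceptance: normalized residual below $10^{-11}$, typically $10^{-14}$.

**Scaling.**  `scale_to_unit()` moves the equilibrium to $(1,1)$:
$\bar\kappa_i = \kappa_i \bar x^{a_i} \bar y^{b_i}$, $K = \bar x/\bar y$,
with the $y$-equation carrying the factor $K$.  For chains
$\bar\kappa_i = \lambda \cdot (h_1, h_1{+}h_2, h_1{+}h_2{+}h_3)_i$ and for
three-reaction systems $\bar\kappa_i = \lambda \cdot$ (cross products);
$\lambda$ is recovered from the first relation and checked against the
other two at $10^{-10}$ relative — a failed check signals a wrong
equilibrium.  `jacobian_report()` differentiates the scaled field and
cross-checks the determinant against the closed forms
$\det J = \frac{h_1+h_2+h_3}{\lambda} K \bar\kappa_1\bar\kappa_2\bar\kappa_3$
(chains) and
$\det J = \frac{K}{\lambda} \bar\kappa_1\bar\kappa_2\bar\kappa_3
[a_1(b_2-b_3)+a_2(b_3-b_1)+a_3(b_1-b_2)]$ (three reactions).

## Focal values and their normalization

At a fine focus (trace $0$, determinant $> 0$) the stability question is
decided by the focal values $L_1, L_2, \dots$: coefficients of the odd
powers of the radius in the displacement of the Poincaré return map.  The
package computes them as follows.

1. Taylor-expand the field about the equilibrium to order $2k_{\max} + 2$
   using generalized binomial coefficients,
   $x^a y^b = \sum \binom{a}{i}\binom{b}{j} u^i v^j$ (exact for rational
   exponents; `local_expansion()`).
2. Bring the linear part $J = \begin{pmatrix} \alpha & \beta \\ \gamma &
   -\alpha\end{pmatrix}$ to rotation form with the specific change of
   coordinates $U = u$, $V = -(\alpha u + \beta v)/\omega$,
   $\omega = \sqrt{\det J}$.  Keeping $U$ equal to the original
   $x$-displacement fixes the radial gauge; without this choice the
   higher-order coefficients are only defined up to positive factors.
3. Build a formal first integral $H = (U^2 + V^2)/2 + H_3 + H_4 + \dots$
   degree by degree.  At odd degree the homological operator
   $\omega(U\partial_V - V\partial_U)$ is invertible; at even degree
   $2k + 2$ the unremovable residual is
   $\dot H = g_{2k+2}\,(U^2+V^2)^{k+1} + \dots$.
4. Report $L_k = -2\pi\, g_{2k+2}/\omega$.

The constant in step 4 is the package's convention anchor.  It was fixed
once by requiring agreement with the two published closed-form first focal
values of the quadrangle and chain families (both carrying a factor
$\pi$); the ratio of the implemented $L_1$ to those formulas is $1$ to
thirteen digits across both families and all sampled parameters, and the
same convention then reproduces, with no further freedom, the published
second and third focal values, every published root, and the value
$5\pi/13$ for the zigzag network.  Acceptance criterion 1 re-verifies the
ratio at 20 sampled parameter points per family.

Three points deserve care:

* **Arithmetic.** The reference implementations of such computations are
  symbolic; this environment has no computer-algebra system, so the
  recursion runs in double precision.  The expansion coefficients are
  $O(1)$–$O(10^2)$ for every fixture, and comparison with the published
  closed forms shows $\ge 8$ significant digits for $L_1$–$L_3$; all
  acceptance targets are met with two or more digits to spare.  Center
  checks therefore use the threshold $|L_k| < 10^{-8}$ rather than an
  exact symbolic zero.
* **Higher values are convention-dependent.** $L_{k}$ is well defined only
  modulo $L_1, \dots, L_{k-1}$.  All published higher values are evaluated
  on the locus where the lower ones vanish, so the residual ambiguity is
  below the numerical noise floor.
* **Which coordinates.** For families already given in scaled form the
  focal values refer to the scaled system.  For the zigzag network the
  published value is matched by the focal value of the *original* vector
  field at its equilibrium (an anisotropic rescaling multiplies the
  displacement coefficients by powers of $\bar x$), and
  `hopf_classification("zigzag", ...)` computes it there.

The independent oracle is `return_map_displacement()`: direct integration
from $(1 + r_0, 1)$ back to the section $\{y = 1, x > 1\}$ with matching
crossing orientation.  Its sign must agree with the first nonzero focal
value, and for every certified center it is below $10^{-8}$ at
$r_0 = 0.05$.

## Center certificates

* **Bendixson–Dulac** (quadrangles).  With $h = x^{-\alpha} y^{-\beta}$
  the scaled divergence is a sum of terms with coefficients
  $(\alpha - a_i)(a_i - a_{i+1})$ and $(\beta - b_i)(b_i - b_{i+1})$.  The
  feasible $\alpha$ set is the interval
  $[\max\{a_i : a_i < a_{i+1}\},\ \min\{a_i : a_i > a_{i+1}\}]$; the
  published treatment enumerates the orderings with $a_1$ minimal and
  notes the rest are analogous, so the interval formula is taken as the
  general form and validated against a brute-force feasibility scan over
  many orderings and tie patterns.  A certificate needs both intervals
  nonempty and at least one strict term; the chosen exponents are the
  interval midpoints (determinism).  When the test is inconclusive the
  obstruction pattern $a_i < a_{i+3} < a_{i+1} < a_{i+2}$ (indices cyclic,
  $a_i$ minimal) is reported with its index.
* **Reversibility.**  A field with $\dot y(x, y) = -\dot x(y, x)$ as an
  exact identity of term sets is symmetric under reflection across the
  diagonal with time reversal, so a fine focus on the diagonal is a
  center.  The three-reaction sufficient conditions (sign chain, ratio
  ordering, geometric-mean condition, $K = -c_1/d_1$) are checked in
  order and the first violated condition is named.  The rate-constant
  construction ($\kappa_1$ free,
  $\kappa_3/\kappa_2 = -\frac{c_2}{d_3}(-c_1/d_1)^{p-q-1}$) is verified by
  the full pipeline: solve the unscaled equilibrium, scale, re-check
  reversibility.
* **Liénard composition.**  For the source pattern
  $(1,0), (0,-\tfrac12), (0,-2)$, differentiating the $y$-equation once
  yields $\ddot y + f(y)\dot y + g(y) = 0$; the origin is a center iff
  $F = \Phi \circ G$ for analytic $\Phi$ with $\Phi(0) = 0$, where $F, G$
  are the antiderivatives.  Under the balance
  $c_1\bar\kappa_1 = K d_2 \bar\kappa_2 = 4 K d_3 \bar\kappa_3 \ne 0$ this
  holds with quadratic $\Phi$; the two $\Phi$ coefficients are computed
  from their closed forms and independently re-fitted by least squares on
  sampled $(G, F)$ pairs, and both must agree to $10^{-8}$ — a cheap trap
  for sign errors in $\lambda$.  Zero reaction-vector components may drop
  terms from one equation of the scaled field; the pattern check works on
  the union of exponents and treats missing terms as zero coefficients.

## Bifurcation searches

Trace-zero loci are closed forms in every family.  Degenerate points are
found by bisection (one dimension, brackets from the stated parameter
domains) or damped finite-difference Newton (two dimensions, seeded at the
published approximations rounded to two digits, which avoids circularity
while staying in the right basin; a coarse sign-change scan gives the same
seeds).  Roots reproduce all published values: the quadrangle $K_0$, the
chain point $(q, r, K) = (1/4, 15/8, 4/3)$, the three-reaction curve
points $(1, 165/49)$ and $((1+\sqrt{3961})/60, 3)$, the joint root
$(\hat a, \hat b, \hat d)$, and the free-exponent quadrangle pair
$(K, b_4) \approx (0.0909, 4.757)$.  The emitted perturbation schedules
record the proof-order steps (which parameter, which direction, which
relations are maintained) and the expected cycle counts; the three- and
four-cycle configurations themselves live in parameter windows far too
small for desk-scale numerics, so they are *not* numerically witnessed —
the package's evidence is the focal-value sign chain, as in the source
analyses.

## Numerical dynamics

Integration runs in $(\log x, \log y)$, so positivity is structural, with
an adaptive Dormand–Prince 5(4) scheme in compiled code (no ODE-suite
dependency is available in this toolchain).  Section crossings are located
by bisection of a single embedded step inside the accepted step, giving
crossing abscissae at integrator accuracy.  Orbits that reach
$y < 10^{-6}$ are reported as boundary convergence ("axis") and orbits
leaving $[10^{-30}, 10^{30}]^2$ as blow-up.  `count_limit_cycles()` scans
the return-map displacement on a section grid, refines sign changes by
bisection and classifies stability via the numerical return-map slope;
displacements below $10^{-9}$ at both bracket ends are treated as center
noise, not roots.

Some orbits of the reversible-center families reach the coordinate axes in
*finite time* (power-law fields with negative exponents are singular
there); this is genuine dynamics, reported as a step failure/left-box
status rather than an error.  In particular the closed-orbit region of the
reversible chain family with $(p, q) = (2, -1)$ meets the diagonal only up
to about $1.1$ — diagonal starts beyond that escape to the axis.

## The zigzag fixture

The zigzag network is stated in the sources only as a figure, so the
package reconstructs it from its published invariants: equilibrium family
$(1/\sqrt{2-\kappa}, \sqrt{2-\kappa})$ for $\kappa < 2$, Jacobian trace
$5\kappa - 9$, invariant $x$-axis consisting of equilibria that attract
nearby orbits iff $\kappa > 1$, deficiency one, unit rate constants except
one free $\kappa$.  These constraints force the source complexes
$Y$, $X{+}2Y$, $3Y$ and the ODE
$$\dot x = (1+\kappa) y - 3 x y^2 + y^3, \qquad
  \dot y = (1-\kappa) y + x y^2 - y^3,$$
realized on the complexes $X, Y, X{+}2Y, 3Y$ by the five reactions
$Y \to X{+}2Y$ (rate 1), $Y \to X$ (rate $\kappa$), $X{+}2Y \to 3Y$
(rate 3), $X{+}2Y \to X$ (rate 1), $3Y \to X{+}2Y$ (rate 1), with
$\ell = t = 1$ and no weak reversibility.  The reconstruction is confirmed
by a value not used in its derivation: the first focal value at
$\kappa = 9/5$ equals $5\pi/13$ to ten digits ($\det J = 4(2-\kappa)^2$,
$g_4 = -1/13$).  Only the net per-source coefficients are pinned by the
invariants; any re-decomposition into reactions with the same net
coefficients gives the identical ODE.

## Synthetic networks

`random_network()` draws quadrangle cycles, chains and three-reaction
systems with half-integer exponents in $[-2, 4]$ and log-uniform rate
constants in $[e^{-1}, e]$ — the same lattice and magnitude range as the
worked examples — and rejects degenerate configurations (collinear
sources, rank-deficient reaction vectors).  These generators exercise the
structural and equilibrium code on the classes the theory covers; they do
not emulate mass-conserving kinetics, multistationarity, or anything
beyond two species, so green property tests establish correctness of the
implemented criteria on their stated domain, not biological realism.

## Limitations

* Focal values beyond $L_4$, normal forms for non-semisimple linear parts,
  and interval-certified root isolation are out of scope.
* The fourth-cycle configuration rests on numerical evidence
  ($L_4 < 0$ in double precision at the degenerate point); like the
  sources, the package treats four limit cycles as a conjecture.
* The Dulac test covers monomial multipliers on quadrangle cycles only.
* The permanence of the chain family is used as a remark (boundedness is
  checked numerically, not proved).
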