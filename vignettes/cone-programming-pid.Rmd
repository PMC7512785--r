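---
title: "Partial information decomposition as an exponential cone program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial information decomposition as an exponential cone program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pidcone)
```

## The decomposition

For discrete random variables $X, Y, Z$ with finite ranges, the mutual
information $MI(X; Y, Z)$ admits a decomposition into four nonnegative
parts: information shared redundantly by $Y$ and $Z$ about $X$
($SI$), information unique to $Y$ ($UI_Y$) or to $Z$ ($UI_Z$), and
information that emerges only synergistically from the pair ($CI$).
The four parts are tied to classical quantities by three identities:

$$SI + UI_Y = MI(X;Y), \qquad SI + UI_Z = MI(X;Z),$$
$$SI + UI_Y + UI_Z + CI = MI(X;Y,Z),$$

so fixing any one of them fixes the whole decomposition.  The BROJA
measure (after Bertschinger, Rauh, Olbrich, Jost and Ay) defines the
synergy as

$$CI(X;Y,Z) = MI(X;Y,Z) \; - \; \min_{q} \, MI_q(X;Y,Z),$$

where the minimum runs over all joint distributions $q$ of $(X,Y,Z)$
that share the input's $(x,y)$ and $(x,z)$ pair marginals.  Given the
marginal constraints, minimizing $MI_q$ is equivalent to maximizing the
conditional entropy $H_q(X \mid Y,Z)$, a concave function over a
polytope — a convex program, but one whose objective is non-smooth on the
boundary, where the optimum often sits.  That boundary non-smoothness is
what makes naive solvers unreliable here, and what motivates the conic
treatment.

## The exponential cone program

Writing the objective atomically, each term $q_{xyz}\ln(q_{xyz}/q_{*yz})$
is handled by one three-dimensional exponential cone
$K_{\exp} = \mathrm{cl}\{(r,t,q) : q > 0,\; q e^{r/q} \le t\}$: the program

$$\min -\textstyle\sum r_{xyz} \quad \text{s.t.} \quad
  q_{x,y,*} = p_{x,y,*},\; q_{x,*,z} = p_{x,*,z},\;
  q_{*,y,z} = t_{xyz},\; (-r,-t,-q)_{xyz} \preceq_{K_{\exp}} 0$$

is equivalent to the smooth problem, and its Lagrange dual has one
multiplier $\lambda_{xy}$ or $\lambda_{xz}$ per marginal equation, one
$\mu_{xyz}$ per coupling equation, and a dual-cone multiplier triple
$\nu_{xyz}$ per cone, with the reduced dual feasibility condition

$$\lambda_{xy} + \lambda_{xz} + \mu_{*,y,z} + 1 + \ln(-\mu_{xyz}) \ge 0 .$$

`build_exp_program()` assembles exactly this conic data (sparse `A`,
`b`, `G = -I`, `h = 0`, one cone per supported triplet).  Two structural
reductions are applied, both exact:

* **Zero-probability discarding.**  Input atoms with $p = 0$ are dropped
  at construction.
* **Support restriction.**  Variables are created only for triplets with
  $p_{x,y,*} > 0$ *and* $p_{x,*,z} > 0$; every other coordinate of any
  feasible $q$ is identically zero.  This is what keeps the Copy-gate
  family tractable: its unrestricted variable count scales as
  $|Y|^2|Z|^2$, the restricted one as $|Y||Z|$.

The analytic point $\tilde q_{xyz} = p_{x,y,*}\,p_{x,*,z}/p_{x,*,*}$
(the conditional-independence coupling), with $\tilde t = \tilde
q_{*,y,z}$ and $\tilde r = \tilde q \ln(\tilde t/\tilde q) - 100$, is
strictly feasible: its own pair marginals reproduce $p$'s exactly on the
support, and $\tilde q e^{\tilde r/\tilde q} = \tilde t e^{-100/\tilde q}
< \tilde t$.  The existence of this interior point is what upgrades weak
duality to strong duality, so a zero duality gap is the correct
optimality certificate, and `interior_point()` exposes the construction
so that the certificate's precondition can be checked computationally
rather than assumed.  (The $-100$ offset is inherited as-is; any strictly
negative offset works, and its magnitude is irrelevant because the $r$
variables are unconstrained in sign.)

## The solver

No exponential-cone solver is available to this package's target
environment as a dependency, so the backend is implemented here, as a
primal path-following interior-point method specialized to this problem
family.  After eliminating the $r$ and $t$ variables, every program in
the package has the form

$$\min \; \sum_{i \in E} v_i \ln(v_i / V_{b(i)}) \quad \text{s.t.}
  \quad Bv = b,\; v \ge 0,$$

with $V_b$ the sum of $v$ over an aggregation cell.  The engine follows
the central path of $f(v) - \tau \sum_i \ln v_i$ with feasible-start
Newton steps, exploiting three structural facts:

* the Hessian is per-cell diagonal-minus-rank-one, so its inverse is a
  cancellation-free Sherman–Morrison update (the update factor is
  computed as $1/\sum_i \tau v_i/(v_i+\tau)$; the textbook
  $1 - \beta s_b$ form loses six digits once $\tau \ll V_b$);
* the Newton system is solved through the Schur complement
  $B H^{-1} B^\top$ (dense Cholesky below 320 rows, sparse above) and
  polished by iterative refinement against the exact Hessian;
* at an exactly centered point the multipliers satisfy
  $\ln(v_i/V_b) + (B^\top\lambda)_i = \tau/v_i > 0$, so the returned dual
  point is feasible *with positive margin* and the duality gap equals
  $n\tau$ — the certificates are small by construction, not by luck.

The barrier is driven from $\tau = 0.1$ to $10^{-11}$ by factors of 50.
The floor value is a compromise struck once for all instances: the
decomposition error inherits a term of order $n\tau\lvert\ln\tau\rvert$
from the boundary-active coordinates (which sit at $v \sim \tau$), so
$10^{-11}$ leaves the gate benchmarks with errors near $10^{-11}$ bits,
comfortably below their $10^{-9}$ validation threshold, while staying
inside what double precision supports for the Newton systems.

Two failure modes of hard instances shaped the engine:

* **Vanishing cells.**  When the optimum lies on a face where a whole
  $(y,z)$ cell's mass vanishes, the Newton systems become severely
  ill-conditioned near the barrier floor.  The engine therefore computes
  the certificate triple (primal violation, dual violation, duality gap)
  at the end of every stage past $\tau = 10^{-6}$ and snapshots the
  deepest iterate meeting the strict tolerances; if a deeper stage stalls
  or degrades, that snapshot is returned instead of the damaged iterate.
* **Deceptive decrements.**  A small Newton decrement does not bound the
  dual residual of large coordinates (the allowed decrement there scales
  like $\mathrm{feastol}^2 \cdot v$), so certificate stages iterate to the
  numerical noise floor — detected as repeated tiny steps without
  decrement progress — rather than to a $\tau$-proportional threshold.
  The equality multipliers are additionally re-fit at stage ends by a
  rank-revealing least-squares solve of the centrality equations, which
  removes the noise the Schur solve leaves along near-null directions of
  $B^\top$.

Solutions are classified `optimal` when the three certificates meet the
strict tolerances (`feastol` $10^{-7}$ for both feasibility violations,
`abstol` $10^{-6}$ or `reltol` $10^{-6}$ for the gap), `inaccurate` at
the relaxed tolerances ($10^{-3}$, $10^{-4}$, $10^{-4}$), and `failed`
otherwise; in all three cases the vectors are returned, and an exception
is raised only when no iterate exists at all.  `max_iter` (default 100)
caps total Newton iterations.

## From solution to decomposition

`decompose()` evaluates the decomposition from the positive part of the
returned $q$ (nonpositive entries dropped, no renormalization):
$CI = MI_p(X;Y,Z) - MI_{q^+}(X;Y,Z)$, $UI_Y = MI_{q^+}(X;Y\mid Z)$,
$UI_Z = MI_{q^+}(X;Z\mid Y)$, $SI = MI_p(X;Y) - UI_Y$, reported in bits.
The conditional-mutual-information route reproduces the additivity
identities exactly at the optimum; off-optimum discrepancies are exposed,
not hidden, through the `Num_err` triple:

1. `Num_err[1]`: $\max(|q^+_{x,y,*} - p_{x,y,*}|, |q^+_{x,*,z} -
   p_{x,*,z}|, -q_{xyz})$,
2. `Num_err[2]`: $\min(\lambda_{xy} + \lambda_{xz} + \mu_{*,y,z} + 1 +
   \ln(-\mu_{xyz}),\, 0)$ over triplets,
3. `Num_err[3]`: $\max(-H_q(X\mid Y,Z) + \lambda^\top b,\, 0)$, the
   duality-gap violation, with $H$ evaluated from the returned $q$ (the
   robust choice before convergence; at optimality it coincides with
   $\sum r$).

Slightly negative decomposition values caused by numerical noise are
reported as-is; quality is judged from `Num_err`, not by clipping.

## Trivariate extensions

For a target $S$ and three sources $X, Y, Z$, the synergy
$CI(S;X,Y,Z)$ minimizes $MI(S;X,Y,Z)$ over distributions sharing the
three (target, source) pair marginals — structurally the bivariate
program with the source triple in the conditioning role
(`build_tri_synergy_program()`).  The unique information
$UI(S;X\setminus Y,Z)$ subtracts from that optimum the minimum of
$MI(S;Y,Z)$ over the same polytope.  The second objective depends on $q$
only through the aggregates $q_{s,*,y,z}$, and its printed formulation
declares variables on $S\times Y\times Z$ while constraining marginals
over $(s,x)$ — dimensionally inconsistent as stated.  This package
resolves it by keeping $q$ over the full quadruple support as nonnegative
scalar variables and introducing aggregate variables
$u_{s,y,z} = q_{s,*,y,z}$ that carry the exponential cones
(`build_tri_condmarg_program()`); this reading is flagged as ours, chosen
because it preserves both the marginal constraints and the objective
exactly.  Both programs run on the same engine (the aggregates are the
entropy variables; the $q$ enter linearly), and both return the same
certificate triple, so the strong-duality claims are checked numerically
on every instance rather than assumed from theory.

A note on dual sign conventions: the printed componentwise dual system
pins $\nu^1 = -1$ and couples $\nu^2$ to the coupling multiplier
$\mu < 0$; membership of $\nu$ in the dual cone requires $\nu^2 > 0$, so
the package emits $\nu^2 = -\mu$, which is the choice consistent with the
reduced dual constraint that the certificates use.

## Synthetic benchmark families

The package generates all of its validation inputs:

* **Gates** (`gate()`): seven canonical deterministic maps of independent
  uniform input bits (Rdn, Unq, Xor, And, RdnXor, RdnUnqXor, XorAnd).
  Exact input distributions are used — no sampling noise — so each gate
  has a closed-form or brute-force-computable decomposition and the
  estimator can be validated to $10^{-9}$ bits.
* **Copy gates** (`copy_gate(m, n)`): $x = (y,z)$ on uniform independent
  $(y,z)$; $UI_Y = \log_2 m$, $UI_Z = \log_2 n$, $SI = CI = 0$ in closed
  form at every size, which validates correctness at scale (the test
  grid runs $m, n \le 30$, chosen so the full suite stays in the minutes
  range on one core; the support reduction makes far larger sizes
  feasible).
* **Random distributions** (`random_pmf()`): draws from the flat
  Dirichlet (i.i.d. standard-exponential weights, normalized) on the
  outcome simplex, in three families — $|X|{=}|Y|{=}2$ with $|Z|$
  varying, $|X|{=}|Z|{=}2$ with $|Y|$ varying, and cubes
  $|X|{=}|Y|{=}|Z|{=}s$.  The robustness suite runs 100 draws per group
  with $|Z|, |Y| \le 8$ and $s \le 10$ (again a one-core-minutes
  choice), and asks for at least 99% of each group solved at strict
  tolerances.

These families probe complementary failure modes — exactness on
structured boundary optima (gates), scale (Copy), and boundary-touching
random geometry (simplex draws, the known hard case for this
optimization).  What they do not emulate is real estimated data:
empirical distributions carry sampling noise, zero-inflation and
estimation bias that are out of scope here (the package takes a pmf as
ground truth; it does not estimate one from samples).  Passing these
suites therefore certifies the *optimizer*, not any statistical
procedure upstream of it.

## Reproducibility and numerical choices

All experiment harnesses are seed-reproducible end to end: a single seed
draws per-instance sub-seeds, and `random_pmf(sizes, seed)` restores the
caller's RNG state.  The builders are deterministic (lexicographic
ordering on stringified symbols), and the solver contains no randomness,
so identical inputs give bit-identical problem data and certificates.

Remaining numerical choices, and their defaults: total-mass tolerance on
input pmfs $10^{-10}$; KKT static regularization $10^{-12}$ times the
Schur diagonal scale (bumped $10^6$-fold once on Cholesky failure);
dense/sparse crossover at 320 equality rows; fraction-to-boundary factor
0.995 with Armijo backtracking.  Degenerate inputs are handled
structurally: a single-atom pmf yields a one-cone program whose optimum
is the atom itself; a constant coordinate collapses the corresponding
marginal family to one row; duplicated input rows are aggregated.

## Limitations

* The engine is specialized to entropy-block objectives; it is not a
  general conic solver, and the `ConeProblem` data it consumes carries
  the reduction metadata it needs.
* Very adversarial instances can exhaust `max_iter` before the strict
  tolerances are met; they are reported `inaccurate` or `failed` with
  honest certificates rather than retried.
* Alphabets beyond a few tens per coordinate are untested territory for
  runtime (the scaling is driven by $|X||Y||Z|$ variables and
  $|X|(|Y|+|Z|)$ equality rows).
* Only the two trivariate quantities with an exponential-cone form are
  implemented; the remaining terms of the trivariate lattice are out of
  scope.
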