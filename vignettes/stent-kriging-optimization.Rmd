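---
title: "Adaptive Kriging optimization of stent geometry and balloon length: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Kriging optimization of stent geometry and balloon length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentopt)
```

# The optimization problems

Two design problems share one optimizer in this package.

**Fatigue life.** Under pulsatile arterial loading every node of a
deployed stent cycles between a systolic and a diastolic stress state,
summarized as mean stress $\sigma_m = (\sigma_{sys}+\sigma_{dia})/2$ and
alternating stress $\sigma_a = |\sigma_{sys}-\sigma_{dia}|/2$. On the
Goodman diagram the failure line
$\sigma_a/\sigma_N + \sigma_m/\sigma_{UTS} = 1$ separates safe states
(below) from failure-prone ones. The design objective is the *shortest*
signed Euclidean distance $D^{shortest}$ from any node to that line —
a stent is only as durable as its worst node — maximized over strut
geometry subject to all nodes remaining safe:

$$\max_x D^{shortest}(x) \quad \text{s.t.}\quad
  \underline{x} \le x \le \bar{x},\quad
  \sigma_a/\sigma_N + \sigma_m/\sigma_{UTS} \le 1 .$$

**Expansion quality.** The dogboning ratio
$DR = (d^{distal} - d^{proximal})/d^{proximal}$ (radial displacements
$d = r(t) - r_0$) quantifies non-uniform expansion: positive means the
distal ends flare first, negative means they lag. It is evaluated at
32 ms — the end of the pressure hold, when the stent is maximally
expanded against the vessel wall and transient injury peaks — and the
balloon length $L$ is chosen to minimize $|DR(32\,\mathrm{ms})|$ on its
admissible interval.

Both evaluators are treated as expensive black boxes; in production each
call is a nonlinear finite-element run, here the bundled reduced-order
models stand in (section "Reduced-order stand-ins" below).

# The surrogate

`kriging()` fits ordinary Kriging: a Gaussian process with constant
trend and anisotropic squared-exponential correlation
$R_{ij} = \exp\{-\sum_l \theta_l (u_{il}-u_{jl})^2\}$ on coordinates
scaled to $[0,1]^d$. Three modelling decisions were genuinely open and
resolved as follows:

* **Correlation family.** Gaussian (squared-exponential). The objectives
  the surrogate stands in for — safety distances and displacement ratios
  of smooth elastic structures under smoothly varying geometry — are
  infinitely differentiable away from contact transitions, which is the
  regime this kernel encodes. It is also the standard choice in the EGO
  literature this loop follows.
* **Trend.** Constant (ordinary Kriging). Predictions are then weighted
  averages of the observed responses, which is the behaviour wanted from
  an interpolator refined pointwise; with 5–60 training points there is
  no basis for estimating higher-order trends.
* **Hyperparameters.** $\theta$ is estimated by maximizing the
  concentrated log-likelihood
  $-\tfrac n2 \log\hat\sigma^2 - \tfrac12 \log|R|$ over
  $\log_{10}\theta \in [-3, 3]^d$ (i.e. `theta_bounds = c(1e-3, 1e3)` on
  the unit cube) with 10 seeded multistart L-BFGS-B searches plus one
  deterministic start at $\theta = 10$. The search space is bounded
  because on $[0,1]$-scaled coordinates correlation lengths outside that
  range are indistinguishable from white noise or a constant.

Numerical conditioning: a relative nugget of $10^{-10}$ is added to the
correlation diagonal; if the Cholesky factorization still fails the
nugget escalates by factors of 10 up to $10^{-6}$, after which fitting
aborts with an error naming the likely near-duplicate points. Exact
duplicates with consistent responses are collapsed before fitting;
duplicates with conflicting responses are an error (this is an
interpolating, noise-free model by design — stochastic Kriging is out of
scope). A single training point yields the degenerate constant surrogate
with zero process variance, preserving the limit "one observation
predicts itself everywhere".

The predictive variance uses the full ordinary-Kriging formula including
the trend-estimation term
$(1 - \mathbf{1}^\top R^{-1} r)^2 / (\mathbf{1}^\top R^{-1}\mathbf{1})$,
clamped at zero against cancellation. Tests tie mean and variance to an
independently written dense-solve BLUP oracle at $10^{-8}$.

# Initial design: the modified rectangular grid

`mrg_design()` builds the initial training sample in three steps:

1. **Factorial grid.** Per-axis level counts are the smallest factorial
   with at least `n` points (greedy reduction from
   $\lceil n^{1/d}\rceil$ levels, never below 2 per axis). A request with
   $n < 2^d$ is rejected with the achievable counts named.
2. **Maximin subsample.** If the grid exceeds `n`, points are selected
   greedily: the most distant pair first, then whichever candidate
   maximizes its minimum distance to the selected set (seeded
   tie-breaking).
3. **Boundary modification.** Every coordinate sitting on a bound is
   moved inward by `shrink` × range plus a seeded jitter of at most 1% of
   the range. Interior points carry more information for the surrogate
   than boundary points, and the jitter breaks replicated coordinate
   values, which helps identify the anisotropic correlation lengths.

The grid-then-maximin construction is this package's own resolution of an
underdetermined sampling recipe: only the two target properties —
boundary points moved inward, fewer replicated coordinates — are fixed,
not the algorithm. `shrink` defaults to 0.1 and must be below 0.5 to
preserve coordinate ordering; with `shrink = 0` the grid is returned
unmodified (no jitter either, so the $n=2$ one-dimensional design is
exactly the two endpoints). A statistical test checks the space-filling
property: the MRG design's minimum pairwise distance beats uniform random
sampling in at least 90 of 100 seeded trials.

There is no principled mapping from the published initial sample sizes
(18 for the 3-D geometry spaces, 10 and 5 for the 1-D length spaces) to a
grid structure; the sizes are taken as given inputs.

# The adaptive loop

`ego()` minimizes (maximization negates the evaluator — one code path):

1. Evaluate the MRG design; the iteration starts from its best point,
   whose value serves as $f_0$.
2. Refit the Kriging model from scratch each iteration — with at most a
   few dozen points the refit is cheap, and re-estimated correlation
   lengths adapt as sampling concentrates near the optimum.
3. Maximize Expected Improvement
   $EI(x) = (f_{min}-\hat y)\Phi(u) + s\,\phi(u)$, $u = (f_{min}-\hat y)/s$,
   by 64 seeded L-BFGS-B starts (random starts, the best training points,
   and the winner of a 1024-point seeded space-filling scan). The scan
   guards against all local searches missing the global EI peak, which is
   cheap insurance in $d \le 3$. At $s = 0$ the acquisition degrades to
   $\max(f_{min}-\hat y, 0)$.
4. Evaluate the selected point and test convergence:
   $EI_k/(Y_{max}-Y_{min}) \le \varepsilon_1$ (no promising candidates
   left), $|f_k - \hat y_k| \le \varepsilon_2$ (surrogate locally
   accurate), $|f_k - f_{k-1}| \le \varepsilon_3$ (objective stalled) —
   all three simultaneously. If the sampled responses are all equal the
   EI ratio is defined as 0. A proposal numerically identical to a
   training point is recorded with $EI_k = 0$ (it carries no new
   information), which lets the first criterion fire rather than stall.

Defaults $\varepsilon_1 = \varepsilon_2 = \varepsilon_3 = 10^{-4}$ and
`max_iterations = 50`: the tolerances are not prescribed anywhere
upstream; $10^{-4}$ of a safety margin in MPa or of a dimensionless
dogboning ratio is far below engineering significance for either
objective, and 50 iterations is roughly three times the largest iteration
count the method needed in its published applications (4–17).

**Constraint handling.** The fatigue constraint (no node above the
failure line) enters through `fatigue_objective()`: feasible designs
return $-D^{shortest}$; infeasible ones return the worst feasible
objective seen so far plus `penalty` (default 10) times the violation
depth in MPa. This keeps the surrogate single-output and orders every
infeasible design behind every feasible one. The penalty makes the
objective only continuous (not smooth) across the feasibility boundary;
since the optimum is interior and feasible, the Gaussian-kernel surrogate
tolerates this in practice, and the parameter-recovery test confirms it.

**Bookkeeping.** Every run records, per iteration: the point, $EI_k$,
the prediction $\hat y_k$, the evaluation $f_k$, and the three
convergence flags; runs serialize to JSON (bit-exact reload, using
17-significant-digit output) and CSV. If the evaluator throws, the
partial history is flushed to disk before the error propagates.

# Fatigue layer choices

* **Distance metric.** $D$ is the Euclidean point-to-line distance in raw
  MPa coordinates,
  $D = (1 - \sigma_m/\sigma_{UTS} - \sigma_a/\sigma_N) \big/
  \sqrt{(1/\sigma_{UTS})^2 + (1/\sigma_N)^2}$, signed negative above the
  line. Nothing upstream fixes the coordinate scaling of the diagram, so
  `normalized = TRUE` exposes the alternative metric in
  $(\sigma_m/\sigma_{UTS},\, \sigma_a/\sigma_N)$ coordinates where the
  failure line is $x + y = 1$; raw MPa is the default because safety
  margins are conventionally quoted in stress units.
* **Units.** MPa internally; GPa tables convert on load
  (`goodman_material(..., unit = "GPa")`). The bundled stent steel is
  $\sigma_{UTS} = 580$ MPa, $\sigma_N = 115$ MPa, yield 315 MPa.
* Compressive (negative) mean stress passes through the same formula; the
  margin is monotone decreasing in both $\sigma_m$ and $\sigma_a$.

# Expansion layer choices

* **Recoil and foreshortening** are absolute differences in mm — recoil
  $r(32) - r(42)$ per end, foreshortening $L_0 - L(42)$ — matching the
  mm-denominated comparison tables these metrics are reported in.
  (Relative variants are a one-line division by the user.)
* **Dogboning displacements** are $r(t) - r_0$: radius gained since the
  crimped state.
* The report requires exact 32 ms and 42 ms samples rather than
  interpolating: the metrics are defined at phase boundaries, and a
  history that does not sample them is a data error worth surfacing.
* **Pressure profile**: piecewise-linear trapezoid, 0–25 ms ramp,
  25–32 ms hold, 32–42 ms unload; `pressure_at()` errors outside
  $[0, 42]$ ms.
* **Calibration**: the peak pressure that dilates the stent to its
  nominal radius after unloading depends on balloon length, so
  `calibrate_pressure()` bisects a monotone pressure-to-radius evaluator,
  stopping when the achieved radius is within `tol` (default $10^{-3}$ mm)
  of target; the bracket is checked to straddle the target before any
  iteration.
* The sign convention on the length interval — dogbone ($DR>0$) at the
  upper bound, spindle ($DR<0$) at the lower — resolves a garbled
  upstream statement that typeset both bounds identically; it is the
  physically sensible reading (a longer balloon over-drives the ends) and
  the bundled balloon model follows it.

# Reduced-order stand-ins

The toy models exist so that every pipeline property is testable against
closed-form truth. They are *verification fixtures*, not physics.

**Fatigue model.** With $z \in [0,1]^d$ the scaled geometry, effective
stiffness $s(z) = \prod_i (0.5+z_i)^{1/d}$, and
$r^2 = \|z - z^*\|^2$, the worst node's stresses are
$$\sigma_m = A\,s\,(1+\gamma r^2), \qquad \sigma_a = (B/s)\,(1+\gamma r^2),$$
so stiffer geometry raises the mean stress and lowers the alternating
stress — the monotone trade-off that makes the fatigue optimum interior.
A pure power law in the scalar $s$ alone cannot have a *unique* interior
maximizer in $d>1$ (its level sets are surfaces), hence the shared
quadratic factor: $A$ and $B$ are solved so the Goodman load
$h(s) = \sigma_m/\sigma_{UTS} + \sigma_a/\sigma_N$ at $z^*$ is minimized
exactly at $s^* = s(z^*)$ with margin $D^*$, making $z^*$ a stationary
point, and the positive-definite Hessian of $h(s)(1+\gamma r^2)$ makes it
the unique interior maximum (confirmed by a $30^3$ grid scan in the
tests). Remaining nodes are scaled-down copies, so
$D^{shortest}(x) = (1 - h(s)(1+\gamma r^2))/k$ in closed form.

Defaults pin the model to the published diamond-stent design case: space
$w_1 \in [0.22, 0.34]$, $w_2 \in [0.2, 0.3]$, $t_1 \in [0.1, 0.14]$ mm,
optimum at the reported optimal geometry $(0.2685, 0.2128, 0.1047)$ mm,
and $D^* = 39.12$ MPa (the reported original stress pair's 31.96 MPa
margin scaled by the reported 22.39% improvement). $\gamma = 0.5$ keeps
the corner regions infeasible enough to exercise the penalty path while
leaving the optimum comfortably interior. These are stated-world choices
made once, not tuned quantities — the recovery test asks only that the
optimizer find the constructed optimum, wherever it was constructed.

**Balloon model.** Displacements follow the pressure profile with an
accelerating ramp $\psi(t) = (t/25)^2$, a plateau, and an exponential
recoil settling within ~2 ms of unloading. The distal gain is
$1 + \delta(L)$ with $\delta(L)$ linear in $L$ and zero at $L^*$, so
$DR(32\,\mathrm{ms}) = \delta(L)$ exactly: strictly increasing, one sign
change, negative/positive at the interval ends. Radius after unloading is
linear in peak pressure, hence strictly monotone and bisectable. Defaults
reproduce the published diamond-stent deployment numbers at the original
5.1 mm length — peak dogboning 0.0884, recoils 0.0205/0.0220 mm,
foreshortening 0.2149 mm — with $L^* = 4.959$ mm, the reported optimal
length.

**What the toys do not emulate:** contact mechanics, plasticity,
balloon pleating/folding, vessel/plaque interaction, mesh-dependent
stress concentrations, or any noise. A green parameter-recovery test
therefore establishes that the *optimizer* finds constructed optima of
smooth-but-realistic response shapes within stated budgets — it says
nothing about FEM fidelity, which is explicitly out of scope.

**Analytic registry.** `standard_test_functions()` adds a 1-D quadratic,
the multimodal 1-D Forrester function and the 2-D Branin function with
stored optima (grid-verified in the tests) for optimizer validation.

# Degenerate inputs and edge cases

* Degenerate bounds (`lower >= upper`), duplicate variable names and
  dimension mismatches are rejected at construction.
* Constant training responses: the surrogate predicts the constant
  everywhere; EI then peaks at the maximum-variance point, so the loop
  still explores.
* Zero response range makes the EI convergence ratio 0 by convention.
* Out-of-bounds prediction warns and flags extrapolation instead of
  failing — useful when inspecting a fitted surrogate, harmless inside
  the loop, which never proposes outside the box.
* `max_iterations = 0` returns the best initial sample with status
  `budget_exhausted`; infinite tolerances stop after exactly one adaptive
  iteration.

# Known limitations

* Single-output, noise-free surrogate: no batch/parallel EI, no
  observation noise, no multi-objective Pareto search.
* The penalized constraint treatment assumes the feasible region contains
  the optimum with margin; tightly active constraints would warrant an
  explicit constrained-EI acquisition.
* EI maximization budgets (64 starts + 1024 scan) are tuned for
  $d \le 3$; higher-dimensional spaces would need scaling.
* Published iteration counts of the original FEM-driven studies are not
  reproducible here, since they depend on proprietary FEM evaluators and
  unreported tolerances; the package reproduces the method, the printed
  comparison arithmetic, and recovery of constructed optima.
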