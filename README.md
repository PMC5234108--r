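# stentopt

Adaptive Kriging-surrogate design optimization for balloon-expandable
coronary stents and their dilatation balloons.

## The problem

A stent's geometry controls two things its designers care about most:

* **Fatigue life.** After deployment the stent endures pulsatile arterial
  loading — on the order of 4×10⁸ cycles over a ten-year service life.
  Each node of the structure sees a systolic/diastolic stress cycle,
  summarized by the mean stress σ_m = (σ_sys + σ_dia)/2 and the
  alternating stress σ_a = |σ_sys − σ_dia|/2. On the Goodman diagram the
  failure line

      σ_a/σ_N + σ_m/σ_UTS = 1

  (σ_N endurance limit, σ_UTS ultimate tensile strength) separates safe
  from failure-prone states; a design's safety margin is D_shortest, the
  shortest Euclidean distance from any node's (σ_m, σ_a) point to that
  line. Fatigue optimization maximizes D_shortest over the strut widths
  and thickness, subject to every node staying below the line.

* **Expansion quality.** A mismatched balloon length makes the stent's
  distal ends flare ahead of its center (dogboning, DR > 0) or lag behind
  it (spindling, DR < 0), injuring the vessel wall and promoting
  restenosis. With radial displacements d = r(t) − r0,

      DR = (d_distal − d_proximal) / d_proximal,

  evaluated at peak expansion (32 ms of the 0–25–32–42 ms trapezoidal
  inflation profile). Balloon-length optimization minimizes |DR(32 ms)|.
  Radial elastic recoil r(32) − r(42) per end and foreshortening
  L0 − L(42) are reported alongside.

Both objectives are expensive black boxes (each evaluation is a nonlinear
finite-element simulation), so the package searches them through an
**ordinary-Kriging surrogate refined by Expected Improvement** (the EGO
strategy): a modified-rectangular-grid (MRG) initial design, a Gaussian
anisotropic correlation fitted by concentrated maximum likelihood, and at
each iteration one new evaluation at the EI maximizer

    EI(x) = (f_min − ŷ(x)) Φ(u) + s(x) φ(u),   u = (f_min − ŷ(x))/s(x),

until the three-part convergence test holds:

    EI_k/(Y_max − Y_min) ≤ ε₁,   |f_k − ŷ_k| ≤ ε₂,   |f_k − f_{k−1}| ≤ ε₃.

Closed-form reduced-order models (`toy_fatigue_model()`,
`toy_balloon_model()`) stand in for the FEM so the whole pipeline runs in
seconds and every numerical claim is testable; any user evaluator — an R
function or a CSV table of precomputed FEM results — plugs into the same
`ego()` loop.

## Worked example

```r
library(stentopt)

# safety margin of one strut hot-spot on the Goodman diagram
material <- stent_steel_304()            # sigma_UTS 580 MPa, sigma_N 115 MPa
goodman_margin(304.6, 22.02, material)
#>   distance safe
#> 1 31.96294 TRUE

# fatigue-life optimization of the bundled diamond-stent stress model:
# maximize D_shortest over strut widths w1, w2 and thickness t1 (mm)
tm  <- toy_fatigue_model()
obj <- fatigue_objective(function(x) toy_fatigue_evaluate(tm, x), material)
run <- ego(obj, tm$space, n_init = 18,
           criteria = convergence_criteria(eps1 = 1e-6, max_iterations = 25),
           seed = 42)
run
#> Adaptive Kriging optimization (minimization)
#>   18 initial + 25 adaptive evaluations, status: budget_exhausted
#>   best point: w1 = 0.265814, w2 = 0.212708, t1 = 0.105094
#>   best value: -39.0975
```

The objective is −D_shortest, so the best design found carries a
39.10 MPa shortest safety distance — against the model's constructed
optimum of 39.12 MPa at (0.2685, 0.2128, 0.1047) mm.

```r
# expansion performance of a 5.1 mm balloon on the bundled expansion model
tb <- toy_balloon_model()
expansion_report(toy_balloon_evaluate(tb, 5.1))
#> Expansion performance report
#>   dogboning ratio    32 ms: 0.088407   42 ms: 0.0887405
#>   radial recoil   proximal: 0.0204819 mm  distal: 0.0219727 mm
#>   foreshortening: 0.214949 mm

# peak pressure that dilates the stent to the 2.2 mm nominal vessel radius
p <- calibrate_pressure(toy_balloon_radius_fn(tb, 4.959), 2.2, c(0.2, 3),
                        tol = 1e-4)
#> calibrated pressure: 1.1632 MPa in 14 evaluations
```

A 0.088 dogboning ratio means the distal ends over-expand by ~9% at peak
inflation; re-running `ego()` with `dogboning_objective()` over the
4.6–5.1 mm length interval drives it below 1e-4 (see
`scripts/acceptance.R`).

## Command line

A thin CLI wraps the same functions (`inst/cli/stentopt` after install):

```sh
stentopt sample             --config cfg.json --out points.csv
stentopt optimize           --config cfg.json --seed 1 --out run.json
stentopt fatigue-eval       --stress nodes.csv
stentopt expansion-report   --history history.csv
stentopt calibrate-pressure --target 2.2 --bracket 0.2,3
```

Configs are JSON (design-space bounds, `n_init`, convergence tolerances,
seed, evaluator choice); see `?load_run_config`.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch against the
installed package — the fatigue-geometry search, the balloon-length
search, the bisection pressure calibration and the deployment comparison
— under a single seed, and writes its JSON result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

The methods vignette (`vignettes/stent-kriging-optimization.Rmd`) documents
the model assumptions, every tunable parameter with its default and units,
what the reduced-order models do and do not emulate, and the numerical
choices (nugget escalation, multistart budgets, tie-breaking, degenerate
inputs).
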