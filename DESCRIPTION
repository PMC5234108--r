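Package: stentopt
Title: Adaptive Kriging Surrogate Optimization of Stent Geometry and
    Dilatation Balloon Length
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Surrogate-based design optimization for balloon-expandable
    coronary stents. Fits ordinary Kriging (Gaussian-process) surrogates to
    expensive black-box evaluations, refines them adaptively with the
    Expected Improvement acquisition under a three-part convergence test,
    and provides the two domain objective layers: Goodman-diagram fatigue
    safety distance (mean/alternating stress decomposition, shortest
    distance to the failure line) and balloon-expansion performance metrics
    (dogboning ratio, radial elastic recoil, foreshortening, trapezoidal
    inflation pressure profile, bisection pressure calibration). Bundled
    closed-form reduced-order models stand in for finite-element evaluators
    so the full pipeline is testable on a laptop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
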