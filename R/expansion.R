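#' Trapezoidal balloon inflation pressure profile
#'
#' Time-varying pressure applied to the balloon's inner surface in three
#' phases: linear loading from 0 to `p_max` over `[0, t_ramp_end]`,
#' constant `p_max` over `[t_ramp_end, t_hold_end]`, linear unloading back
#' to 0 over `[t_hold_end, t_unload_end]`. Defaults: 0-25 ms loading,
#' 25-32 ms hold, 32-42 ms unloading.
#'
#' @param p_max Peak pressure, MPa.
#' @param t_ramp_end,t_hold_end,t_unload_end Phase boundaries, ms.
#' @return An object of class `"pressure_profile"`.
#' @export
pressure_profile <- function(p_max, t_ramp_end = 25, t_hold_end = 32,
                             t_unload_end = 42) {
  stopifnot(is.finite(p_max), p_max > 0,
            0 < t_ramp_end, t_ramp_end < t_hold_end, t_hold_end < t_unload_end)
  structure(list(p_max = p_max, t_ramp_end = t_ramp_end,
                 t_hold_end = t_hold_end, t_unload_end = t_unload_end),
            class = "pressure_profile")
}

#' @export
print.pressure_profile <- function(x, ...) {
  cat(sprintf(paste0("Pressure profile: 0-%g ms ramp to %g MPa, hold to ",
                     "%g ms, unload to %g ms\n"),
              x$t_ramp_end, x$p_max, x$t_hold_end, x$t_unload_end))
  invisible(x)
}

#' Evaluate the pressure profile
#'
#' Piecewise-linear and continuous; errors outside `[0, t_unload_end]`.
#'
#' @param profile A [pressure_profile()].
#' @param t Time(s), ms. Vectorized.
#' @return Pressure(s), MPa.
#' @examples
#' p <- pressure_profile(1.2)
#' pressure_at(p, c(0, 28, 37))  # 0, 1.2, 0.6
#' @export
pressure_at <- function(profile, t) {
  stopifnot(inherits(profile, "pressure_profile"))
  if (any(t < 0 | t > profile$t_unload_end))
    stop(sprintf("time must be within [0, %g] ms", profile$t_unload_end))
  with(profile, {
    out <- numeric(length(t))
    ramp <- t <= t_ramp_end
    hold <- t > t_ramp_end & t <= t_hold_end
    unld <- t > t_hold_end
    out[ramp] <- p_max * t[ramp] / t_ramp_end
    out[hold] <- p_max
    out[unld] <- p_max * (t_unload_end - t[unld]) / (t_unload_end - t_hold_end)
    out
  })
}

#' Dogboning ratio
#'
#' Non-uniformity of stent expansion along its length:
#' \deqn{DR = (d^{distal}_{radial} - d^{proximal}_{radial}) /
#'       d^{proximal}_{radial}.}
#' Positive: the distal ends flare first (dogbone shape, struts pushed
#' into the vessel wall). Negative: the distal ends lag (spindle shape,
#' struts squeezed inward). Zero: uniform expansion.
#'
#' @param d_distal,d_proximal Distal / proximal radial displacements, mm.
#' @return The (dimensionless) ratio.
#' @examples
#' dogboning(1.2, 1.0)  # 0.2: dogbone
#' dogboning(0.8, 1.0)  # -0.2: spindle
#' @export
dogboning <- function(d_distal, d_proximal) {
  stopifnot(is.finite(d_distal), is.finite(d_proximal))
  if (d_proximal == 0)
    stop("dogboning ratio is undefined for zero proximal displacement")
  (d_distal - d_proximal) / d_proximal
}

#' Stent expansion history
#'
#' Time series of the stent's proximal and distal outer radius and its
#' length under the inflation pressure profile, plus the initial (crimped)
#' radius `r0` and length `L0`. Samples at 32 ms (peak expansion) and
#' 42 ms (after balloon deflation) are required by [expansion_report()].
#'
#' @param times Strictly increasing times, ms.
#' @param r_proximal,r_distal Radius time series, mm (positive).
#' @param length Stent length time series, mm (positive).
#' @param r0 Initial radius, mm.
#' @param L0 Initial length, mm.
#' @return An object of class `"expansion_history"`.
#' @export
expansion_history <- function(times, r_proximal, r_distal, length, r0, L0) {
  n <- base::length(times)
  stopifnot(n >= 2L, all(diff(times) > 0),
            base::length(r_proximal) == n, base::length(r_distal) == n,
            base::length(length) == n,
            all(r_proximal > 0), all(r_distal > 0), all(length > 0),
            is.finite(r0), r0 > 0, is.finite(L0), L0 > 0)
  structure(list(times = as.numeric(times),
                 r_proximal = as.numeric(r_proximal),
                 r_distal = as.numeric(r_distal),
                 length = as.numeric(length),
                 r0 = r0, L0 = L0),
            class = "expansion_history")
}

#' @export
print.expansion_history <- function(x, ...) {
  cat(sprintf(paste0("Expansion history: %d samples over [%g, %g] ms, ",
                     "r0 = %g mm, L0 = %g mm\n"),
              length(x$times), min(x$times), max(x$times), x$r0, x$L0))
  invisible(x)
}

history_at <- function(h, t, what) {
  i <- which(abs(h$times - t) < 1e-9)
  if (!length(i))
    stop(sprintf("expansion history has no sample at t = %g ms", t))
  h[[what]][i[1L]]
}

#' Expansion performance report
#'
#' Computes the comparison metrics of a deployment from its history:
#' dogboning ratio at 32 ms (peak expansion — when transient vessel
#' injury is largest) and at 42 ms (after deflation), radial elastic
#' recoil per end `r(32) - r(42)` in mm, and foreshortening
#' `L0 - length(42)` in mm. Radial displacements for the dogboning ratio
#' are `r(t) - r0`.
#'
#' @param history An [expansion_history()] (must sample 32 and 42 ms).
#' @return An object of class `"expansion_report"`: list with
#'   `dogboning_32`, `dogboning_42`, `recoil_proximal`, `recoil_distal`,
#'   `foreshortening`.
#' @export
expansion_report <- function(history) {
  stopifnot(inherits(history, "expansion_history"))
  h <- history
  rp32 <- history_at(h, 32, "r_proximal"); rp42 <- history_at(h, 42, "r_proximal")
  rd32 <- history_at(h, 32, "r_distal");   rd42 <- history_at(h, 42, "r_distal")
  L42 <- history_at(h, 42, "length")
  structure(list(
    dogboning_32 = dogboning(rd32 - h$r0, rp32 - h$r0),
    dogboning_42 = dogboning(rd42 - h$r0, rp42 - h$r0),
    recoil_proximal = rp32 - rp42,
    recoil_distal = rd32 - rd42,
    foreshortening = h$L0 - L42),
    class = "expansion_report")
}

#' @export
print.expansion_report <- function(x, ...) {
  cat("Expansion performance report\n")
  cat(sprintf("  dogboning ratio    32 ms: %.6g   42 ms: %.6g\n",
              x$dogboning_32, x$dogboning_42))
  cat(sprintf("  radial recoil   proximal: %.6g mm  distal: %.6g mm\n",
              x$recoil_proximal, x$recoil_distal))
  cat(sprintf("  foreshortening: %.6g mm\n", x$foreshortening))
  invisible(x)
}

#' @export
as.data.frame.expansion_report <- function(x, ...) {
  as.data.frame(unclass(x))
}

#' Relative reduction between an original and an optimized metric
#'
#' `100 * (1 - optimal/original)` percent — positive when the optimized
#' deployment improves (reduces) the metric.
#'
#' @param original,optimal Metric values (same units); `original != 0`.
#' @return Percent reduction.
#' @examples
#' relative_reduction(0.0868, 0.0016)  # 98.16: dogboning nearly eliminated
#' @export
relative_reduction <- function(original, optimal) {
  stopifnot(is.finite(original), is.finite(optimal))
  if (original == 0) stop("relative reduction is undefined for a zero original")
  100 * (1 - optimal / original)
}

#' Calibrate the peak inflation pressure by bisection
#'
#' The pressure needed to dilate a stent to its nominal diameter after
#' balloon unloading depends on balloon length, so it is recalibrated per
#' design by binary search on a monotone evaluator.
#'
#' @param radius_evaluator Function: peak pressure (MPa) -> stent radius
#'   after unloading (mm); must be nondecreasing on the bracket.
#' @param target_radius Target radius, mm.
#' @param bracket `c(p_lo, p_hi)` MPa; `radius(p_lo) <= target <=
#'   radius(p_hi)` is checked before iterating.
#' @param tol Radius tolerance, mm (default 1e-3).
#' @param max_evals Evaluation budget (default 60).
#' @return The calibrated pressure, MPa, with attributes `radius` (the
#'   achieved radius) and `evaluations` (evaluator calls used).
#' @examples
#' calibrate_pressure(function(p) 2 * p, 3, c(0, 10))  # 1.5
#' @export
calibrate_pressure <- function(radius_evaluator, target_radius, bracket,
                               tol = 1e-3, max_evals = 60L) {
  stopifnot(is.function(radius_evaluator), length(bracket) == 2L,
            bracket[1L] < bracket[2L], tol > 0)
  p_lo <- bracket[1L]; p_hi <- bracket[2L]
  r_lo <- radius_evaluator(p_lo); r_hi <- radius_evaluator(p_hi)
  evals <- 2L
  if (target_radius < r_lo - tol || target_radius > r_hi + tol)
    stop(sprintf(paste0("bracket does not straddle the target: radius(%g) = ",
                        "%g, radius(%g) = %g, target %g"),
                 p_lo, r_lo, p_hi, r_hi, target_radius))
  if (abs(r_lo - target_radius) <= tol)
    return(structure(p_lo, radius = r_lo, evaluations = evals))
  if (abs(r_hi - target_radius) <= tol)
    return(structure(p_hi, radius = r_hi, evaluations = evals))
  repeat {
    p_mid <- (p_lo + p_hi) / 2
    r_mid <- radius_evaluator(p_mid)
    evals <- evals + 1L
    if (abs(r_mid - target_radius) <= tol)
      return(structure(p_mid, radius = r_mid, evaluations = evals))
    if (evals >= max_evals)
      stop(sprintf("pressure calibration did not reach tol = %g in %d evaluations",
                   tol, max_evals))
    if (r_mid < target_radius) p_lo <- p_mid else p_hi <- p_mid
  }
}

#' Build the dogboning objective for the balloon-length search
#'
#' Wraps an expansion evaluator (balloon length -> expansion history) into
#' the scalar objective \eqn{f(L) = |DR(32\,ms)|}, the absolute dogboning
#' ratio at peak expansion, for minimization by [ego()].
#'
#' @param history_evaluator Function: named design point (balloon length,
#'   mm) -> [expansion_history()].
#' @return A function: design point -> nonnegative objective.
#' @export
dogboning_objective <- function(history_evaluator) {
  stopifnot(is.function(history_evaluator))
  function(L) {
    rep <- expansion_report(history_evaluator(L))
    abs(rep$dogboning_32)
  }
}

#' Write / read an expansion history as CSV
#'
#' Columns `time_ms`, `r_proximal_mm`, `r_distal_mm`, `length_mm`; the
#' initial radius and length ride along as a leading comment-style
#' metadata line `# r0=<mm>,L0=<mm>`.
#'
#' @param history An [expansion_history()].
#' @param path File path.
#' @return `path` invisibly / the reloaded [expansion_history()].
#' @export
write_history_csv <- function(history, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# r0=%.12g,L0=%.12g", history$r0, history$L0), con)
  utils::write.csv(data.frame(time_ms = history$times,
                              r_proximal_mm = history$r_proximal,
                              r_distal_mm = history$r_distal,
                              length_mm = history$length),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_history_csv
#' @export
read_history_csv <- function(path) {
  meta <- readLines(path, n = 1L)
  if (!grepl("^# *r0=", meta))
    stop("expansion-history CSV is missing the '# r0=...,L0=...' metadata line")
  r0 <- as.numeric(sub("^.*r0=([0-9.eE+-]+).*$", "\\1", meta))
  L0 <- as.numeric(sub("^.*L0=([0-9.eE+-]+).*$", "\\1", meta))
  df <- utils::read.csv(path, comment.char = "#")
  expansion_history(df$time_ms, df$r_proximal_mm, df$r_distal_mm,
                    df$length_mm, r0 = r0, L0 = L0)
}
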