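#' Reduced-order stent fatigue stress-field model
#'
#' Deterministic closed-form stand-in for a finite-element fatigue
#' evaluation, built so the full optimization pipeline can be exercised
#' and verified without FEM. The model reproduces the stiffness-stress
#' trade-off of real strut geometry: thinner/narrower struts lower the
#' radial stiffness, which raises the alternating stress under pulsatile
#' loading and lowers the mean stress — so the shortest Goodman safety
#' distance has an interior optimum.
#'
#' Construction: design coordinates are scaled to \eqn{z \in [0,1]^d};
#' the effective stiffness is the geometric mean
#' \eqn{s(z) = \prod_i (0.5 + z_i)^{1/d}}. The worst node's stresses are
#' \deqn{\sigma_m = A\,s\,(1 + \gamma\|z - z^*\|^2), \qquad
#'       \sigma_a = (B/s)\,(1 + \gamma\|z - z^*\|^2),}
#' with \eqn{A, B} solved so that the Goodman load
#' \eqn{h(s) = \sigma_m/\sigma_{UTS} + \sigma_a/\sigma_N} (at \eqn{z^*})
#' is minimized exactly at \eqn{s^* = s(z^*)} with margin \eqn{D^*}:
#' \eqn{A = \sigma_{UTS} h^*/(2s^*)}, \eqn{B = \sigma_N h^* s^*/2},
#' \eqn{h^* = 1 - D^* \sqrt{(1/\sigma_{UTS})^2 + (1/\sigma_N)^2}}. The
#' shared quadratic factor makes \eqn{x^*} the unique interior maximizer
#' of the shortest distance (the gradient vanishes there because
#' \eqn{h'(s^*) = 0}, and the Hessian of \eqn{h(s)(1+\gamma r^2)} is
#' positive definite), while \eqn{\sigma_m} stays strictly increasing and
#' \eqn{\sigma_a} strictly decreasing in the stiffness \eqn{s} at any
#' fixed offset from \eqn{x^*}. Additional nodes are scaled-down copies of
#' the worst node, so the shortest distance is available in closed form.
#'
#' Defaults are the diamond-shaped stent's design space (strut widths
#' w1 in \[0.22, 0.34\] mm, w2 in \[0.2, 0.3\] mm, thickness t1 in
#' \[0.1, 0.14\] mm), the published optimal geometry
#' (0.2685, 0.2128, 0.1047) mm as the constructed optimum, an optimal
#' margin of 39.12 MPa, and stainless-steel-304 fatigue constants.
#'
#' @param space Design space (default: the diamond-stent geometry space).
#' @param x_star Constructed optimum, native units (interior point).
#' @param D_star Shortest safety distance at the optimum, MPa (> 0).
#' @param gamma Curvature of the off-optimum stress inflation (>= 0).
#' @param n_nodes Number of stress nodes returned per evaluation.
#' @param material A [goodman_material()].
#' @return An object of class `"toy_fatigue_model"` with a closed-form
#'   `x_star`/`D_star` and all construction constants.
#' @seealso [toy_fatigue_evaluate()], [fatigue_objective()]
#' @export
toy_fatigue_model <- function(space = design_space(w1 = c(0.22, 0.34),
                                                   w2 = c(0.2, 0.3),
                                                   t1 = c(0.1, 0.14)),
                              x_star = c(0.2685, 0.2128, 0.1047),
                              D_star = 39.12,
                              gamma = 0.5,
                              n_nodes = 25L,
                              material = stent_steel_304()) {
  assert_space(space)
  z_star <- drop(scale01(space, matrix(x_star, nrow = 1L)))
  if (any(z_star <= 0 | z_star >= 1))
    stop("'x_star' must lie strictly inside the design space")
  stopifnot(D_star > 0, gamma >= 0, n_nodes >= 1L)
  k <- sqrt(1 / material$sigma_UTS^2 + 1 / material$sigma_N^2)
  h_star <- 1 - D_star * k
  if (h_star <= 0) stop("'D_star' exceeds the distance of the origin to the line")
  s_star <- stiffness_s(z_star)
  structure(list(space = space, x_star = stats::setNames(x_star, space$names),
                 z_star = z_star, D_star = D_star, gamma = gamma,
                 n_nodes = as.integer(n_nodes), material = material,
                 A = material$sigma_UTS * h_star / (2 * s_star),
                 B = material$sigma_N * h_star * s_star / 2,
                 s_star = s_star, h_star = h_star),
            class = "toy_fatigue_model")
}

## effective radial stiffness: geometric mean of shifted unit coordinates
stiffness_s <- function(z) prod(0.5 + z)^(1 / length(z))

#' Evaluate the toy fatigue model
#'
#' @param model A [toy_fatigue_model()].
#' @param x Design point, native units (mm), inside the model's space.
#' @return A `stress_point_set` of `n_nodes` (mean, alternating) stress
#'   pairs, MPa; node 1 is always the worst node, whose margin equals the
#'   model's closed-form shortest distance at `x`.
#' @export
toy_fatigue_evaluate <- function(model, x) {
  stopifnot(inherits(model, "toy_fatigue_model"))
  x <- design_point(model$space, x)
  z <- drop(scale01(model$space, matrix(x, nrow = 1L)))
  s <- stiffness_s(z)
  infl <- 1 + model$gamma * sum((z - model$z_star)^2)
  sm <- model$A * s * infl
  sa <- model$B / s * infl
  cj <- if (model$n_nodes > 1L)
    1 - 0.5 * (seq_len(model$n_nodes) - 1L) / (model$n_nodes - 1L)
  else 1
  stress_points(sigma_m = sm * cj, sigma_a = sa * cj^0.9)
}

#' Closed-form shortest safety distance of the toy fatigue model
#'
#' Available analytically because node 1 dominates:
#' \eqn{D(x) = (1 - h(s)(1+\gamma r^2))/k} with
#' \eqn{h(s) = (A/\sigma_{UTS})s + (B/\sigma_N)/s}.
#'
#' @param model A [toy_fatigue_model()].
#' @param x Design point, native units.
#' @return The shortest distance, MPa (negative if infeasible).
#' @export
toy_fatigue_distance <- function(model, x) {
  x <- design_point(model$space, x)
  z <- drop(scale01(model$space, matrix(x, nrow = 1L)))
  s <- stiffness_s(z)
  h <- model$A / model$material$sigma_UTS * s +
       model$B / model$material$sigma_N / s
  k <- sqrt(1 / model$material$sigma_UTS^2 + 1 / model$material$sigma_N^2)
  (1 - h * (1 + model$gamma * sum((z - model$z_star)^2))) / k
}

#' @export
print.toy_fatigue_model <- function(x, ...) {
  cat("Reduced-order stent fatigue model\n")
  cat("  space     :", format(x$space), "\n")
  cat("  optimum   :", paste(sprintf("%s = %.6g", names(x$x_star), x$x_star),
                             collapse = ", "), "\n")
  cat(sprintf("  margin at optimum: %.4g MPa; gamma = %g; %d nodes\n",
              x$D_star, x$gamma, x$n_nodes))
  invisible(x)
}

#' Reduced-order balloon expansion model
#'
#' Deterministic closed-form stand-in for a finite-element stent-balloon
#' expansion simulation, driven by the trapezoidal [pressure_profile()].
#' Radial displacement ramps up with the square of time during loading
#' (expansion accelerates as the balloon pressurizes), plateaus during the
#' hold, and recoils elastically within ~2 ms of unloading onset. The
#' distal ends see a length-dependent gain: the dogboning ratio at peak
#' expansion (32 ms) is linear in balloon length L, negative at the lower
#' bound (spindle), positive at the upper bound (dogbone) and exactly zero
#' at `L_star`. Radius after unloading is strictly increasing in the peak
#' pressure, so the model is bisection-calibratable.
#'
#' Defaults describe the diamond-shaped stent deployment: L in
#' \[4.6, 5.1\] mm, zero-dogboning length 4.959 mm (the published optimal
#' balloon length), crimped radius 1.27 mm (2.54 mm outer diameter),
#' stent length 8.68 mm, nominal expanded radius 2.25 mm (healthy-vessel
#' radius) at the 1.2 MPa reference pressure, dogboning slope fitted so
#' the original 5.1 mm balloon gives the published 0.0884 peak dogboning,
#' recoil fractions matched to the published 0.0205/0.0220 mm recoils and
#' foreshortening coefficient to the published 0.2149 mm.
#'
#' @param space 1-D design space for the balloon length, mm.
#' @param L_star Zero-dogboning balloon length, mm (inside the space).
#' @param r0 Initial (crimped) stent radius, mm.
#' @param L0 Initial stent length, mm.
#' @param p_ref Reference peak pressure, MPa.
#' @param d_ref Proximal radial displacement at peak expansion under
#'   `p_ref`, mm.
#' @param dog_slope Dogboning change per unit of `(L - L_star)/range`.
#' @param rho_proximal,rho_distal Elastic recoil fractions of the peak
#'   displacement, per end.
#' @param fs_coef Foreshortening per mm of mean radial displacement.
#' @param profile_times Phase boundaries `c(t_ramp_end, t_hold_end,
#'   t_unload_end)`, ms.
#' @return An object of class `"toy_balloon_model"`.
#' @seealso [toy_balloon_evaluate()], [dogboning_objective()],
#'   [calibrate_pressure()]
#' @export
toy_balloon_model <- function(space = design_space(L = c(4.6, 5.1)),
                              L_star = 4.959,
                              r0 = 1.27, L0 = 8.68,
                              p_ref = 1.2, d_ref = 0.98,
                              dog_slope = 0.3135,
                              rho_proximal = 0.0209,
                              rho_distal = 0.0206,
                              fs_coef = 0.2145,
                              profile_times = c(25, 32, 42)) {
  assert_space(space)
  if (space$dim != 1L) stop("the balloon model's design space is 1-D (length L)")
  if (L_star <= space$lower || L_star >= space$upper)
    stop("'L_star' must lie strictly inside the length interval")
  stopifnot(r0 > 0, L0 > 0, p_ref > 0, d_ref > 0, dog_slope > 0,
            rho_proximal > 0, rho_proximal < 1,
            rho_distal > 0, rho_distal < 1, fs_coef >= 0)
  structure(list(space = space, L_star = L_star, r0 = r0, L0 = L0,
                 p_ref = p_ref, d_ref = d_ref, dog_slope = dog_slope,
                 rho_proximal = rho_proximal, rho_distal = rho_distal,
                 fs_coef = fs_coef, profile_times = profile_times),
            class = "toy_balloon_model")
}

#' Evaluate the toy balloon model
#'
#' @param model A [toy_balloon_model()].
#' @param L Balloon length, mm, inside the model's interval (a named
#'   design point or bare number).
#' @param p_max Peak inflation pressure, MPa (default: the model's
#'   reference pressure).
#' @param dt Sampling step, ms (default 1; the history always samples the
#'   phase boundaries exactly).
#' @return An [expansion_history()] over `[0, t_unload_end]` ms.
#' @export
toy_balloon_evaluate <- function(model, L, p_max = model$p_ref, dt = 1) {
  stopifnot(inherits(model, "toy_balloon_model"), p_max > 0, dt > 0, dt <= 1)
  L <- unname(design_point(model$space, L))
  tb <- model$profile_times
  times <- sort(unique(c(seq(0, tb[3L], by = dt), tb)))

  width <- model$space$upper - model$space$lower
  delta <- model$dog_slope * (L - model$L_star) / width   # = DR at 32 ms
  d_prox_peak <- model$d_ref * p_max / model$p_ref
  d_dist_peak <- d_prox_peak * (1 + delta)

  ramp <- function(t) ifelse(t <= tb[1L], (t / tb[1L])^2, 1)
  recoil <- function(t, rho)
    ifelse(t <= tb[2L], 1, 1 - rho * (1 - exp(-(t - tb[2L]) / 0.8)))

  d_prox <- d_prox_peak * ramp(times) * recoil(times, model$rho_proximal)
  d_dist <- d_dist_peak * ramp(times) * recoil(times, model$rho_distal)
  len <- model$L0 - model$fs_coef * (d_prox + d_dist) / 2

  expansion_history(times = times,
                    r_proximal = model$r0 + d_prox,
                    r_distal = model$r0 + d_dist,
                    length = len,
                    r0 = model$r0, L0 = model$L0)
}

#' Radius after balloon unloading, as a function of peak pressure
#'
#' Convenience closure for [calibrate_pressure()]: proximal stent radius
#' at the end of unloading (42 ms) under the given peak pressure.
#'
#' @param model A [toy_balloon_model()].
#' @param L Balloon length, mm.
#' @return A function: pressure (MPa) -> radius (mm), strictly increasing.
#' @export
toy_balloon_radius_fn <- function(model, L) {
  function(p) {
    h <- toy_balloon_evaluate(model, L, p_max = p)
    history_at(h, model$profile_times[3L], "r_proximal")
  }
}

#' @export
print.toy_balloon_model <- function(x, ...) {
  cat("Reduced-order balloon expansion model\n")
  cat(sprintf("  L in [%g, %g] mm, zero-dogboning length L* = %g mm\n",
              x$space$lower, x$space$upper, x$L_star))
  cat(sprintf("  r0 = %g mm, L0 = %g mm, reference pressure %g MPa\n",
              x$r0, x$L0, x$p_ref))
  invisible(x)
}

#' Serialize toy model parameters to JSON (and reload them)
#'
#' Lets tests and configs pin an exact model construction.
#' @param model A `toy_fatigue_model` or `toy_balloon_model`.
#' @param path File path.
#' @return `path` invisibly; `read_toy_model_json` returns the rebuilt
#'   model.
#' @export
write_toy_model_json <- function(model, path) {
  if (inherits(model, "toy_fatigue_model")) {
    obj <- list(type = "toy_fatigue",
                space = list(name = model$space$names,
                             lower = model$space$lower,
                             upper = model$space$upper),
                x_star = unname(model$x_star), D_star = model$D_star,
                gamma = model$gamma, n_nodes = model$n_nodes,
                material = list(sigma_N = model$material$sigma_N,
                                sigma_UTS = model$material$sigma_UTS))
  } else if (inherits(model, "toy_balloon_model")) {
    obj <- list(type = "toy_balloon",
                space = list(name = model$space$names,
                             lower = model$space$lower,
                             upper = model$space$upper),
                L_star = model$L_star, r0 = model$r0, L0 = model$L0,
                p_ref = model$p_ref, d_ref = model$d_ref,
                dog_slope = model$dog_slope,
                rho_proximal = model$rho_proximal,
                rho_distal = model$rho_distal, fs_coef = model$fs_coef,
                profile_times = model$profile_times)
  } else stop("not a toy model")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_toy_model_json
#' @export
read_toy_model_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- design_space(data.frame(name = o$space$name, lower = o$space$lower,
                                upper = o$space$upper))
  if (identical(o$type, "toy_fatigue")) {
    toy_fatigue_model(space = sp, x_star = o$x_star, D_star = o$D_star,
                      gamma = o$gamma, n_nodes = o$n_nodes,
                      material = goodman_material(o$material$sigma_N,
                                                  o$material$sigma_UTS))
  } else if (identical(o$type, "toy_balloon")) {
    toy_balloon_model(space = sp, L_star = o$L_star, r0 = o$r0, L0 = o$L0,
                      p_ref = o$p_ref, d_ref = o$d_ref,
                      dog_slope = o$dog_slope,
                      rho_proximal = o$rho_proximal,
                      rho_distal = o$rho_distal, fs_coef = o$fs_coef,
                      profile_times = o$profile_times)
  } else stop("unknown toy model type: ", o$type)
}

#' Registry of analytic test objectives with known minima
#'
#' Standard closed-form functions for validating the adaptive optimizer:
#' a 1-D quadratic, the 1-D multimodal Forrester function and the 2-D
#' Branin function, each with its design space and known (argmin, min).
#'
#' @param name Function name; omit for the full registry.
#' @return With `name`: a list with `fn` (taking a named design point),
#'   `space`, `argmin` (matrix, one row per global minimizer) and `fmin`.
#'   Without: the named registry list.
#' @examples
#' tf <- standard_test_functions("branin")
#' tf$fmin  # 0.397887...
#' @export
standard_test_functions <- function(name = NULL) {
  registry <- list(
    quadratic1d = list(
      fn = function(p) (p[[1L]] - 0.3)^2,
      space = design_space(x = c(0, 1)),
      argmin = matrix(0.3, 1, 1), fmin = 0),
    forrester1d = list(
      fn = function(p) (6 * p[[1L]] - 2)^2 * sin(12 * p[[1L]] - 4),
      space = design_space(x = c(0, 1)),
      argmin = matrix(0.7572488, 1, 1), fmin = -6.0207401),
    branin = list(
      fn = function(p) {
        x1 <- p[[1L]]; x2 <- p[[2L]]
        a <- 1; b <- 5.1 / (4 * pi^2); cc <- 5 / pi
        r <- 6; s <- 10; tt <- 1 / (8 * pi)
        a * (x2 - b * x1^2 + cc * x1 - r)^2 + s * (1 - tt) * cos(x1) + s
      },
      space = design_space(x1 = c(-5, 10), x2 = c(0, 15)),
      argmin = rbind(c(-pi, 12.275), c(pi, 2.275), c(9.42478, 2.475)),
      fmin = 0.397887))
  if (is.null(name)) return(registry)
  if (!name %in% names(registry))
    stop("unknown test function '", name, "'; registry: ",
         paste(names(registry), collapse = ", "))
  registry[[name]]
}
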