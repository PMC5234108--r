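#' Fatigue material constants for the Goodman diagram
#'
#' The Goodman failure line in the (mean stress, alternating stress) plane
#' runs from \eqn{(\sigma_{UTS}, 0)} to \eqn{(0, \sigma_N)}:
#' \deqn{\sigma_a/\sigma_N + \sigma_m/\sigma_{UTS} = 1.}
#' Stress states below the line survive high-cycle loading; states above
#' it are failure-prone. Internal unit is MPa.
#'
#' @param sigma_N Endurance limit, MPa (stress amplitude survived
#'   indefinitely).
#' @param sigma_UTS Ultimate tensile strength, MPa.
#' @param sigma_yield Optional yield stress, MPa (carried for reporting).
#' @param unit `"MPa"` (default) or `"GPa"`; GPa inputs are converted.
#' @return An object of class `"goodman_material"`.
#' @examples
#' # 316L-class stainless stent steel: sigma_UTS 0.58 GPa, sigma_N 0.115 GPa
#' goodman_material(sigma_N = 0.115, sigma_UTS = 0.58, unit = "GPa")
#' @export
goodman_material <- function(sigma_N, sigma_UTS, sigma_yield = NULL,
                             unit = c("MPa", "GPa")) {
  unit <- match.arg(unit)
  f <- if (unit == "GPa") 1000 else 1
  sigma_N <- sigma_N * f; sigma_UTS <- sigma_UTS * f
  if (!is.null(sigma_yield)) sigma_yield <- sigma_yield * f
  stopifnot(is.finite(sigma_N), is.finite(sigma_UTS),
            sigma_N > 0, sigma_UTS > 0)
  if (sigma_N >= sigma_UTS)
    stop("endurance limit must be below the ultimate tensile strength")
  structure(list(sigma_N = sigma_N, sigma_UTS = sigma_UTS,
                 sigma_yield = sigma_yield),
            class = "goodman_material")
}

#' Default stent material: stainless steel 304
#'
#' Ultimate tensile strength 580 MPa, endurance limit 115 MPa, yield
#' stress 315 MPa — the bilinear isotropic stent steel used throughout the
#' bundled examples.
#' @return A [goodman_material()].
#' @export
stent_steel_304 <- function() {
  goodman_material(sigma_N = 115, sigma_UTS = 580, sigma_yield = 315)
}

#' @export
print.goodman_material <- function(x, ...) {
  cat(sprintf("Goodman material: sigma_N = %g MPa, sigma_UTS = %g MPa%s\n",
              x$sigma_N, x$sigma_UTS,
              if (!is.null(x$sigma_yield))
                sprintf(", yield = %g MPa", x$sigma_yield) else ""))
  invisible(x)
}

#' Mean / alternating stress decomposition of a pulsatile load
#'
#' The cardiac pressure cycle loads every stent node between a systolic
#' and a diastolic stress level; fatigue assessment uses the mean stress
#' \eqn{\sigma_m = (\sigma_{sys} + \sigma_{dia})/2} and the alternating
#' (amplitude) stress \eqn{\sigma_a = |\sigma_{sys} - \sigma_{dia}|/2}.
#'
#' @param sigma_systolic,sigma_diastolic Nodal stress under systolic /
#'   diastolic load, MPa. Vectorized.
#' @return A data.frame with columns `sigma_m` and `sigma_a` (MPa).
#' @examples
#' mean_amplitude(120, 80)  # sigma_m = 100, sigma_a = 20
#' @export
mean_amplitude <- function(sigma_systolic, sigma_diastolic) {
  stopifnot(all(is.finite(sigma_systolic)), all(is.finite(sigma_diastolic)))
  data.frame(sigma_m = (sigma_systolic + sigma_diastolic) / 2,
             sigma_a = abs(sigma_systolic - sigma_diastolic) / 2)
}

#' Signed safety distance to the Goodman failure line
#'
#' Euclidean point-to-line distance in the \eqn{(\sigma_m, \sigma_a)}
#' plane (MPa on both axes), signed positive for safe states (below the
#' line) and negative for failure-prone states:
#' \deqn{D = \frac{1 - \sigma_m/\sigma_{UTS} - \sigma_a/\sigma_N}
#'       {\sqrt{(1/\sigma_{UTS})^2 + (1/\sigma_N)^2}}.}
#' With `normalized = TRUE` the distance is computed instead in the
#' dimensionless coordinates \eqn{(\sigma_m/\sigma_{UTS},
#' \sigma_a/\sigma_N)} where the failure line is \eqn{x + y = 1} (distance
#' \eqn{(1 - x - y)/\sqrt 2}). Raw MPa coordinates are the default.
#'
#' @param sigma_m Mean stress(es), MPa. Negative (compressive) means are
#'   allowed.
#' @param sigma_a Alternating stress(es), MPa, nonnegative.
#' @param material A [goodman_material()].
#' @param normalized Use dimensionless coordinates (default `FALSE`).
#' @return A data.frame with columns `distance` (MPa, or dimensionless if
#'   normalized) and `safe` (logical); the sign of `distance` always
#'   agrees with `safe`.
#' @examples
#' m <- stent_steel_304()
#' goodman_margin(0, 0, m)       # ~112.8 MPa from the origin
#' goodman_margin(580, 0, m)     # on the line: 0, safe
#' @export
goodman_margin <- function(sigma_m, sigma_a, material, normalized = FALSE) {
  stopifnot(inherits(material, "goodman_material"),
            all(is.finite(sigma_m)), all(is.finite(sigma_a)),
            all(sigma_a >= 0))
  g <- 1 - sigma_m / material$sigma_UTS - sigma_a / material$sigma_N
  dist <- if (normalized) g / sqrt(2)
          else g / sqrt(1 / material$sigma_UTS^2 + 1 / material$sigma_N^2)
  data.frame(distance = dist, safe = g >= 0)
}

#' Shortest safety distance of a nodal stress set
#'
#' The fatigue objective of a stent design is the shortest distance from
#' any node's \eqn{(\sigma_m, \sigma_a)} state to the Goodman failure
#' line: the design is only as safe as its worst node. A negative value
#' means at least one node violates the failure-line constraint.
#'
#' @param points A `stress_point_set` from [stress_points()], or a
#'   data.frame with columns `sigma_m`, `sigma_a` (and optionally
#'   `node_id`).
#' @param material A [goodman_material()].
#' @param normalized Passed to [goodman_margin()].
#' @return A list with `distance` (the minimum signed margin, MPa),
#'   `worst_node` (its id) and `safe` (no node above the line).
#' @export
shortest_distance <- function(points, material, normalized = FALSE) {
  df <- as_stress_df(points)
  if (nrow(df) == 0L) stop("stress point set is empty")
  m <- goodman_margin(df$sigma_m, df$sigma_a, material, normalized)
  i <- which.min(m$distance)
  list(distance = m$distance[i],
       worst_node = df$node_id[i],
       safe = all(m$safe))
}

#' Construct a nodal stress point set
#'
#' @param sigma_m,sigma_a Vectors of mean / alternating stress, MPa.
#' @param node_id Optional node identifiers (defaults to 1..n).
#' @return An object of class `"stress_point_set"` (a data.frame).
#' @export
stress_points <- function(sigma_m, sigma_a, node_id = seq_along(sigma_m)) {
  stopifnot(length(sigma_m) == length(sigma_a), all(sigma_a >= 0))
  structure(data.frame(node_id = node_id, sigma_m = sigma_m,
                       sigma_a = sigma_a),
            class = c("stress_point_set", "data.frame"))
}

as_stress_df <- function(points) {
  df <- as.data.frame(points)
  if (!all(c("sigma_m", "sigma_a") %in% names(df)))
    stop("need columns sigma_m and sigma_a")
  if (is.null(df$node_id)) df$node_id <- seq_len(nrow(df))
  df
}

#' Read a nodal stress table from CSV
#'
#' Accepts either raw cyclic extremes (columns `sigma_systolic`,
#' `sigma_diastolic`) — converted through [mean_amplitude()] — or an
#' already-decomposed table (columns `sigma_m`, `sigma_a`); the layout is
#' auto-detected from the header. An optional `node_id` column is kept.
#'
#' @param path CSV path.
#' @param unit `"MPa"` (default) or `"GPa"` for the stress columns.
#' @return A `stress_point_set`.
#' @export
read_stress_csv <- function(path, unit = c("MPa", "GPa")) {
  unit <- match.arg(unit)
  f <- if (unit == "GPa") 1000 else 1
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("sigma_systolic", "sigma_diastolic") %in% names(df))) {
    ma <- mean_amplitude(df$sigma_systolic * f, df$sigma_diastolic * f)
  } else if (all(c("sigma_m", "sigma_a") %in% names(df))) {
    ma <- data.frame(sigma_m = df$sigma_m * f, sigma_a = df$sigma_a * f)
  } else {
    stop("stress CSV needs columns sigma_systolic+sigma_diastolic ",
         "or sigma_m+sigma_a")
  }
  id <- if ("node_id" %in% names(df)) df$node_id else seq_len(nrow(df))
  stress_points(ma$sigma_m, ma$sigma_a, id)
}

#' Export a Goodman diagram as CSV
#'
#' Writes the nodal points plus the two failure-line endpoints
#' \eqn{(\sigma_{UTS}, 0)} and \eqn{(0, \sigma_N)} (rows tagged in a
#' `role` column) so the diagram can be drawn by any plotting tool.
#'
#' @param points A `stress_point_set`.
#' @param material A [goodman_material()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_goodman_csv <- function(points, material, path) {
  df <- as_stress_df(points)
  df$role <- "node"
  line <- data.frame(node_id = NA,
                     sigma_m = c(material$sigma_UTS, 0),
                     sigma_a = c(0, material$sigma_N),
                     role = "failure_line")
  utils::write.csv(rbind(df[c("node_id", "sigma_m", "sigma_a", "role")], line),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a Goodman diagram
#'
#' @param points A `stress_point_set`.
#' @param material A [goodman_material()].
#' @param ... Passed to [graphics::plot()].
#' @return The input, invisibly.
#' @export
plot_goodman <- function(points, material, ...) {
  df <- as_stress_df(points)
  graphics::plot(df$sigma_m, df$sigma_a,
                 xlim = c(0, material$sigma_UTS) * 1.05,
                 ylim = c(0, material$sigma_N) * 1.05,
                 xlab = "mean stress sigma_m (MPa)",
                 ylab = "alternating stress sigma_a (MPa)",
                 main = "Goodman diagram", ...)
  graphics::segments(material$sigma_UTS, 0, 0, material$sigma_N, lty = 2)
  invisible(points)
}

#' Build the fatigue safety-distance objective for the optimizer
#'
#' Wraps a stress-field evaluator (design point -> nodal stress set) into
#' a scalar minimization objective: \eqn{-D_{shortest}} for feasible
#' designs, so minimizing it maximizes the shortest safety distance. A
#' design with any node above the failure line is infeasible; it is
#' assigned the worst feasible objective seen so far plus
#' `penalty * violation` (violation = depth of the worst node beyond the
#' line, MPa), which keeps the surrogate single-output while ordering
#' every infeasible design behind every feasible one.
#'
#' @param stress_evaluator Function: named design point -> stress set
#'   accepted by [shortest_distance()].
#' @param material A [goodman_material()].
#' @param penalty Penalty slope per MPa of violation (default 10).
#' @param normalized Passed to the margin computation.
#' @return A function: design point -> objective value (to be minimized),
#'   suitable for [ego()].
#' @export
fatigue_objective <- function(stress_evaluator, material, penalty = 10,
                              normalized = FALSE) {
  stopifnot(is.function(stress_evaluator), penalty > 0)
  state <- new.env(parent = emptyenv())
  state$worst_feasible <- 0      # the on-line design, objective -D = 0
  function(x) {
    sd <- shortest_distance(stress_evaluator(x), material, normalized)
    if (sd$distance >= 0) {
      obj <- -sd$distance
      state$worst_feasible <- max(state$worst_feasible, obj)
      obj
    } else {
      state$worst_feasible + penalty * (-sd$distance)
    }
  }
}
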