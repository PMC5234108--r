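#' Expected Improvement acquisition
#'
#' For a minimization problem with current best observed value `f_min` and
#' a Gaussian predictive distribution with the given mean and standard
#' deviation, the expected improvement is
#' \deqn{EI = (f_{min} - \hat y)\,\Phi(u) + s\,\phi(u), \quad
#'       u = (f_{min} - \hat y)/s}
#' when \eqn{s > 0}, and \eqn{\max(f_{min} - \hat y, 0)} when \eqn{s = 0}.
#' It is always nonnegative and balances exploitation (low predicted mean)
#' against exploration (high predictive uncertainty).
#'
#' @param f_min Current best (smallest) observed objective value.
#' @param mean Predictive mean(s).
#' @param sd Predictive standard deviation(s), `>= 0`.
#' @return Nonnegative EI value(s), vectorized over `mean`/`sd`.
#' @examples
#' expected_improvement(0, mean = 0, sd = 1)  # = dnorm(0) ~ 0.3989
#' @export
expected_improvement <- function(f_min, mean, sd) {
  if (!all(is.finite(f_min), is.finite(mean), is.finite(sd)))
    stop("non-finite inputs to expected_improvement")
  if (any(sd < 0)) stop("'sd' must be nonnegative")
  d <- f_min - mean
  ei <- pmax(d, 0)                       # sd == 0 branch
  pos <- sd > 0
  if (any(pos)) {
    u <- d[pos] / sd[pos]
    ei[pos] <- d[pos] * stats::pnorm(u) + sd[pos] * stats::dnorm(u)
  }
  pmax(ei, 0)
}

#' Maximize Expected Improvement over a design space
#'
#' Seeded multistart bounded local optimization (64 starts by default) of
#' the EI surface, combined with the best point of a 1024-point seeded
#' space-filling scan — the EI surface is multimodal and the scan guards
#' against all local searches missing the global peak.
#'
#' @param model A [kriging()] fit.
#' @param f_min Current best observed objective value.
#' @param space A [design_space()] (defaults to the model's).
#' @param seed Integer seed.
#' @param multistarts Number of local searches (default 64).
#' @param scan_points Size of the space-filling scan (default 1024).
#' @return A list with `point` (named numeric, native units) and `ei`.
#' @export
maximize_ei <- function(model, f_min, space = model$space, seed = 1L,
                        multistarts = 64L, scan_points = 1024L) {
  assert_space(space)
  d <- space$dim
  rng <- local_rng(seed)
  neg_ei_scaled <- function(u) {
    p <- predict(model, unscale01(space, matrix(u, nrow = 1L)))
    -expected_improvement(f_min, p$mean, p$sd)
  }

  ## space-filling scan
  Uscan <- matrix(rng$runif(scan_points * d), ncol = d)
  Pscan <- predict(model, unscale01(space, Uscan))
  ei_scan <- expected_improvement(f_min, Pscan$mean, Pscan$sd)
  best_u <- Uscan[which.max(ei_scan), , drop = TRUE]
  best_ei <- max(ei_scan)

  ## multistart local refinement: random starts plus the scan winner and
  ## the training points (EI peaks often sit between close training points)
  starts <- matrix(rng$runif(multistarts * d), ncol = d)
  starts[1L, ] <- best_u
  k <- min(nrow(model$U), max(0L, multistarts - 2L))
  if (k > 0L) {
    ord <- order(model$y)[seq_len(k)]
    starts[1L + seq_len(k), ] <- pmin(pmax(model$U[ord, , drop = FALSE], 0), 1)
  }
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(starts[i, ], neg_ei_scaled, method = "L-BFGS-B",
                   lower = rep(0, d), upper = rep(1, d),
                   control = list(maxit = 100L)),
      error = function(e) NULL)
    if (!is.null(opt) && -opt$value > best_ei) {
      best_ei <- -opt$value
      best_u <- opt$par
    }
  }
  pt <- drop(unscale01(space, matrix(best_u, nrow = 1L)))
  list(point = stats::setNames(pt, space$names), ei = max(best_ei, 0))
}

#' Convergence criteria for the adaptive optimization loop
#'
#' Three simultaneous conditions stop the loop at iteration \eqn{k}:
#' \deqn{EI_k / (Y_{max} - Y_{min}) \le \varepsilon_1}
#' \deqn{|f_k - \hat y_k| \le \varepsilon_2}
#' \deqn{|f_k - f_{k-1}| \le \varepsilon_3}
#' where \eqn{Y_{max}, Y_{min}} are the extremes of the responses observed
#' so far, \eqn{\hat y_k} is the surrogate's prediction at the new point
#' and \eqn{f_k} its evaluated objective. The first says the acquisition
#' has no promising candidates left; the second that the surrogate has
#' become accurate where it matters; the third that the objective has
#' stopped moving.
#'
#' @param eps1 Tolerance on the range-normalized EI (dimensionless).
#' @param eps2 Tolerance on the surrogate prediction error, objective units.
#' @param eps3 Tolerance on the objective step, objective units.
#' @param max_iterations Adaptive-iteration budget.
#' @return An object of class `"convergence_criteria"`.
#' @export
convergence_criteria <- function(eps1 = 1e-4, eps2 = 1e-4, eps3 = 1e-4,
                                 max_iterations = 50L) {
  stopifnot(eps1 > 0, eps2 > 0, eps3 > 0, max_iterations >= 0)
  structure(list(eps1 = eps1, eps2 = eps2, eps3 = eps3,
                 max_iterations = as.integer(max_iterations)),
            class = "convergence_criteria")
}

#' Evaluate the three-part convergence test
#'
#' @param ei_k EI value at the newly selected point.
#' @param f_k Evaluated objective at the new point.
#' @param yhat_k Surrogate prediction at the new point.
#' @param f_prev Objective value at the previous iteration (at `k = 1`,
#'   the best initial-sample value, which is where the iteration starts).
#' @param y_all All responses observed so far (for `Y_max - Y_min`; if the
#'   range is zero the EI ratio is taken as 0 by convention).
#' @param criteria A [convergence_criteria()].
#' @return A list with `converged` (logical) and `flags` (logical triple,
#'   one per inequality).
#' @export
check_convergence <- function(ei_k, f_k, yhat_k, f_prev, y_all, criteria) {
  y_range <- diff(range(y_all))
  ratio <- if (y_range > 0) ei_k / y_range else 0
  flags <- c(ei = ratio <= criteria$eps1,
             surrogate = abs(f_k - yhat_k) <= criteria$eps2,
             step = abs(f_k - f_prev) <= criteria$eps3)
  list(converged = all(flags), flags = flags)
}

#' Adaptive Kriging (EGO) optimization of a black-box objective
#'
#' Runs the efficient-global-optimization loop: evaluate an initial
#' modified-rectangular-grid design, fit an ordinary-Kriging surrogate,
#' select the next design by maximizing Expected Improvement, evaluate it,
#' refit, and stop when the three-part convergence test holds or the
#' iteration budget is exhausted. The loop minimizes; set
#' `maximize = TRUE` to negate the evaluator internally (used for the
#' fatigue safety-distance objective, which is maximized).
#'
#' @param evaluator Function taking a named numeric design point (native
#'   units) and returning a single finite objective value. For expensive
#'   models this is the only thing evaluated more than once per iteration.
#' @param space A [design_space()].
#' @param n_init Initial sample size for [mrg_design()].
#' @param criteria A [convergence_criteria()].
#' @param seed Integer seed governing the initial design, hyperparameter
#'   multistarts and EI search; fixes the whole run.
#' @param maximize If `TRUE`, maximize the evaluator instead.
#' @param shrink Passed to [mrg_design()].
#' @param theta_bounds,restarts,nugget Passed to [kriging()]; the surrogate
#'   is refitted from scratch every iteration.
#' @param partial_path Optional path: if the evaluator throws, the partial
#'   history collected so far is written there as JSON before re-raising.
#'
#' @return An object of class `"ego_run"`: list with `space`, `X`, `y`
#'   (all evaluated points/objectives, internal minimization sign),
#'   `iterations` (data.frame: k, coordinates, `ei`, `predicted`,
#'   `evaluated`, convergence flags), `best_point`, `best_value` (on the
#'   user's scale), `status` (`"converged"` or `"budget_exhausted"`),
#'   `maximize`, `n_init`, `seed`, `criteria`, and the final `model`.
#'
#' @examples
#' sp <- design_space(x = c(0, 1))
#' run <- ego(function(p) (p[["x"]] - 0.3)^2, sp, n_init = 5,
#'            criteria = convergence_criteria(max_iterations = 15), seed = 1)
#' run$best_point
#' @export
ego <- function(evaluator, space, n_init,
                criteria = convergence_criteria(), seed = 1L,
                maximize = FALSE, shrink = 0.1,
                theta_bounds = c(1e-3, 1e3), restarts = 10L,
                nugget = 1e-10, partial_path = NULL) {
  assert_space(space)
  stopifnot(is.function(evaluator))
  sign <- if (maximize) -1 else 1
  rng <- local_rng(seed)

  run_env <- new.env(parent = emptyenv())
  run_env$X <- NULL; run_env$y <- numeric(0); run_env$iters <- list()
  eval_point <- function(pt) {
    pt <- design_point(space, pt)
    val <- tryCatch(sign * as.numeric(evaluator(pt)), error = function(e) {
      if (!is.null(partial_path)) flush_partial(run_env, space, partial_path)
      stop("evaluator failed at (", paste(signif(pt, 6), collapse = ", "),
           "): ", conditionMessage(e), call. = FALSE)
    })
    if (length(val) != 1L || !is.finite(val))
      stop("evaluator must return a single finite value")
    run_env$X <- rbind(run_env$X, matrix(pt, nrow = 1L,
                                         dimnames = list(NULL, space$names)))
    run_env$y <- c(run_env$y, val)
    val
  }

  design <- mrg_design(space, n_init, shrink = shrink, seed = seed)
  apply(design$points, 1L, eval_point)

  ## the iteration starts from the best initial sample; its value is f_0
  f_prev <- min(run_env$y)
  status <- "budget_exhausted"
  model <- NULL

  k <- 0L
  while (k < criteria$max_iterations) {
    k <- k + 1L
    model <- kriging(run_env$X, run_env$y, space = space,
                     theta_bounds = theta_bounds, restarts = restarts,
                     nugget = nugget, seed = rng$derive(k))
    f_min <- min(run_env$y)
    acq <- maximize_ei(model, f_min, space, seed = rng$derive(1000L + k))
    yhat_k <- predict(model, matrix(acq$point, nrow = 1L))$mean

    ## a proposal (numerically) identical to a training point carries no
    ## new information; nudge it to the scan's best distinct candidate
    if (any(apply(run_env$X, 1L, function(r) max(abs(r - acq$point)) <
                  1e-12 * max(space$upper - space$lower)))) {
      acq$ei <- 0
    }
    f_k <- eval_point(acq$point)

    cc <- check_convergence(acq$ei, f_k, yhat_k, f_prev, run_env$y, criteria)
    run_env$iters[[k]] <- c(list(k = k), as.list(acq$point),
                            list(ei = acq$ei, predicted = yhat_k,
                                 evaluated = f_k,
                                 conv_ei = unname(cc$flags[1L]),
                                 conv_surrogate = unname(cc$flags[2L]),
                                 conv_step = unname(cc$flags[3L])))
    f_prev <- f_k
    if (cc$converged) { status <- "converged"; break }
  }

  best_i <- which.min(run_env$y)
  iters <- if (length(run_env$iters))
    do.call(rbind, lapply(run_env$iters, as.data.frame))
  else {
    cols <- c("k", space$names, "ei", "predicted", "evaluated",
              "conv_ei", "conv_surrogate", "conv_step")
    stats::setNames(as.data.frame(matrix(nrow = 0L, ncol = length(cols))), cols)
  }
  structure(list(space = space,
                 X = run_env$X, y = sign * run_env$y,
                 iterations = iters,
                 best_point = stats::setNames(run_env$X[best_i, ], space$names),
                 best_value = sign * run_env$y[best_i],
                 status = status, maximize = maximize,
                 n_init = n_init, seed = as.integer(seed),
                 criteria = criteria, model = model),
            class = "ego_run")
}

flush_partial <- function(run_env, space, path) {
  obj <- list(points = as.data.frame(run_env$X), responses = run_env$y,
              iterations = lapply(run_env$iters, identity),
              status = "aborted")
  try(write_json_atomic(obj, path), silent = TRUE)
}

#' @export
print.ego_run <- function(x, ...) {
  cat(sprintf("Adaptive Kriging optimization (%s)\n",
              if (x$maximize) "maximization" else "minimization"))
  cat(sprintf("  %d initial + %d adaptive evaluations, status: %s\n",
              x$n_init, nrow(x$iterations), x$status))
  cat("  best point:", paste(sprintf("%s = %.6g", names(x$best_point),
                                     x$best_point), collapse = ", "), "\n")
  cat(sprintf("  best value: %.6g\n", x$best_value))
  invisible(x)
}

#' @export
summary.ego_run <- function(object, ...) {
  print(object)
  if (nrow(object$iterations)) {
    cat("iteration trace (k, EI, predicted, evaluated, flags):\n")
    print(object$iterations, digits = 5, row.names = FALSE)
  }
  invisible(object)
}

#' @export
as.data.frame.ego_run <- function(x, ...) x$iterations

#' @export
plot.ego_run <- function(x, ...) {
  sgn <- if (x$maximize) -1 else 1
  run_best <- cummin(sgn * x$y) * sgn
  graphics::plot(seq_along(x$y), run_best, type = "s",
                 xlab = "evaluation", ylab = "running best objective",
                 main = "Adaptive Kriging optimization progress", ...)
  graphics::abline(v = x$n_init + 0.5, lty = 2)
  invisible(x)
}

#' Serialize / reload an optimization run
#'
#' `write_ego_json` stores the full history (all evaluated points and
#' responses, the iteration table, best point/value, status, criteria,
#' seed); `read_ego_json` reloads it into a `ego_run`-shaped list (without
#' the fitted surrogate). `write_ego_csv` writes the per-iteration table:
#' one row per adaptive iteration with k, coordinates, EI, predicted and
#' evaluated objective and the three convergence flags.
#' @param run An [ego()] result.
#' @param path File path.
#' @return `path` (writers, invisibly) or the reloaded list.
#' @export
write_ego_json <- function(run, path) {
  obj <- list(space = list(names = run$space$names, lower = run$space$lower,
                           upper = run$space$upper),
              points = as.data.frame(run$X),
              responses = run$y,
              iterations = run$iterations,
              best_point = as.list(run$best_point),
              best_value = run$best_value,
              status = run$status,
              maximize = run$maximize,
              n_init = run$n_init,
              seed = run$seed,
              criteria = unclass(run$criteria))
  write_json_atomic(obj, path)
  invisible(path)
}

#' @rdname write_ego_json
#' @export
read_ego_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$best_point <- unlist(obj$best_point)
  obj$space <- design_space(data.frame(name = obj$space$names,
                                       lower = obj$space$lower,
                                       upper = obj$space$upper))
  obj
}

#' @rdname write_ego_json
#' @export
write_ego_csv <- function(run, path) {
  utils::write.csv(run$iterations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## atomic write: temp file in the destination directory, then rename
write_json_atomic <- function(obj, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  # digits = I(17): doubles round-trip bit-exactly
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", na = "null")
  file.rename(tmp, path)
  invisible(path)
}
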