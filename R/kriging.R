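#' Fit an ordinary-Kriging surrogate
#'
#' Interpolating Gaussian-process surrogate with constant trend (ordinary
#' Kriging) and anisotropic Gaussian (squared-exponential) correlation
#' \deqn{R_{ij} = \exp\{-\sum_l \theta_l (u_{il} - u_{jl})^2\}}
#' on coordinates scaled to the unit cube. Correlation hyperparameters
#' \eqn{\theta} are estimated by maximizing the concentrated log-likelihood
#' with seeded multistart local optimization on the log scale, unless a
#' fixed `theta` is supplied. Predictions are best linear unbiased
#' combinations of the observed responses and reproduce the training data
#' exactly (up to a small conditioning nugget).
#'
#' @param x Training inputs: an `n` x `d` matrix/data.frame in native
#'   units, or a [mrg_design()] result (its points are used).
#' @param y Numeric response vector, one value per training point.
#' @param space A [design_space()]; required when `x` is a bare matrix so
#'   coordinates can be scaled internally. Taken from `x` when `x` is a
#'   `sample_design`.
#' @param theta Optional fixed positive correlation hyperparameters (length
#'   `d` or 1, on the unit-cube scale); skips likelihood estimation.
#' @param theta_bounds Search box for `theta`, default `c(1e-3, 1e3)`.
#' @param restarts Number of multistart local searches (default 10).
#' @param nugget Relative nugget added to the correlation diagonal for
#'   conditioning, default `1e-10`; escalated by factors of 10 up to
#'   `1e-6` if the Cholesky factorization fails.
#' @param seed Integer seed for the multistart locations.
#'
#' @return An object of class `"kriging"` with elements `space`, `X`
#'   (native units), `U` (unit-cube coordinates), `y`, `theta`, `mu`
#'   (process mean), `sigma2` (process variance), `nugget` (as used),
#'   plus cached factorization quantities.
#'
#' @seealso [predict.kriging()], [ego()]
#' @examples
#' sp <- design_space(x = c(0, 1))
#' X <- matrix(seq(0, 1, length.out = 8))
#' fit <- kriging(X, sin(2 * pi * X[, 1]), space = sp, seed = 1)
#' predict(fit, 0.3125)
#' @export
kriging <- function(x, y, space = NULL, theta = NULL,
                    theta_bounds = c(1e-3, 1e3), restarts = 10L,
                    nugget = 1e-10, seed = 1L) {
  if (inherits(x, "sample_design")) {
    if (is.null(space)) space <- x$space
    x <- x$points
  }
  assert_space(space)
  X <- as_matrix_points(space, x)
  y <- as.numeric(y)
  n <- nrow(X)
  d <- space$dim
  if (length(y) != n) stop("'y' must have one response per training point")
  if (!all(is.finite(y))) stop("responses must be finite")
  if (n < 1L) stop("at least one training point is required")

  ## duplicate handling: identical inputs with identical responses are
  ## collapsed; conflicting responses are a modelling error
  U <- scale01(space, X)
  dup <- duplicated(round(U, 12L))
  if (any(dup)) {
    key <- apply(round(U, 12L), 1L, paste, collapse = "|")
    for (k in unique(key[dup])) {
      idx <- which(key == k)
      if (diff(range(y[idx])) > 1e-9 * max(1, diff(range(y))))
        stop(sprintf(paste0("duplicate training points with conflicting ",
                            "responses: rows %s"),
                     paste(idx, collapse = ", ")))
    }
    X <- X[!dup, , drop = FALSE]; U <- U[!dup, , drop = FALSE]; y <- y[!dup]
    n <- nrow(X)
  }

  if (n == 1L) {
    ## degenerate surrogate: constant mean, zero process variance
    fit <- list(space = space, X = X, U = U, y = y,
                theta = rep(1, d), mu = y[1L], sigma2 = 0,
                nugget = nugget, L = matrix(1, 1, 1),
                Rinv_res = matrix(0, 1, 1), Rinv_one = matrix(1, 1, 1),
                one_Rinv_one = 1, estimated = FALSE)
    return(structure(fit, class = "kriging"))
  }

  if (!is.null(theta)) {
    theta <- rep_len(as.numeric(theta), d)
    if (any(theta <= 0)) stop("'theta' must be positive")
    estimated <- FALSE
  } else {
    theta <- estimate_theta(U, y, theta_bounds, restarts, nugget, seed)
    estimated <- TRUE
  }

  f <- krig_factorize(U, y, theta, nugget)
  structure(c(list(space = space, X = X, U = U, y = y, theta = theta,
                   estimated = estimated), f),
            class = "kriging")
}

## correlation matrix under Gaussian kernel, unit-cube coordinates
corr_matrix <- function(U, theta) {
  n <- nrow(U)
  R <- matrix(1, n, n)
  for (l in seq_len(ncol(U))) {
    dl <- outer(U[, l], U[, l], "-")
    R <- R * exp(-theta[l] * dl * dl)
  }
  R
}

corr_vector <- function(U, u, theta) {
  r <- rep(1, nrow(U))
  for (l in seq_len(ncol(U)))
    r <- r * exp(-theta[l] * (U[, l] - u[l])^2)
  r
}

## Cholesky with nugget escalation: 1e-10 -> 1e-9 -> ... -> 1e-6
chol_with_nugget <- function(R, nugget) {
  ng <- nugget
  while (ng <= 1e-6 + 1e-18) {
    L <- tryCatch(chol(R + diag(ng, nrow(R))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, nugget = ng))
    ng <- ng * 10
  }
  stop("correlation matrix is singular even with nugget 1e-6; ",
       "training points may be (near-)duplicated")
}

krig_factorize <- function(U, y, theta, nugget) {
  n <- nrow(U)
  cf <- chol_with_nugget(corr_matrix(U, theta), nugget)
  L <- cf$L                                 # upper-triangular: R = t(L) %*% L
  one <- rep(1, n)
  Rinv_one <- backsolve(L, forwardsolve(t(L), one))
  one_Rinv_one <- sum(one * Rinv_one)
  mu <- sum(Rinv_one * y) / one_Rinv_one
  res <- y - mu
  Rinv_res <- backsolve(L, forwardsolve(t(L), res))
  sigma2 <- max(sum(res * Rinv_res) / n, 0)
  list(mu = mu, sigma2 = sigma2, nugget = cf$nugget, L = L,
       Rinv_res = Rinv_res, Rinv_one = Rinv_one, one_Rinv_one = one_Rinv_one)
}

## concentrated log-likelihood (constant trend profiled out):
## -n/2 log(sigma2_hat) - 1/2 log|R|
concentrated_loglik <- function(log10_theta, U, y, nugget) {
  theta <- 10^log10_theta
  n <- nrow(U)
  cf <- tryCatch(chol_with_nugget(corr_matrix(U, theta), nugget),
                 error = function(e) NULL)
  if (is.null(cf)) return(-1e10)
  L <- cf$L
  one <- rep(1, n)
  Rinv_one <- backsolve(L, forwardsolve(t(L), one))
  mu <- sum(Rinv_one * y) / sum(one * Rinv_one)
  res <- y - mu
  Rinv_res <- backsolve(L, forwardsolve(t(L), res))
  sigma2 <- sum(res * Rinv_res) / n
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1e-300
  logdet <- 2 * sum(log(diag(L)))
  ll <- -n / 2 * log(sigma2) - logdet / 2
  if (!is.finite(ll)) -1e10 else ll
}

estimate_theta <- function(U, y, theta_bounds, restarts, nugget, seed) {
  d <- ncol(U)
  lb <- log10(theta_bounds[1L]); ub <- log10(theta_bounds[2L])
  rng <- local_rng(seed)
  starts <- matrix(rng$runif(restarts * d, lb, ub), nrow = restarts)
  starts[1L, ] <- rep(log10(10), d)   # one deterministic, sensible start
  best <- NULL; best_ll <- -Inf
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(starts[i, ], function(p) -concentrated_loglik(p, U, y, nugget),
                   method = "L-BFGS-B", lower = rep(lb, d), upper = rep(ub, d),
                   control = list(maxit = 200L)),
      error = function(e) NULL)
    if (!is.null(opt) && -opt$value > best_ll) {
      best_ll <- -opt$value
      best <- opt$par
    }
  }
  if (is.null(best)) stop("hyperparameter estimation failed from every start")
  10^best
}

#' Predict from a Kriging surrogate
#'
#' Returns the BLUP mean and the Kriging variance at new locations. The
#' variance is zero (up to the nugget) at training points and grows with
#' distance from the data; it feeds the Expected Improvement acquisition.
#'
#' @param object A [kriging()] fit.
#' @param newdata Points in native units: vector (single point), matrix or
#'   data.frame.
#' @param ... Unused.
#' @return A data.frame with columns `mean`, `variance`, `sd` and a logical
#'   attribute-free column `extrapolating` flagging points outside the
#'   design-space bounds (a warning is emitted for those, not an error).
#' @export
predict.kriging <- function(object, newdata, ...) {
  space <- object$space
  Xn <- as_matrix_points(space, newdata)
  Un <- scale01(space, Xn)
  extra <- apply(Un < -1e-8 | Un > 1 + 1e-8, 1L, any)
  if (any(extra))
    warning(sprintf("%d point(s) outside the design-space bounds: extrapolating",
                    sum(extra)))
  m <- nrow(Un)
  mean <- numeric(m); var <- numeric(m)
  if (nrow(object$U) == 1L) {
    mean[] <- object$mu; var[] <- 0
  } else {
    L <- object$L
    for (i in seq_len(m)) {
      r <- corr_vector(object$U, Un[i, ], object$theta)
      mean[i] <- object$mu + sum(r * object$Rinv_res)
      Rinv_r <- backsolve(L, forwardsolve(t(L), r))
      v <- object$sigma2 *
        (1 - sum(r * Rinv_r) + (1 - sum(object$Rinv_one * r))^2 / object$one_Rinv_one)
      var[i] <- max(v, 0)
    }
  }
  data.frame(mean = mean, variance = var, sd = sqrt(var),
             extrapolating = extra)
}

#' @export
print.kriging <- function(x, ...) {
  cat(sprintf("Ordinary Kriging surrogate: %d training points, %d-D\n",
              nrow(x$X), x$space$dim))
  cat("  theta  :", paste(signif(x$theta, 4), collapse = ", "),
      if (isTRUE(x$estimated)) "(MLE)" else "(fixed)", "\n")
  cat(sprintf("  mean   : %.6g\n  var    : %.6g\n  nugget : %g\n",
              x$mu, x$sigma2, x$nugget))
  invisible(x)
}

#' @export
summary.kriging <- function(object, ...) {
  pr <- predict(object, object$X)
  structure(list(n = nrow(object$X), dim = object$space$dim,
                 theta = object$theta, mu = object$mu,
                 sigma2 = object$sigma2, nugget = object$nugget,
                 max_interp_error = max(abs(pr$mean - object$y)),
                 y_range = range(object$y)),
            class = "summary.kriging")
}

#' @export
print.summary.kriging <- function(x, ...) {
  cat(sprintf("Ordinary Kriging: n = %d, d = %d\n", x$n, x$dim))
  cat("  theta:", paste(signif(x$theta, 4), collapse = ", "), "\n")
  cat(sprintf("  process mean %.6g, variance %.6g, nugget %g\n",
              x$mu, x$sigma2, x$nugget))
  cat(sprintf("  responses in [%.6g, %.6g]\n", x$y_range[1], x$y_range[2]))
  cat(sprintf("  max |interpolation error| at training points: %.3g\n",
              x$max_interp_error))
  invisible(x)
}

#' @export
coef.kriging <- function(object, ...) {
  c(stats::setNames(object$theta, paste0("theta_", object$space$names)),
    mu = object$mu, sigma2 = object$sigma2)
}

#' @export
residuals.kriging <- function(object, ...) {
  predict(object, object$X)$mean - object$y
}

#' Serialize a Kriging model summary to JSON
#'
#' Writes the hyperparameters, process mean/variance and training size —
#' enough to audit a fit, not to reload it (refit from the training CSV
#' for that).
#' @param model A [kriging()] fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kriging_json <- function(model, path) {
  obj <- list(type = "ordinary_kriging",
              n = nrow(model$X),
              variables = model$space$names,
              theta = model$theta,
              process_mean = model$mu,
              process_variance = model$sigma2,
              nugget = model$nugget)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a training set (design points + response column) as CSV
#'
#' Same CSV dialect as [write_design_csv()] with an extra `response`
#' column.
#' @param x Point matrix or `sample_design`.
#' @param y Response vector.
#' @param path File path.
#' @export
write_training_csv <- function(x, y, path, space = NULL) {
  pts <- if (inherits(x, "sample_design")) {
    if (is.null(space)) space <- x$space
    x$points
  } else x
  if (!is.null(space)) pts <- as_matrix_points(space, pts)
  df <- as.data.frame(pts)
  df$response <- as.numeric(y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_training_csv
#' @param space Design space the points belong to.
#' @export
read_training_csv <- function(path, space) {
  assert_space(space)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"response" %in% names(df)) stop("training CSV needs a 'response' column")
  list(x = as_matrix_points(space, df), y = as.numeric(df$response))
}
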