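# Independent oracles, deliberately implemented with none of the package's
# internals: dense textbook formulas and numeric minimization only.

# ordinary-Kriging BLUP by explicit dense solve (constant trend, Gaussian
# correlation on [0,1]-scaled coordinates, fixed theta, fixed nugget)
blup_oracle <- function(U, y, theta, u_new, nugget = 1e-10) {
  n <- nrow(U)
  R <- matrix(1, n, n)
  for (l in seq_len(ncol(U))) R <- R * exp(-theta[l] * outer(U[, l], U[, l], "-")^2)
  R <- R + diag(nugget, n)
  Ri <- solve(R)
  one <- rep(1, n)
  mu <- drop(t(one) %*% Ri %*% y) / drop(t(one) %*% Ri %*% one)
  r <- rep(1, n)
  for (l in seq_len(ncol(U))) r <- r * exp(-theta[l] * (U[, l] - u_new[l])^2)
  mean <- mu + drop(t(r) %*% Ri %*% (y - mu))
  s2 <- drop(t(y - mu) %*% Ri %*% (y - mu)) / n
  var <- s2 * (1 - drop(t(r) %*% Ri %*% r) +
                 (1 - drop(t(one) %*% Ri %*% r))^2 / drop(t(one) %*% Ri %*% one))
  list(mean = mean, variance = max(var, 0))
}

# point-to-Goodman-line distance by numeric minimization over points of the
# parameterized failure line (sigma_m, sigma_a) = (phi*UTS, (1-phi)*N),
# signed by which side of the line the point lies on
goodman_oracle <- function(sm, sa, sigma_N, sigma_UTS) {
  d2 <- function(phi) (phi * sigma_UTS - sm)^2 + ((1 - phi) * sigma_N - sa)^2
  # the line is infinite; search well beyond the [0,1] segment
  opt <- stats::optimize(d2, interval = c(-50, 50), tol = 1e-12)
  side <- 1 - sm / sigma_UTS - sa / sigma_N
  sign(side) * sqrt(opt$objective)
}

diamond_space <- function() {
  design_space(w1 = c(0.22, 0.34), w2 = c(0.2, 0.3), t1 = c(0.1, 0.14))
}

unit_space_1d <- function() design_space(x = c(0, 1))
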