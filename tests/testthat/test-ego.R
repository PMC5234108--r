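test_that("expected improvement matches its closed form and limits", {
  # no uncertainty: improvement is the positive part of f_min - mean
  expect_equal(expected_improvement(5, mean = 6, sd = 0), 0)
  expect_equal(expected_improvement(5, mean = 3, sd = 0), 2)
  # standard-normal case: EI = dnorm(0) at mean = f_min, sd = 1
  expect_equal(expected_improvement(0, 0, 1), dnorm(0), tolerance = 1e-12)
  expect_error(expected_improvement(NaN, 0, 1), "non-finite")
  expect_error(expected_improvement(0, 0, -1), "nonnegative")
})

test_that("expected improvement agrees with a Monte-Carlo oracle", {
  set.seed(101)
  cases <- data.frame(f_min = c(0, 1, -0.5, 2),
                      mean = c(0, 0.5, 0, 2.4),
                      sd = c(1, 2, 0.3, 0.8))
  for (i in seq_len(nrow(cases))) {
    y <- rnorm(1e6, cases$mean[i], cases$sd[i])
    mc <- mean(pmax(cases$f_min[i] - y, 0))
    expect_equal(expected_improvement(cases$f_min[i], cases$mean[i], cases$sd[i]),
                 mc, tolerance = 5e-3)
  }
})

test_that("maximize_ei finds the grid-scan optimum", {
  sp <- unit_space_1d()
  grid <- matrix(seq(0, 1, length.out = 1e4))

  # constant data: EI peaks where predicted variance peaks
  fitc <- kriging(matrix(c(0, 0.25, 0.5, 0.75, 1)), rep(2, 5), space = sp,
                  theta = 30)
  res <- maximize_ei(fitc, f_min = 2, seed = 1)
  prg <- predict(fitc, grid)
  eig <- expected_improvement(2, prg$mean, prg$sd)
  expect_gte(res$ei, max(eig) - 1e-9)
  v_at <- predict(fitc, res$point)$variance
  expect_gte(v_at, max(prg$variance) - 1e-9)

  # V-shaped data: returned EI >= dense grid scan EI
  Xv <- matrix(c(0, 0.2, 0.45, 0.7, 1))
  yv <- abs(Xv[, 1] - 0.45)
  fitv <- kriging(Xv, yv, space = sp, theta = 20)
  resv <- maximize_ei(fitv, f_min = min(yv), seed = 2)
  prv <- predict(fitv, grid)
  eiv <- expected_improvement(min(yv), prv$mean, prv$sd)
  expect_gte(resv$ei, max(eiv) - 1e-9)
})

test_that("check_convergence evaluates the three inequalities", {
  crit <- convergence_criteria(eps1 = 0.01, eps2 = 0.1, eps3 = 0.1)
  # all pass
  cc <- check_convergence(ei_k = 0, f_k = 1, yhat_k = 1, f_prev = 1,
                          y_all = c(0, 1, 2), criteria = crit)
  expect_true(cc$converged)
  expect_equal(unname(cc$flags), c(TRUE, TRUE, TRUE))
  # EI ratio fails alone: EI/(Ymax-Ymin) = 2*eps1
  cc <- check_convergence(ei_k = 0.04, f_k = 1, yhat_k = 1, f_prev = 1,
                          y_all = c(0, 2), criteria = crit)
  expect_false(cc$converged)
  expect_equal(unname(cc$flags), c(FALSE, TRUE, TRUE))
  # surrogate error fails: EI passes, |f - yhat| = 0.5 > eps2
  cc <- check_convergence(ei_k = 0.001, f_k = 1.5, yhat_k = 1, f_prev = 1.5,
                          y_all = c(0, 1), criteria = crit)
  expect_false(cc$converged)
  expect_equal(unname(cc$flags[1:2]), c(TRUE, FALSE))
  # zero response range: EI ratio defined as 0 by convention
  cc <- check_convergence(ei_k = 1, f_k = 1, yhat_k = 1, f_prev = 1,
                          y_all = c(1, 1), criteria = crit)
  expect_true(cc$flags[["ei"]])
})

test_that("the adaptive loop recovers a 1-D quadratic optimum", {
  tf <- standard_test_functions("quadratic1d")
  run <- ego(tf$fn, tf$space, n_init = 5,
             criteria = convergence_criteria(max_iterations = 20), seed = 1)
  expect_lt(abs(run$best_point[["x"]] - 0.3), 0.01)
  expect_lte(run$best_value, 1e-3)
  expect_identical(run$status, "converged")
  # every evaluated point is inside the space
  expect_true(all(run$X >= 0 & run$X <= 1))
  # running best is non-increasing
  expect_true(all(diff(cummin(run$y)) <= 0))
})

test_that("with infinite tolerances the loop stops after one iteration", {
  tf <- standard_test_functions("quadratic1d")
  run <- ego(tf$fn, tf$space, n_init = 5,
             criteria = convergence_criteria(eps1 = Inf, eps2 = Inf, eps3 = Inf,
                                             max_iterations = 50), seed = 1)
  expect_equal(nrow(run$iterations), 1L)
  expect_identical(run$status, "converged")
})

test_that("a zero iteration budget returns the best initial sample", {
  tf <- standard_test_functions("quadratic1d")
  run <- ego(tf$fn, tf$space, n_init = 6,
             criteria = convergence_criteria(max_iterations = 0), seed = 2)
  expect_identical(run$status, "budget_exhausted")
  expect_equal(nrow(run$X), 6L)
  expect_equal(run$best_value, min(run$y))
})

test_that("maximization negates the evaluator through a single code path", {
  sp <- unit_space_1d()
  run <- ego(function(p) -(p[["x"]] - 0.3)^2, sp, n_init = 5,
             criteria = convergence_criteria(max_iterations = 15), seed = 1,
             maximize = TRUE)
  expect_lt(abs(run$best_point[["x"]] - 0.3), 0.01)
  expect_gte(run$best_value, -1e-3)
  expect_equal(run$best_value, max(run$y))
})

test_that("runs are reproducible and serialize losslessly", {
  tf <- standard_test_functions("quadratic1d")
  crit <- convergence_criteria(max_iterations = 8)
  r1 <- ego(tf$fn, tf$space, n_init = 5, criteria = crit, seed = 9)
  r2 <- ego(tf$fn, tf$space, n_init = 5, criteria = crit, seed = 9)
  expect_identical(r1$X, r2$X)
  expect_identical(r1$iterations, r2$iterations)

  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_ego_json(r1, p1); write_ego_json(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_ego_json(p1)
  expect_equal(back$best_value, r1$best_value)
  expect_equal(unname(back$best_point), unname(r1$best_point))
  expect_identical(back$status, r1$status)

  cp <- withr::local_tempfile(fileext = ".csv")
  write_ego_csv(r1, cp)
  it <- utils::read.csv(cp)
  expect_equal(nrow(it), nrow(r1$iterations))
  expect_true(all(c("k", "x", "ei", "predicted", "evaluated") %in% names(it)))
})

test_that("an evaluator exception aborts with partial history on disk", {
  sp <- unit_space_1d()
  pp <- withr::local_tempfile(fileext = ".json")
  boom <- function(p) if (p[["x"]] > 0) stop("fem crashed") else 0
  expect_error(
    ego(boom, sp, n_init = 5,
        criteria = convergence_criteria(max_iterations = 5), seed = 1,
        partial_path = pp),
    "evaluator failed")
  expect_true(file.exists(pp))
  partial <- jsonlite::read_json(pp, simplifyVector = TRUE)
  expect_identical(partial$status, "aborted")
})
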