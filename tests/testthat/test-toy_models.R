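test_that("toy fatigue model is deterministic and bounded to its space", {
  tm <- toy_fatigue_model()
  x <- c(0.3, 0.25, 0.12)
  s1 <- toy_fatigue_evaluate(tm, x)
  s2 <- toy_fatigue_evaluate(tm, x)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), tm$n_nodes)
  expect_error(toy_fatigue_evaluate(tm, c(0.5, 0.25, 0.12)), "outside bounds")
})

test_that("toy fatigue margins peak exactly at the constructed optimum", {
  tm <- toy_fatigue_model()
  m <- tm$material
  # margin at x* equals the constructed D*, with all nodes safe
  sd_star <- shortest_distance(toy_fatigue_evaluate(tm, tm$x_star), m)
  expect_equal(sd_star$distance, tm$D_star, tolerance = 1e-9)
  expect_true(sd_star$safe)
  # closed-form distance agrees with the node-set evaluation everywhere
  set.seed(31)
  for (i in 1:20) {
    x <- tm$space$lower + runif(3) * (tm$space$upper - tm$space$lower)
    expect_equal(shortest_distance(toy_fatigue_evaluate(tm, x), m)$distance,
                 toy_fatigue_distance(tm, x), tolerance = 1e-9)
  }
  # corners are strictly worse than the interior optimum
  for (cx in list(tm$space$lower, tm$space$upper,
                  c(0.22, 0.3, 0.14), c(0.34, 0.2, 0.1))) {
    expect_lt(toy_fatigue_distance(tm, cx), tm$D_star)
  }
})

test_that("dense grid search confirms the constructed optimum is the true one", {
  tm <- toy_fatigue_model()
  ax <- lapply(1:3, function(i) seq(tm$space$lower[i], tm$space$upper[i],
                                    length.out = 30))
  grid <- as.matrix(expand.grid(ax))
  vals <- apply(grid, 1, function(x) toy_fatigue_distance(tm, x))
  expect_true(all(vals <= tm$D_star + 1e-12))
  best <- grid[which.max(vals), ]
  # the 30^3 grid's best cell brackets x*: within one grid step per axis
  step <- (tm$space$upper - tm$space$lower) / 29
  expect_true(all(abs(best - tm$x_star) <= step))
})

test_that("stress components trade off monotonically with effective stiffness", {
  # along a stiffness-increasing path at fixed offset from the optimum,
  # sigma_m strictly increases and sigma_a strictly decreases
  tm <- toy_fatigue_model(gamma = 0)   # pure stiffness dependence
  path <- seq(0.05, 0.95, length.out = 15)
  X <- cbind(tm$space$lower[1] + path * diff(range(c(tm$space$lower[1], tm$space$upper[1]))),
             tm$space$lower[2] + path * (tm$space$upper[2] - tm$space$lower[2]),
             tm$space$lower[3] + path * (tm$space$upper[3] - tm$space$lower[3]))
  sm <- apply(X, 1, function(x) toy_fatigue_evaluate(tm, x)$sigma_m[1])
  sa <- apply(X, 1, function(x) toy_fatigue_evaluate(tm, x)$sigma_a[1])
  expect_true(all(diff(sm) > 0))
  expect_true(all(diff(sa) < 0))
})

test_that("toy balloon histories have the stated shape and signs", {
  tb <- toy_balloon_model()
  # dogboning at 32 ms: zero at L*, positive at the upper bound (dogbone),
  # negative at the lower bound (spindle)
  expect_equal(expansion_report(toy_balloon_evaluate(tb, tb$L_star))$dogboning_32,
               0, tolerance = 1e-12)
  expect_gt(expansion_report(toy_balloon_evaluate(tb, tb$space$upper))$dogboning_32, 0)
  expect_lt(expansion_report(toy_balloon_evaluate(tb, tb$space$lower))$dogboning_32, 0)

  h <- toy_balloon_evaluate(tb, 5.0)
  expect_s3_class(h, "expansion_history")
  expect_true(all(c(32, 42) %in% h$times))
  expect_lte(max(diff(h$times)), 1)            # >= 1 ms resolution
  # ramp-plateau-recoil: radius grows to 25 ms, flat in the hold,
  # recoils after unloading
  r32 <- h$r_proximal[h$times == 32]
  expect_equal(h$r_proximal[h$times == 25], r32)
  expect_lt(h$r_proximal[h$times == 42], r32)
  expect_gt(r32, h$r0)

  # purity: equal inputs give identical histories
  expect_identical(toy_balloon_evaluate(tb, 4.8), toy_balloon_evaluate(tb, 4.8))
  expect_error(toy_balloon_evaluate(tb, 5.5), "outside bounds")
})

test_that("toy balloon dogboning has exactly one sign change in L", {
  tb <- toy_balloon_model()
  Ls <- seq(tb$space$lower, tb$space$upper, length.out = 101)
  dr <- vapply(Ls, function(L)
    expansion_report(toy_balloon_evaluate(tb, L))$dogboning_32, 0)
  expect_true(all(diff(dr) > 0))               # strictly increasing in L
  expect_equal(sum(diff(sign(dr)) != 0), 1L)   # one crossing
})

test_that("radius after unloading increases with peak pressure", {
  tb <- toy_balloon_model()
  f <- toy_balloon_radius_fn(tb, 4.9)
  ps <- seq(0.4, 2.4, by = 0.2)
  rs <- vapply(ps, f, 0)
  expect_true(all(diff(rs) > 0))
  # and is therefore bisection-calibratable to the nominal vessel radius
  p <- calibrate_pressure(f, 2.2, c(0.2, 3), tol = 1e-4)
  expect_equal(attr(p, "radius"), 2.2, tolerance = 1e-4)
})

test_that("toy model parameters round-trip through JSON", {
  tm <- toy_fatigue_model(D_star = 35, gamma = 0.8, n_nodes = 7L)
  pf <- withr::local_tempfile(fileext = ".json")
  write_toy_model_json(tm, pf)
  tm2 <- read_toy_model_json(pf)
  x <- c(0.25, 0.28, 0.13)
  expect_equal(toy_fatigue_distance(tm2, x), toy_fatigue_distance(tm, x),
               tolerance = 1e-12)

  tb <- toy_balloon_model(L_star = 4.8, dog_slope = 0.2)
  pb <- withr::local_tempfile(fileext = ".json")
  write_toy_model_json(tb, pb)
  tb2 <- read_toy_model_json(pb)
  expect_equal(unclass(toy_balloon_evaluate(tb2, 4.7)),
               unclass(toy_balloon_evaluate(tb, 4.7)), tolerance = 1e-12)
})

test_that("the analytic test-function registry stores verified optima", {
  reg <- standard_test_functions()
  expect_true(all(c("quadratic1d", "forrester1d", "branin") %in% names(reg)))
  expect_error(standard_test_functions("nope"), "registry")

  q <- standard_test_functions("quadratic1d")
  expect_equal(q$fn(c(x = 0.3)), q$fmin)

  # each stored minimum is confirmed by a dense grid scan of its space
  for (nm in names(reg)) {
    tf <- reg[[nm]]
    d <- tf$space$dim
    m <- if (d == 1) 1e5 else 1000
    ax <- lapply(seq_len(d), function(i)
      seq(tf$space$lower[i], tf$space$upper[i], length.out = m))
    grid <- as.matrix(do.call(expand.grid, ax))
    vals <- apply(grid, 1, function(r) tf$fn(r))
    expect_gte(min(vals), tf$fmin - 1e-6)      # nothing beats the stored min
    expect_equal(min(vals), tf$fmin, tolerance = 5e-3)
    # every stored argmin evaluates to fmin
    for (j in seq_len(nrow(tf$argmin)))
      expect_equal(tf$fn(tf$argmin[j, ]), tf$fmin, tolerance = 1e-4)
  }
})
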