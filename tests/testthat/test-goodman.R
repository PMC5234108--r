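test_that("mean/amplitude decomposition of the cardiac cycle", {
  expect_equal(mean_amplitude(100, 100), data.frame(sigma_m = 100, sigma_a = 0))
  expect_equal(mean_amplitude(120, 80), data.frame(sigma_m = 100, sigma_a = 20))
  # amplitude is an absolute difference: swapping the extremes changes nothing
  expect_equal(mean_amplitude(80, 120), data.frame(sigma_m = 100, sigma_a = 20))
})

test_that("material constructor validates and converts units", {
  m <- goodman_material(0.115, 0.58, sigma_yield = 0.315, unit = "GPa")
  expect_equal(m$sigma_N, 115)
  expect_equal(m$sigma_UTS, 580)
  expect_equal(m$sigma_yield, 315)
  expect_equal(stent_steel_304()$sigma_UTS, 580)
  expect_error(goodman_material(600, 580), "below the ultimate")
  expect_error(goodman_material(-1, 580))
})

test_that("signed margin matches closed-form anchor points", {
  m <- stent_steel_304()
  # a point on the failure line has zero distance and is (boundary) safe
  on_line <- goodman_margin(580, 0, m)
  expect_equal(on_line$distance, 0)
  expect_true(on_line$safe)
  # the origin: classic point-to-line distance UTS*N/sqrt(UTS^2+N^2)
  origin <- goodman_margin(0, 0, m)
  expect_equal(origin$distance, 580 * 115 / sqrt(580^2 + 115^2),
               tolerance = 1e-12)
  expect_equal(origin$distance, 112.80, tolerance = 1e-4)
  # a service stress state of a real strut hot-spot
  svc <- goodman_margin(304.6, 22.02, m)
  expect_equal(svc$distance, goodman_oracle(304.6, 22.02, 115, 580),
               tolerance = 1e-6)
  expect_equal(svc$distance, 31.963, tolerance = 1e-4)
  expect_true(svc$safe)
})

test_that("margin equals the numeric point-to-line oracle on random points", {
  m <- stent_steel_304()
  set.seed(77)
  sm <- runif(1000, -100, 650)
  sa <- runif(1000, 0, 160)
  got <- goodman_margin(sm, sa, m)$distance
  want <- mapply(goodman_oracle, sm, sa,
                 MoreArgs = list(sigma_N = 115, sigma_UTS = 580))
  expect_equal(got, want, tolerance = 1e-6)
  # sign and safe flag always agree
  expect_identical(got >= 0, goodman_margin(sm, sa, m)$safe)
})

test_that("margin scales with units and responds monotonically to stress", {
  m_mpa <- stent_steel_304()
  m_gpa <- goodman_material(115e3, 580e3)  # both stresses and limits x1000
  d1 <- goodman_margin(304.6, 22.02, m_mpa)$distance
  d2 <- goodman_margin(304600, 22020, m_gpa)$distance
  expect_equal(d2, 1000 * d1, tolerance = 1e-9)
  # increasing sigma_a or sigma_m never increases a safe point's margin
  base <- goodman_margin(300, 20, m_mpa)$distance
  expect_lt(goodman_margin(310, 20, m_mpa)$distance, base)
  expect_lt(goodman_margin(300, 25, m_mpa)$distance, base)
  # compressive (negative) mean stress uses the same formula
  expect_gt(goodman_margin(-50, 20, m_mpa)$distance,
            goodman_margin(0, 20, m_mpa)$distance)
})

test_that("normalized coordinates put the line at x + y = 1", {
  m <- stent_steel_304()
  d <- goodman_margin(0, 0, m, normalized = TRUE)$distance
  expect_equal(d, 1 / sqrt(2), tolerance = 1e-12)
})

test_that("shortest_distance is the brute-force minimum over nodes", {
  m <- stent_steel_304()
  # single point: its own margin
  one <- stress_points(300, 20)
  expect_equal(shortest_distance(one, m)$distance,
               goodman_margin(300, 20, m)$distance)
  # a set containing one on-line point has zero shortest distance
  withline <- stress_points(c(300, 580), c(20, 0))
  expect_equal(shortest_distance(withline, m)$distance, 0)
  # 100 random safe points: equals the per-point minimum, worst node right
  set.seed(5)
  sm <- runif(100, 0, 400); sa <- runif(100, 0, 60)
  keep <- goodman_margin(sm, sa, m)$safe
  pts <- stress_points(sm[keep], sa[keep])
  sd <- shortest_distance(pts, m)
  margins <- goodman_margin(pts$sigma_m, pts$sigma_a, m)$distance
  expect_equal(sd$distance, min(margins))
  expect_equal(sd$worst_node, pts$node_id[which.min(margins)])
  expect_error(shortest_distance(stress_points(numeric(0), numeric(0)), m),
               "empty")
})

test_that("fatigue_objective orders designs by margin and penalizes violations", {
  m <- stent_steel_304()
  # evaluator returning an on-line point everywhere: objective 0 everywhere
  flat <- fatigue_objective(function(x) stress_points(580, 0), m)
  expect_equal(flat(c(0.3)), 0)
  expect_equal(flat(c(0.9)), 0)
  # toy model at its construction optimum attains the known maximal margin
  tm <- toy_fatigue_model()
  obj <- fatigue_objective(function(x) toy_fatigue_evaluate(tm, x), m)
  expect_equal(obj(tm$x_star), -tm$D_star, tolerance = 1e-9)
  corner <- tm$space$lower
  expect_gt(obj(corner), -tm$D_star)
  # any unsafe node makes the objective worse than every feasible value
  unsafe <- fatigue_objective(function(x) stress_points(c(300, 600), c(20, 50)), m)
  expect_gt(unsafe(c(0.5)), 0)
})

test_that("stress tables round-trip through CSV in both layouts", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(node_id = 1:3,
                              sigma_systolic = c(120, 330, 300),
                              sigma_diastolic = c(80, 280, 300)),
                   path, row.names = FALSE)
  pts <- read_stress_csv(path)
  expect_equal(pts$sigma_m, c(100, 305, 300))
  expect_equal(pts$sigma_a, c(20, 25, 0))

  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sigma_m = c(0.1, 0.2), sigma_a = c(0.01, 0.02)),
                   path2, row.names = FALSE)
  pts2 <- read_stress_csv(path2, unit = "GPa")
  expect_equal(pts2$sigma_m, c(100, 200))

  # Goodman-diagram export carries the two failure-line endpoints
  gp <- withr::local_tempfile(fileext = ".csv")
  write_goodman_csv(pts, stent_steel_304(), gp)
  g <- utils::read.csv(gp)
  line <- g[g$role == "failure_line", ]
  expect_equal(line$sigma_m, c(580, 0))
  expect_equal(line$sigma_a, c(0, 115))
})
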