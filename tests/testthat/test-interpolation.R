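test_that("the interpolant passes through every node exactly", {
  set.seed(4)
  for (rep in 1:5) {
    x <- sort(runif(8, -30, 500))
    y <- rnorm(8, 80, 10)
    f <- makima_fun(x, y)
    expect_equal(f(x), y, tolerance = 1e-12)
  }
})

test_that("straight lines are reproduced everywhere", {
  x <- c(-30, 15, 30, 50, 75, 100, 200, 500)
  y <- 2.5 * x + 7
  f <- makima_fun(x, y)
  grid <- seq(-30, 500, by = 0.5)
  expect_lt(max(abs(f(grid) - (2.5 * grid + 7))) / max(abs(y)), 1e-9)
  # flat data too (degenerate weights)
  g <- makima_fun(x, rep(3, 8))
  expect_equal(g(grid), rep(3, length(grid)), tolerance = 1e-12)
})

test_that("modified-Akima values match an independent implementation", {
  # frozen oracle: scipy.interpolate.Akima1DInterpolator(method = "makima")
  x1 <- c(-30, 15, 30, 50, 75, 100, 200, 500)
  y1 <- c(100, 75.9, 75.9, 80.2, 84.9, 87.8, 89.6, 89.7)
  q1 <- c(-10, 0, 22.5, 40, 60, 150, 350)
  e1 <- c(86.165779334605, 80.520468768384, 75.391223722075, 77.970803388563,
          82.220183005867, 89.021652440137, 89.992244714473)
  expect_equal(makima_fun(x1, y1)(q1), e1, tolerance = 1e-10)

  x2 <- c(0, 1, 2, 4, 7, 11)
  y2 <- c(0.5, -1.2, 3.4, 2.2, 2.2, -0.7)
  q2 <- c(0.5, 1.5, 3, 5.5, 9)
  e2 <- c(-1.070695674387, 1.373378116583, 2.804943373525, 2.260682486394,
          1.100973502304)
  expect_equal(makima_fun(x2, y2)(q2), e2, tolerance = 1e-10)
})

test_that("makima beats piecewise-linear interpolation on the smooth recovery profile", {
  cfg <- quiet_config(inertial_coefficient = 0)
  positions <- cfg$sensor_array$positions
  profile <- function(x) {
    # generator's axial shape for a known drop, downstream recovery branch
    drop <- 20
    sapply(x, function(xi) {
      s <- flowphantom:::axial_drop_shape(xi, cfg)
      cfg$upstream_baseline_pressure - drop * s
    })
  }
  y <- profile(positions)
  grid <- seq(38.1, 500, by = 0.5)  # recovery zone (past the jet core)
  truth <- profile(grid)
  err_mak <- max(abs(makima_fun(positions, y)(grid) - truth))
  err_lin <- max(abs(approx(positions, y, xout = grid)$y - truth))
  expect_lt(err_mak, err_lin)
})

test_that("degenerate spatial inputs are rejected", {
  expect_error(makima_fun(c(1, 1, 2, 3), c(0, 1, 2, 3)), "duplicate")
  expect_error(sensor_array(c(0, 10, 10, 20)), "strictly increasing")
  avg <- list(pressures = matrix(1:6, 2), phase_time = c(0, 0.1))
  expect_error(spatial_profile(avg, 0, sensor_array(c(0, 10, 20))), "at least 4")
})

test_that("spatial_profile evaluates the tracing at the snapped instant", {
  cfg <- quiet_config()
  rec <- simulate_recording(cfg, flow_condition("pulsatile", 250))
  avg <- ensemble_average(rec, segment_cycles(rec))
  f <- spatial_profile(avg, 0.07)
  i <- which.min(abs(avg$phase_time - 0.07))
  expect_equal(f(cfg$sensor_array$positions), as.numeric(avg$pressures[i, ]),
               tolerance = 1e-12)
})
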