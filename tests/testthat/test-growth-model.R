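test_that("growth curve matches its closed form at the printed examples", {
  up <- growth_curve(nu = 1, eta = 5, epsilon = 15, omega = 0.001)
  expect_equal(growth_rate(up, 10), 1.999)
  expect_equal(curve_extrema(up)$maximum, 1.999)
  expect_equal(curve_extrema(up)$infimum, -0.001)
  expect_equal(curve_extrema(up)$argmax, 10)

  sym <- growth_curve(nu = 1, eta = 5, epsilon = 15, omega = 1)
  expect_equal(growth_rate(sym, 5), 0, tolerance = 1e-12)
  expect_equal(growth_rate(sym, 10), 1)
  expect_lt(abs(growth_rate(sym, 1e6) - (-1)), 1e-9)
  expect_equal(curve_extrema(sym)$maximum, 1)
  expect_equal(curve_extrema(sym)$infimum, -1)
})

test_that("growth rate has the required sign pattern and zero crossings", {
  set.seed(42)
  for (k in 1:25) {
    eta <- runif(1, 0.5, 10)
    eps <- eta + runif(1, 0.5, 20)
    om <- runif(1, 0.01, 1.9)
    nu <- runif(1, 0.1, 5)
    gc <- growth_curve(nu, eta, eps, om)
    expect_lt(abs(growth_rate(gc, eta)), 1e-9)
    expect_lt(abs(growth_rate(gc, eps)), 1e-9)
    inside <- seq(eta, eps, length.out = 41)[2:40]
    outside_lo <- seq(0, eta, length.out = 11)[1:10]
    outside_hi <- seq(eps * 1.0001, eps * 10, length.out = 20)
    expect_true(all(growth_rate(gc, inside) > 0))
    expect_true(all(growth_rate(gc, outside_lo) < 0))
    expect_true(all(growth_rate(gc, outside_hi) < 0))
  }
})

test_that("analytic extrema agree with a dense grid search", {
  set.seed(7)
  for (k in 1:10) {
    eta <- runif(1, 1, 10)
    eps <- eta + runif(1, 1, 15)
    gc <- growth_curve(runif(1, 0.1, 3), eta, eps, runif(1, 0.01, 1.9))
    grid <- seq(0, 10 * eps, length.out = 1e5)
    vals <- growth_rate(gc, grid)
    ex <- curve_extrema(gc)
    expect_lt(max(vals) - ex$maximum, 1e-6)
    expect_equal(grid[which.max(vals)], ex$argmax, tolerance = 1e-3)
    # infimum is asymptotic: the grid never goes below it
    expect_gt(min(vals), ex$infimum - 1e-9)
  }
})

test_that("invalid curve parameters are rejected at construction", {
  expect_error(growth_curve(1, 5, 5, 1), "eta")
  expect_error(growth_curve(1, 6, 5, 1), "eta")
  expect_error(growth_curve(1, 5, 15, 2), "omega")
  expect_error(growth_curve(1, 5, 15, 0), "omega")
  expect_error(growth_curve(-1, 5, 15, 1))
})

test_that("constant curves sprout independently of activity", {
  gc <- growth_curve(0.25, constant = TRUE)
  expect_equal(growth_rate(gc, c(0, 1, 100)), rep(0.25, 3))
})

test_that("calcium decays exponentially and jumps by beta per spike", {
  tr <- calcium_trace(ca = 1, beta = 0.1, tau_ca = 50)
  tr2 <- update_calcium(tr, n_spikes = 0, dt = 50)
  expect_equal(tr2$ca, exp(-1), tolerance = 1e-12)
  tr3 <- update_calcium(calcium_trace(0), n_spikes = 1, dt = 0)
  expect_equal(tr3$ca, 0.1)
  expect_error(update_calcium(tr, dt = -1), "non-negative")
})

test_that("calcium under Poisson spiking averages to beta * rate * tau", {
  set.seed(11)
  dt <- 0.01
  rate <- 10
  n_steps <- 2e5 # 2000 s
  spikes <- stats::rpois(n_steps, rate * dt)
  dec <- exp(-dt / 50)
  ca <- numeric(n_steps)
  cur <- 0
  for (i in seq_len(n_steps)) {
    cur <- cur * dec + spikes[i] * 0.1
    ca[i] <- cur
  }
  expect_equal(mean(ca[-(1:3e4)]), 0.1 * rate * 50, tolerance = 0.02)
})

test_that("element integration follows the curve and clamps at zero", {
  pool <- element_pool("pre_exc", z = 2)
  const <- growth_curve(0.5, constant = TRUE)
  out <- integrate_elements(pool, const, ca = 1, n_steps = 3, dt = 1)
  expect_equal(out$z, 3.5)

  gc <- growth_curve(1, 5, 15, 1)
  fixed <- integrate_elements(element_pool("post_exc", z = 2), gc, ca = 5,
                              n_steps = 10)
  expect_equal(fixed$z, 2)

  hi <- integrate_elements(element_pool("post_exc", z = 0), gc, ca = 1e5,
                           n_steps = 100)
  expect_equal(hi$z, 0)
})

test_that("harvest, decay and loss match independent floor arithmetic", {
  p <- harvest_free_elements(element_pool("pre_exc", z = 5.7,
                                          z_connected = 3))
  expect_identical(p$z_free, 2L)
  expect_identical(
    harvest_free_elements(element_pool("pre_exc", z = 3,
                                       z_connected = 3))$z_free, 0L)

  d <- decay_free_elements(element_pool("pre_exc", z = 100, z_free = 100))
  expect_identical(d$z_free, 99L)
  expect_identical(decay_free_elements(
    element_pool("pre_exc", z_free = 0))$z_free, 0L)
  expect_identical(decay_free_elements(
    element_pool("pre_exc", z = 50, z_free = 50))$z_free, 49L)

  expect_identical(count_losses(element_pool("post_inh", z = 2.3,
                                             z_connected = 4)), 1L)
  expect_identical(count_losses(element_pool("post_inh", z = 4,
                                             z_connected = 4)), 0L)

  set.seed(5)
  z <- runif(500, 0, 40)
  zc <- sample(0:40, 500, replace = TRUE)
  for (i in seq_along(z)) {
    pool <- element_pool("post_exc", z = z[i], z_connected = zc[i])
    expect_identical(harvest_free_elements(pool)$z_free,
                     as.integer(max(0, floor(z[i] - zc[i]))))
    expect_identical(count_losses(pool),
                     as.integer(max(0, floor(zc[i] - z[i]))))
    zf <- zc[i]
    expect_identical(decay_free_elements(
      element_pool("post_exc", z = z[i] + zf, z_free = zf))$z_free,
      as.integer(floor(zf - 0.01 * zf)))
  }
})
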