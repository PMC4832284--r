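test_that("gaussian_bump evaluates a truncated Gaussian on the sample grid", {
  # zero-amplitude burst is a degenerate no-event
  z <- gaussian_bump(sn_burst(10, 0, 0.3), fs = 10, n_samples = 600)
  expect_true(all(z$values == 0))

  # unit bump centred on a grid point peaks at exactly 1
  b <- gaussian_bump(sn_burst(30, 1, 0.3), fs = 10, n_samples = 600)
  expect_identical(max(b$values), 1)
  expect_equal(b$values[301], 1)

  # truncation at 4 SD: zero outside, positive inside
  tt <- sc_times(b)
  expect_true(all(b$values[abs(tt - 30) > 1.2] == 0))
  expect_true(all(b$values[abs(tt - 30) < 1.19] > 0))

  # discrete mass matches the quadrature oracle of the truncated Gaussian
  oracle <- stats::integrate(function(t) exp(-(t - 30)^2 / (2 * 0.3^2)),
                             30 - 1.2, 30 + 1.2)$value
  expect_equal(sum(b$values) / 10, oracle, tolerance = 1e-4)
  expect_equal(oracle, 0.3 * sqrt(2 * pi), tolerance = 1e-4)

  expect_error(gaussian_bump(sn_burst(10, 1, -0.3), 10, 600), "positive")
  expect_error(sn_burst(10, -1, 0.3), "nonnegative")
})

test_that("canonical response is calibrated to a 1 uS unit-burst peak", {
  p <- default_params()
  for (fs in c(10, 100)) {
    r <- canonical_response(p, fs = fs, horizon = 60)
    expect_equal(max(r$values), 1, tolerance = 1e-3)
    expect_true(all(r$values >= -1e-12))
    expect_lt(r$values[length(r$values)], 1e-3)
  }
})

test_that("canonical response matches a tight-step ODE integration oracle", {
  skip_if_not_installed("deSolve")
  p <- default_params()
  tau <- p$time_constants
  bump <- function(t) exp(-t^2 / (2 * p$burst_sd^2)) *
    (abs(t) <= 4 * p$burst_sd)
  deriv <- function(t, x, parms) {
    list(c((bump(t) - x[1]) / tau[1],
           (x[1] - x[2]) / tau[2],
           (x[2] - x[3]) / tau[3]))
  }
  tt <- (0:599) / 10
  sol <- deSolve::ode(y = c(0, 0, 0), times = c(-1.2, tt), func = deriv,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  y_ode <- sol[-1, 4]
  y_ode <- y_ode / max(y_ode)    # same unit-peak calibration
  r <- canonical_response(p, fs = 10, horizon = 60)
  expect_lt(y_ode[length(y_ode)], 1e-3)                # tail decays
  expect_lt(abs(which.max(r$values) - which.max(y_ode)), 2)
  expect_lt(max(abs(r$values - y_ode)), 0.05)          # coarse-grid shape

  # at 100 Hz the hold-step error of the discretization is ~100x smaller
  tt2 <- (0:5999) / 100
  sol2 <- deSolve::ode(y = c(0, 0, 0), times = c(-1.2, tt2), func = deriv,
                       parms = NULL, rtol = 1e-10, atol = 1e-12)
  y2 <- sol2[-1, 4]
  y2 <- y2 / max(y2)
  r2 <- canonical_response(p, fs = 100, horizon = 60)
  expect_lt(max(abs(r2$values - y2)), 0.005)
})

test_that("simulate_sc is linear, time-invariant and nonnegative", {
  p <- default_params()
  expect_equal(simulate_sc(list(), p, 60, 10)$values, rep(0, 600))

  one <- simulate_sc(list(sn_burst(20, 1)), p, 60, 10)
  expect_equal(max(one$values), 1, tolerance = 1e-3)

  # superposition: joint render equals sum of single-burst renders
  b1 <- sn_burst(12.3, 0.7)
  b2 <- sn_burst(33.8, 1.6)
  joint <- simulate_sc(list(b1, b2), p, 60, 10)$values
  parts <- simulate_sc(list(b1), p, 60, 10)$values +
    simulate_sc(list(b2), p, 60, 10)$values
  expect_lt(max(abs(joint - parts)) / max(parts), 1e-10)

  # scaling the burst scales the response
  half <- simulate_sc(list(sn_burst(12.3, 0.35)), p, 60, 10)$values
  expect_equal(half * 2, simulate_sc(list(b1), p, 60, 10)$values,
               tolerance = 1e-12)

  # time invariance: shifting the onset by k samples shifts the output
  sh <- simulate_sc(list(sn_burst(15.3, 0.7)), p, 60, 10)$values
  base <- simulate_sc(list(b1), p, 60, 10)$values
  k <- 30  # 3 s at 10 Hz
  expect_lt(max(abs(sh[(k + 1):600] - base[1:(600 - k)])), 1e-9)

  # nonnegativity for positive bursts, including tails entering the window
  neg <- simulate_sc(list(sn_burst(-3, 1.5), sn_burst(59.5, 2)), p, 60, 10)
  expect_true(all(neg$values >= -1e-12))
})

test_that("bursts before the window contribute their within-window tail", {
  p <- default_params()
  tail_in <- simulate_sc(list(sn_burst(-3, 1)), p, 60, 10)$values
  expect_gt(max(tail_in), 0.1)       # the response tail is present
  expect_lt(which.max(tail_in), 50)  # and decaying from the window start
  expect_true(all(diff(tail_in[30:600]) <= 1e-12))
})

test_that("invalid forward-model parameters are rejected", {
  expect_error(scrf_params(time_constants = c(1, -1, 2)), "positive")
  expect_error(scrf_params(gain = -2), "auto")
  expect_error(scrf_params(burst_sd = 0), "positive")
  expect_error(sc_signal(c(1, NA), 10), "finite")
  expect_error(sc_signal(numeric(0), 10), "at least one")
})
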