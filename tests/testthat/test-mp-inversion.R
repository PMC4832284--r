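test_that("dictionary covers -9 s to data offset + 1 s in 0.1-s steps", {
  d <- dict60()
  expect_length(d$onsets, 701)
  expect_equal(d$onsets[1], -9)
  expect_equal(d$onsets[701], 61)
  expect_true(all(diff(d$onsets) > 0))
  expect_equal(unique(round(diff(d$onsets), 10)), 0.1)
  expect_true(all(d$norms > 0))
  expect_true(all(d$atoms >= -1e-12))
  expect_error(build_dictionary(0, 10), ">= 1")
})

test_that("each atom is the within-window unit-burst response", {
  d <- dict60()
  p <- default_params()
  for (on in c(-5, 0.3, 30, 59.9, 61)) {
    k <- which(abs(d$onsets - on) < 1e-9)
    ref <- simulate_sc(list(sn_burst(on, 1)), p, 60, 10)$values
    expect_lt(max(abs(d$atoms[, k] - ref)), 1e-10)
  }
  # interior atoms are single-peaked
  a <- d$atoms[, which(d$onsets == 30)]
  pk <- which.max(a)
  expect_true(all(diff(a[1:pk]) >= -1e-12))
  expect_true(all(diff(a[pk:600]) <= 1e-12))
})

test_that("mp_search recovers a scaled atom and stops on the residual rule", {
  d <- dict60()
  y <- sc_signal(0.5 * d$atoms[, which(d$onsets == 30)], 10)
  res <- mp_search(y, d)
  expect_equal(res$selected_onsets, 30)
  expect_equal(res$greedy_coefficients, 0.5, tolerance = 1e-10)
  expect_equal(res$stop_reason, "residual_below_eps")
  # brute-force confirmation of the first argmax
  o <- oracle_mp_step(d$atoms, d$norms, y$values)
  expect_equal(d$onsets[o$j], 30)
  expect_equal(o$a, 0.5, tolerance = 1e-10)
})

test_that("stopping rules: zero data, negated atom, epsilon arithmetic", {
  d <- dict60()
  z <- mp_search(sc_signal(rep(0, 600), 10), d)
  expect_equal(z$n_iterations, 0L)
  expect_equal(z$stop_reason, "residual_below_eps")
  expect_equal(z$eps, sqrt(0.6))

  neg <- mp_search(sc_signal(-d$atoms[, which(d$onsets == 30)], 10), d)
  expect_equal(neg$n_iterations, 0L)
  expect_length(neg$selected_onsets, 0)
  expect_equal(neg$stop_reason, "nonpositive_coefficient")

  expect_equal(z$max_iter, 30)  # ceiling(30 * 60 s / 60)
  d45 <- build_dictionary(450, 10, default_params())
  m <- mp_search(sc_signal(rep(0, 450), 10), d45)
  expect_equal(m$max_iter, 23)  # ceiling(30 * 0.75 min)
  expect_error(mp_search(sc_signal(rep(0, 599), 10), d), "grid")
})

test_that("greedy selection equals the brute-force argmax and the residual
           norm decreases strictly", {
  d <- small_dict(40)
  set.seed(401)
  for (rep in 1:10) {
    w <- runif(5, 0.2, 1.5)
    at <- sample(ncol(d$atoms), 5)
    y <- drop(d$atoms[, at] %*% w) + rnorm(300, sd = 0.05)
    res <- mp_search(sc_signal(y, 10), d)
    expect_gt(res$n_iterations, 0)
    r <- y
    prev <- sqrt(sum(r^2))
    for (i in seq_len(res$n_iterations)) {
      o <- oracle_mp_step(d$atoms, d$norms, r)
      expect_equal(d$onsets[o$j], res$selected_onsets[i])
      expect_equal(o$a, res$greedy_coefficients[i], tolerance = 1e-10)
      r <- r - o$a * d$atoms[, o$j]
      expect_lt(sqrt(sum(r^2)), prev)
      prev <- sqrt(sum(r^2))
    }
    expect_equal(prev, tail(res$residual_norms, 1), tolerance = 1e-8)
  }
})

test_that("inner products agree with naive summation", {
  d <- small_dict(20)
  set.seed(17)
  r <- rnorm(300)
  ip <- drop(crossprod(d$atoms, r))
  for (j in seq(1, 20, by = 4))
    expect_lt(abs(ip[j] - naive_ip(d$atoms[, j], r)), 1e-10)
})

test_that("amplitude reestimation matches the normal-equations oracle", {
  d <- dict60()
  p <- default_params()
  # non-overlapping atoms: exact recovery
  y <- simulate_sc(data.frame(onset = c(10, 40), amplitude = c(0.5, 1.2)),
                   p, 60, 10)
  w <- reestimate_amplitudes(y, d, c(10, 40))
  expect_equal(as.numeric(w), c(0.5, 1.2), tolerance = 1e-8)
  expect_false(attr(w, "rank_deficient"))

  # orthogonality of the regression residual to every selected predictor
  X <- d$atoms[, match(c(10, 40), d$onsets)]
  resid <- y$values - drop(X %*% w)
  expect_lt(max(abs(crossprod(X, resid))),
            1e-8 * sqrt(sum(y$values^2)))

  # single atom: univariate closed form
  g <- d$atoms[, which(d$onsets == 25)]
  y1 <- sc_signal(0.8 * g + 0.01 * sin(1:600), 10)
  w1 <- reestimate_amplitudes(y1, d, 25)
  expect_equal(as.numeric(w1), sum(g * y1$values) / sum(g^2), tolerance = 1e-10)

  # overlapping atoms: greedy mis-splits, regression recovers the truth
  y2 <- simulate_sc(data.frame(onset = c(30, 31.5), amplitude = c(1, 0.8)),
                    p, 60, 10)
  res <- mp_search(y2, d)
  expect_gt(max(abs(sort(res$greedy_coefficients[1:2]) - c(0.8, 1))), 0.05)
  w2 <- reestimate_amplitudes(y2, d, c(30, 31.5))
  expect_equal(as.numeric(w2), c(1, 0.8), tolerance = 1e-6)
  Xo <- d$atoms[, match(c(30, 31.5), d$onsets)]
  expect_equal(as.numeric(w2), oracle_lsq(Xo, y2$values), tolerance = 1e-8)

  # duplicated onsets are merged into one predictor
  wd <- reestimate_amplitudes(y1, d, c(25, 25, 25))
  expect_length(wd, 1)
  expect_error(reestimate_amplitudes(y1, d, numeric(0)), "at least one")
})

test_that("count_sf applies the amplitude threshold per minute of data", {
  cfg <- mp_config()
  expect_equal(count_sf(c(0.05, 0.15, 0.30), cfg, 60)$count, 2L)
  expect_equal(count_sf(c(0.05, 0.15, 0.30), cfg, 60)$rate_per_min, 2)
  expect_equal(count_sf(numeric(0), cfg, 60)$count, 0L)
  expect_equal(count_sf(numeric(0), cfg, 60)$rate_per_min, 0)
  cfg0 <- mp_config(amp_threshold = 0)
  expect_equal(count_sf(c(0.01, 0.2, 0.4), cfg0, 120)$count, 3L)
  expect_equal(count_sf(c(0.01, 0.2), cfg0, 120)$rate_per_min, 1)
})

test_that("conduction delay shifts reported onsets", {
  expect_equal(report_sf_onsets(c(10, 20), 0), c(10, 20))
  expect_equal(report_sf_onsets(c(10, 20), 1), c(9, 19))
  expect_error(report_sf_onsets(10, -1), ">= 0")
})

test_that("noiseless single-SF traces are recovered exactly", {
  d <- dict60()
  p <- default_params()
  set.seed(88)
  for (i in 1:25) {
    a <- runif(1, 0.1, 2)
    on <- runif(1, 5, 55)
    y <- simulate_sc(data.frame(onset = on, amplitude = a), p, 60, 10)
    est <- estimate_sf(y, p, dictionary = d)
    expect_equal(est$count, 1L)
    expect_lte(abs(est$onsets - on), 0.1 + 1e-9)
    amp <- est$amplitudes[est$amplitudes >= est$threshold]
    expect_lt(abs(amp[1] - a) / a, 0.01)
  }
})

test_that("regression reestimation never fits worse than the greedy pass", {
  d <- dict60()
  p <- default_params()
  set.seed(92)
  sp <- sim_spec(target_rate = 8)
  for (i in 1:5) {
    tr <- simulate_trace(sp, p)
    res <- mp_search(tr$signal, d)
    w <- reestimate_amplitudes(tr$signal, d, res$selected_onsets)
    X <- d$atoms[, match(attr(w, "onsets"), d$onsets), drop = FALSE]
    rss_reg <- sum((tr$signal$values - drop(X %*% w))^2)
    expect_lte(rss_reg, sum(res$residual$values^2) + 1e-10)
  }
})
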