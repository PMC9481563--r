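test_that("initial rate is the OLS slope over the leading points", {
  t <- seq(0, 590, by = 10)
  lin <- kinetic_trace(t, 5 + 0.5 * t)
  r <- initial_rate(lin, 30)
  expect_equal(r$rate, 0.5, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  flat <- kinetic_trace(t, rep(7, length(t)))
  expect_equal(initial_rate(flat, 30)$rate, 0)
  set.seed(5)
  noisy <- kinetic_trace(t, 0.5 * t + rnorm(length(t), 0, 0.1))
  rn <- initial_rate(noisy, 30)
  expect_lt(abs(rn$rate - 0.5), 3 * rn$std_error)
  expect_error(initial_rate(kinetic_trace(0:9, 0:9), 30), "need 30")
})

test_that("Michaelis-Menten velocity honours the half-saturation identity", {
  v_half <- mm_velocity(20, kcat = 10, km = 20, enzyme_total = 5)
  vmax <- 10 * 5 / 1000
  expect_equal(v_half, vmax / 2, tolerance = 1e-12)
})

test_that("MM fit recovers noiseless and noisy parameters", {
  s <- 100 * (1 / 2)^(0:7)
  v <- mm_velocity(s, kcat = 10, km = 20, enzyme_total = 2.5)
  fit <- fit_michaelis_menten(s, v, 2.5)
  expect_true(fit$converged && fit$identifiable)
  expect_equal(fit$kcat, 10, tolerance = 1e-3)
  expect_equal(fit$km, 20, tolerance = 1e-3)
  expect_equal(fit$vmax, fit$kcat * 2.5 / 1000, tolerance = 1e-9)
  set.seed(31)
  vn <- v * (1 + rnorm(length(v), 0, 0.05))
  fitn <- fit_michaelis_menten(s, vn, 2.5)
  expect_lt(abs(fitn$kcat / 10 - 1), 0.25)
  expect_lt(abs(fitn$km / 20 - 1), 0.25)
})

test_that("MM fit flags the unidentifiable linear regime", {
  s <- seq(0.1, 1, length.out = 6)  # all far below Km = 500
  v <- mm_velocity(s, kcat = 10, km = 500, enzyme_total = 2.5)
  fit <- fit_michaelis_menten(s, v, 2.5)
  expect_false(fit$identifiable)
})

test_that("integrated progress curve matches an independent ODE solution", {
  set.seed(13)
  for (i in 1:5) {
    kcat <- 10^runif(1, -1, 1); km <- 10^runif(1, 0, 3)
    e <- 10^runif(1, 0, 2); s0 <- 10^runif(1, 0, 2.5)
    times <- seq(0, 5 * km * 1000 / (kcat * e) + 100, length.out = 40)
    tr <- simulate_progress_curve(kcat, km, e, s0, times)
    ode <- deSolve::lsoda(
      c(S = s0), times,
      function(t, y, p) list(-kcat * (e / 1000) * y / (km + y)),
      parms = NULL, rtol = 1e-10, atol = 1e-12)
    s_closed <- s0 * (1 - tr$signal / 100)
    expect_lt(max(abs(s_closed - ode[, "S"])), 1e-6 * s0)
  }
})

test_that("progress curves are monotone, bounded and start at zero product", {
  tr <- simulate_progress_curve(1, 200, 25, 50, seq(0, 7200, 60))
  expect_equal(tr$signal[1], 0)
  expect_true(all(diff(tr$signal) >= -1e-12))
  expect_true(all(tr$signal >= 0 & tr$signal <= 100))
})

test_that("first-order limit reduces to a single exponential", {
  # S0 << Km: S(t)/S0 should equal exp(-kcat E t / Km) within 1% over
  # five half-lives
  kcat <- 2; km <- 5000; e <- 100; s0 <- 10
  k1 <- kcat * (e / 1000) / km
  times <- seq(0, 5 * log(2) / k1, length.out = 50)
  tr <- simulate_progress_curve(kcat, km, e, s0, times)
  s_frac <- 1 - tr$signal / 100
  expect_lt(max(abs(s_frac - exp(-k1 * times))), 0.01)
})

test_that("progress curves are invariant under (kcat/a, a*E)", {
  times <- seq(0, 3600, 30)
  base <- simulate_progress_curve(1, 200, 25, 50, times)
  for (a in c(4, 40)) {
    scaled <- simulate_progress_curve(1 / a, 200, a * 25, 50, times)
    expect_equal(scaled$signal, base$signal, tolerance = 1e-12)
  }
})

test_that("exponential progress fit recovers exact and near-first-order data", {
  t <- seq(0, 600, 10)
  exact <- kinetic_trace(t, 100 * (1 - exp(-0.01 * t)))
  fe <- fit_exponential_progress(exact)
  expect_equal(fe$amplitude, 100, tolerance = 1e-6)
  expect_equal(fe$k_obs, 0.01, tolerance = 1e-6)
  # integrated MM with S0 = 50, Km = 500: k_obs ~ kcat E / Km within 10%
  kcat <- 1; km <- 500; e <- 100; s0 <- 50
  k1 <- kcat * (e / 1000) / km
  times <- seq(0, 4 / k1, length.out = 60)
  tr <- simulate_progress_curve(kcat, km, e, s0, times)
  fmm <- fit_exponential_progress(tr)
  expect_lt(abs(fmm$k_obs / k1 - 1), 0.10)
  flat <- kinetic_trace(t, rep(0, length(t)))
  ff <- fit_exponential_progress(flat)
  expect_equal(ff$amplitude, 0)
  expect_false(ff$identifiable)
})

test_that("enzyme-matching multiplier equals the kcat ratio", {
  times <- seq(0, 7200, 60)
  wt <- list(kcat = 1, km = 200)
  expect_equal(match_enzyme_concentration(wt, list(kcat = 1 / 4, km = 200),
                                          25, 50, times), 4,
               tolerance = 1e-3 / 4)
  expect_equal(match_enzyme_concentration(wt, list(kcat = 1 / 40, km = 200),
                                          25, 50, times), 40,
               tolerance = 1e-3 / 40)
  expect_equal(match_enzyme_concentration(wt, wt, 25, 50, times), 1,
               tolerance = 1e-6)
})

test_that("trace CSV reader validates its input", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("time_s,signal", "0,0", "10,5", "20,bad"), p)
  expect_error(read_trace_csv(p), "line 3")
  writeLines(c("t,y", "0,0"), p)
  expect_error(read_trace_csv(p), "missing column")
})
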