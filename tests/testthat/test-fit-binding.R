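make_direct_series <- function(kd = 50, noise_sd = 0, seed = 1,
                               p_free = 60, p_bound = 260, probe = 100,
                               top = 10000, n = 12, reps = 3, dil = 2 / 3) {
  conc <- top * dil^(0:(n - 1))
  mu <- polarization_signal(fraction_bound_direct(conc, probe, kd),
                            p_free, p_bound)
  set.seed(seed)
  readings <- mu + matrix(rnorm(n * reps, 0, noise_sd), nrow = n)
  titration_series(conc, readings, mode = "direct",
                   fixed_components = list(probe_total = probe))
}

test_that("noiseless direct titration is recovered essentially exactly", {
  fit <- fit_direct_titration(make_direct_series(kd = 50, noise_sd = 0))
  expect_true(fit$converged)
  expect_equal(fit$kd, 50, tolerance = 1e-3)
  expect_equal(fit$p_free, 60, tolerance = 1e-3)
  expect_equal(fit$p_bound, 260, tolerance = 1e-3)
})

test_that("noisy direct titration recovers Kd within its own CI and 20%", {
  fit <- fit_direct_titration(make_direct_series(kd = 50, noise_sd = 2,
                                                 seed = 42))
  expect_true(fit$converged)
  tq <- qt(0.975, fit$n_obs - 3)
  ci <- fit$kd + c(-1, 1) * tq * fit$std_errors[["kd"]]
  expect_true(ci[1] <= 50 && 50 <= ci[2])
  expect_lt(abs(fit$kd / 50 - 1), 0.20)
})

test_that("constant readings are reported as non-identifiable, not fitted", {
  s <- titration_series(10 * 2^(0:7), matrix(100, nrow = 8, ncol = 3),
                        mode = "direct",
                        fixed_components = list(probe_total = 100))
  fit <- fit_direct_titration(s)
  expect_false(fit$converged)
  expect_match(fit$message, "identifiable")
})

make_comp_series <- function(kd_comp = 200, noise_sd = 0, seed = 1,
                             probe_kd = 100, probe = 100, sat = 0.65,
                             p_free = 60, p_bound = 260, n = 12, reps = 3) {
  sc <- assay_scenario("tmp",
                       ground_truth = list(probe_kd = probe_kd,
                                           kd_tight = kd_comp,
                                           kd_weak = kd_comp),
                       assay_design = list(noise_sd = noise_sd,
                                           saturation = sat,
                                           p_free = p_free,
                                           p_bound = p_bound,
                                           n_points = n,
                                           n_replicates = reps),
                       seed = seed)
  gen_competitive_titration(sc, which = "tight", seed = seed)
}

test_that("noiseless competitive titration recovers the competitor Kd", {
  fit <- fit_competitive_titration(make_comp_series(kd_comp = 200,
                                                    noise_sd = 0))
  expect_true(fit$converged)
  expect_equal(fit$kd, 200, tolerance = 1e-3)
})

test_that("noisy competitive titration recovers Kd within 20%", {
  fit <- fit_competitive_titration(make_comp_series(kd_comp = 200,
                                                    noise_sd = 2, seed = 9))
  expect_true(fit$converged)
  expect_lt(abs(fit$kd / 200 - 1), 0.20)
})

test_that("competitive fit demands a probe Kd and non-degenerate competitor", {
  s <- make_comp_series()
  s$fixed_components$probe_kd <- NULL
  expect_error(titration_series(s$varied_conc, s$readings,
                                mode = "competitive",
                                fixed_components = s$fixed_components),
               "probe_kd")
  s2 <- make_comp_series()
  s2$varied_conc[] <- 0
  expect_error(fit_competitive_titration(s2), "identifiable")
})

test_that("predicted competitive signal decreases with competitor", {
  s <- make_comp_series(kd_comp = 200, noise_sd = 0)
  mu <- rowMeans(s$readings)
  expect_true(all(diff(mu) <= 1e-9))
})

test_that("fold change is the Kd ratio with reciprocal symmetry", {
  fit_w <- fit_direct_titration(make_direct_series(kd = 4900))
  fit_t <- fit_direct_titration(make_direct_series(kd = 100))
  f <- kd_fold_change(fit_w, fit_t)
  expect_equal(f$ratio, 49, tolerance = 1e-3)
  expect_equal(kd_fold_change(fit_t, fit_w)$ratio * f$ratio, 1,
               tolerance = 1e-6)
  expect_equal(kd_fold_change(fit_t, fit_t)$ratio, 1)
  bad <- fit_w; bad$converged <- FALSE
  expect_error(kd_fold_change(bad, fit_t), "converged")
})

test_that("titration CSV round-trips and the fit report is valid JSON", {
  s <- make_direct_series(noise_sd = 1, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_titration_csv(s, path)
  s2 <- read_titration_csv(path, mode = "direct",
                           fixed_components = list(probe_total = 100))
  expect_equal(s2$varied_conc, s$varied_conc)
  expect_equal(unname(s2$readings), unname(s$readings), tolerance = 1e-12)
  fit <- fit_direct_titration(s2)
  rp <- tempfile(fileext = ".json")
  write_fit_report(fit, rp)
  parsed <- jsonlite::read_json(rp)
  expect_equal(parsed$parameters$kd_nM, fit$kd, tolerance = 1e-9)
  expect_true(parsed$converged)
})
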