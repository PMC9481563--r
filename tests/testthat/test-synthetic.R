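test_that("generators are deterministic functions of the seed", {
  sc <- binding_scenarios()$shp2_irs1
  a <- gen_direct_titration(sc, seed = 12)
  b <- gen_direct_titration(sc, seed = 12)
  expect_identical(a, b)
  c_ <- gen_direct_titration(sc, seed = 13)
  expect_false(identical(a$readings, c_$readings))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(gen_direct_titration(sc, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("noiseless direct titrations equal the quadratic model exactly", {
  sc <- noiseless(binding_scenarios()$shp2_irs1)
  s <- gen_direct_titration(sc)
  mu <- polarization_signal(
    fraction_bound_direct(s$varied_conc, 100, 100), 60, 260)
  expect_equal(unname(s$readings[, 1]), mu, tolerance = 1e-12)
  expect_equal(s$readings[, 1], s$readings[, 3])
})

test_that("competitive generator hits the configured probe saturation", {
  sc <- noiseless(binding_scenarios()$shp2_cd28)
  s <- gen_competitive_titration(sc, which = "tight")
  fc <- s$fixed_components
  st <- solve_competitive_analytic(fc$receptor_total, fc$probe_total, 0,
                                   fc$probe_kd, 1)
  expect_equal(st$receptor_probe / fc$probe_total, 0.65, tolerance = 1e-6)
  # and out-of-range saturation targets are rejected
  bad <- sc; bad$assay_design$saturation <- 0.95
  expect_error(gen_competitive_titration(bad, "tight"), "0.5, 0.8")
})

test_that("noiseless competitive series refit to the exact competitor Kd", {
  sc <- noiseless(binding_scenarios()$ptp1b_irs1)
  for (w in c("weak", "tight")) {
    s <- gen_competitive_titration(sc, which = w)
    fit <- fit_competitive_titration(s)
    truth <- sc$ground_truth[[paste0("kd_", w)]]
    expect_equal(fit$kd, truth, tolerance = 1e-4)
  }
})

test_that("noiseless 1:4:40 progress curves superimpose", {
  sc <- kinetics_scenarios()$shp2_ce
  sc$assay_design$noise_sd <- 0
  curves <- gen_progress_curves(
    sc, enzyme_multipliers = c(wt = 1, h426a = 4, d425a = 40))
  expect_equal(curves$h426a$signal, curves$wt$signal, tolerance = 1e-12)
  expect_equal(curves$d425a$signal, curves$wt$signal, tolerance = 1e-12)
  # without equalization the mutants lag the wild type
  plain <- gen_progress_curves(sc)
  expect_true(all(plain$d425a$signal <= plain$wt$signal + 1e-9))
  expect_lt(max(plain$d425a$signal), max(plain$wt$signal))
})

test_that("noisy progress curves stay in range and refit their rate", {
  sc <- kinetics_scenarios()$shp2_ce
  curves <- gen_progress_curves(sc, seed = 4)
  tr <- curves$wt
  expect_true(all(tr$signal >= 0 & tr$signal <= 100))
  fit <- fit_exponential_progress(tr)
  # round trip: the noisy fit should sit within 3 SE of the fit to the
  # noiseless curve (the exponential is itself an approximation of the
  # integrated Michaelis-Menten form, so the noiseless fit is the truth here)
  sc0 <- sc; sc0$assay_design$noise_sd <- 0
  ref <- fit_exponential_progress(gen_progress_curves(sc0)$wt)
  expect_lt(abs(fit$k_obs - ref$k_obs), 3 * fit$std_errors[["k_obs"]])
  expect_lt(abs(fit$amplitude - ref$amplitude),
            3 * fit$std_errors[["amplitude"]])
})

test_that("fluorogenic rate tables are exact when noise-free and refit when noisy", {
  sc <- kinetics_scenarios()$shp2_difmup
  sc0 <- noiseless(sc)
  tab0 <- gen_difmup_rates(sc0, "wt")
  expect_equal(tab0$rate,
               mm_velocity(tab0$substrate_uM, 5, 30, 2.5), tolerance = 1e-12)
  expect_identical(gen_difmup_rates(sc, "d425a", seed = 2),
                   gen_difmup_rates(sc, "d425a", seed = 2))
  tab <- gen_difmup_rates(sc, "wt", seed = 6)
  fit <- fit_michaelis_menten(tab$substrate_uM, tab$rate,
                              attr(tab, "enzyme_total"))
  expect_lt(abs(fit$kcat / 5 - 1), 0.25)
  expect_lt(abs(fit$km / 30 - 1), 0.25)
})

test_that("proteome generator plants recoverable motifs deterministically", {
  a <- gen_proteome_with_motifs(10, c(100, 150),
                                planted = c("Y..M[ST]P" = 4), seed = 3)
  b <- gen_proteome_with_motifs(10, c(100, 150),
                                planted = c("Y..M[ST]P" = 4), seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(a$truth), 4L)
  hits <- scan_sequences(a$sequences)
  expect_true(all(paste(a$truth$protein_id, a$truth$tyr_position) %in%
                    paste(hits$protein_id, hits$tyr_position)))
  # with nothing planted, hits are exactly the brute-force chance matches
  bg <- gen_proteome_with_motifs(15, c(100, 200), seed = 8)
  hits_bg <- scan_sequences(bg$sequences)
  bf <- brute_force_hits(bg$sequences, names(default_consensus_patterns()))
  expect_setequal(paste(hits_bg$protein_id, hits_bg$tyr_position),
                  unique(paste(bf$protein_id, bf$tyr_position)))
})

test_that("FASTA round-trips through the writer and the scanner input path", {
  prot <- gen_proteome_with_motifs(4, c(60, 80),
                                   planted = c("Y..M[ST]P" = 2), seed = 14)
  fa <- tempfile(fileext = ".fasta")
  write_fasta(prot$sequences, fa)
  hits_file <- scan_sequences(fa)
  hits_mem <- scan_sequences(prot$sequences)
  expect_equal(hits_file, hits_mem)
})
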