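test_that("effective dose follows the toxic-unit definition", {
  panel <- default_panel()
  expect_equal(effective_dose(c(formaldehyde = 0, copper = 0), panel), 0)
  expect_equal(effective_dose(c(silver = 100), panel), 10)
  expect_equal(effective_dose(c(tetracycline = 2.5), panel), 5)

  # equal-ratio quaternary at EC 10 under strong antagonism
  ppm <- c(formaldehyde = 50, tetracycline = 1.25, silver = 25, copper = 25)
  expect_equal(effective_dose(ppm, panel, lambda = 0.18), 1.8, tolerance = 1e-12)

  expect_error(effective_dose(c(arsenic = 1), panel), "unknown toxicant")
  expect_error(effective_dose(c(copper = -1), panel), ">= 0")
})

test_that("traces are deterministic given a seed and structurally valid", {
  panel <- default_panel()
  man <- expand_manifest(enumerate_setups(panel), panel, n_replicates = 1)
  params <- sim_params()
  row <- man[man$setup_id == "copper+silver:1:1" & man$ec_level == 7, ]

  t1 <- simulate_trace(row, params, seed = 99)
  t2 <- simulate_trace(row, params, seed = 99)
  expect_identical(t1$current_mA, t2$current_mA)

  expect_equal(nrow(t1), 31)  # 60 s baseline + 300 s exposure at 12 s steps
  expect_true(all(diff(t1$time_s) == 12))
  expect_true(all(t1$current_mA > 0))

  t3 <- simulate_trace(row, params, seed = 100)
  expect_false(identical(t1$current_mA, t3$current_mA))
})

test_that("a zero-dose, noise-free trace is flat at the baseline", {
  panel <- default_panel()
  man <- expand_manifest(enumerate_setups(panel), panel, n_replicates = 1)
  params <- sim_params("additive")
  row <- man[man$setup_id == "silver:1" & man$ec_level == 1, ]
  row[paste0("ppm_", panel$name)] <- 0

  tr <- simulate_trace(row, params, seed = 1)
  expect_equal(diff(range(tr$current_mA)), 0, tolerance = 1e-12)
  f <- extract_features(tr)
  expect_equal(f$delta_i_rel, 0, tolerance = 1e-12)
})

test_that("the inhibition plateau matches the closed form of the generator", {
  panel <- toxicant_panel("solo", 100)
  kin <- tibble::tibble(name = "solo", beta = 0.02, tau_decline = 30,
                        lag = 0, stress_amp = 0, tau_up = 20,
                        recovery_amp = 0)
  params <- sim_params(panel = panel, kinetics = kin, noise_sd = 0,
                       i0_sd = 0, stress = FALSE, recovery = FALSE,
                       duration_s = 600)
  man <- expand_manifest(enumerate_setups(panel), panel,
                         ec_levels = 5, n_replicates = 1)
  tr <- simulate_trace(man[1, ], params, seed = 1)
  f <- extract_features(tr)
  # f = beta * dose = 0.02 * 5 = 0.10; duration 600 s >> tau 30 s
  expect_equal(f$delta_i_rel, 0.10, tolerance = 1e-4)
})

test_that("noise-free relative response is nondecreasing in EC per setup", {
  panel <- default_panel()
  man <- expand_manifest(enumerate_setups(panel), panel, n_replicates = 1)
  params <- sim_params(noise_sd = 0, i0_sd = 0)
  sim <- simulate_dataset(man, params, seed = 5)
  feats <- featurize_dataset(sim$traces)
  dat <- dplyr::inner_join(
    sim$truth[c("sample_id", "setup_id", "ec_level")],
    feats[c("sample_id", "delta_i_rel")], by = "sample_id"
  )
  for (s in unique(dat$setup_id)) {
    sub <- dat[dat$setup_id == s, ]
    v <- sub$delta_i_rel[order(sub$ec_level)]
    expect_true(all(diff(v) >= -1e-9), label = paste("monotone in", s))
  }
})

test_that("stress drives the up indicator and adaptation drives back", {
  panel <- default_panel()
  man <- expand_manifest(enumerate_setups(panel), panel, n_replicates = 1)
  params <- sim_params(noise_sd = 0, i0_sd = 0)
  # strong formaldehyde single: early pulse above baseline
  tr_f <- simulate_trace(man[man$setup_id == "formaldehyde:1" &
                             man$ec_level == 10, ], params, seed = 1)
  f_f <- extract_features(tr_f, baseline = list(i0 = 1, sigma0 = 0.002))
  expect_equal(f_f$up, 1L)
  expect_gt(f_f$i_rise, 0)

  # copper single: adaptive stimulation lifts the tail above the minimum
  tr_c <- simulate_trace(man[man$setup_id == "copper:1" &
                             man$ec_level == 10, ], params, seed = 1)
  f_c <- extract_features(tr_c, baseline = list(i0 = 1, sigma0 = 0.002))
  expect_equal(f_c$back, 1L)
  expect_lt(f_c$t_imin, f_c$duration)
})

test_that("dataset simulation is a seeded bijection over the manifest", {
  d1 <- small_dataset(seed = 21L)
  d2 <- small_dataset(seed = 21L)
  expect_identical(d1$sim$traces, d2$sim$traces)
  expect_equal(nrow(d1$truth), nrow(d1$manifest))
  expect_equal(length(unique(d1$sim$traces$sample_id)), nrow(d1$manifest))
  expect_error(simulate_dataset(d1$manifest[0, ], sim_params()), "empty")
})
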