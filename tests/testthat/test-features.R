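test_that("baseline estimation follows the trailing-window mean rule", {
  tr <- tibble::tibble(time_s = seq(0, 120, 12),
                       current_mA = c(0.98, 1.00, 1.02, 1.00, 1.00,
                                      rep(0.9, 6)))
  b <- estimate_baseline(tr, injection_time = 60)
  expect_equal(b$i0, 1.00, tolerance = 1e-12)

  flat <- tibble::tibble(time_s = seq(0, 120, 12),
                         current_mA = c(rep(1, 5), rep(0.8, 6)))
  expect_equal(estimate_baseline(flat, injection_time = 60)$sigma0, 0)

  # no pre-injection samples: fall back to the first sample
  nopre <- tibble::tibble(time_s = seq(0, 48, 12),
                          current_mA = c(0.9, 0.8, 0.7, 0.6, 0.5))
  b2 <- estimate_baseline(nopre, injection_time = 0)
  expect_equal(b2$i0, 0.9)
  expect_equal(b2$sigma0, 0)
})

test_that("the hand-computed five-point trace is reproduced exactly", {
  tr <- tibble::tibble(time_s = seq(0, 48, 12),
                       current_mA = c(1.00, 1.10, 0.90, 0.70, 0.60))
  f <- extract_features(tr, baseline = list(i0 = 1.00, sigma0 = 0),
                        injection_time = 0)
  expect_equal(ncol(f), 22)
  expect_equal(names(f), feature_names())

  expect_equal(f$i_max, 1.10, tolerance = 1e-9)
  expect_equal(f$i_min, 0.60, tolerance = 1e-9)
  expect_equal(f$delta_i, 0.50, tolerance = 1e-9)
  expect_equal(f$delta_i_rel, 0.50, tolerance = 1e-9)
  expect_equal(f$t_imax, 12)
  expect_equal(f$t_imin, 48)
  expect_equal(f$delta_t, -36)
  expect_equal(f$k_secant, 0.5 / -36, tolerance = 1e-9)
  expect_equal(f$i_rise, 0.10, tolerance = 1e-9)
  expect_equal(f$i_drop, 0.40, tolerance = 1e-9)
  expect_equal(f$i_end, 0.60, tolerance = 1e-9)
  expect_equal(f$duration, 48)
  expect_equal(f$k_all, -0.4 / 48, tolerance = 1e-9)
  expect_equal(f$integral, 42.0, tolerance = 1e-9)
  expect_equal(f$up, 1L)
  expect_equal(f$back, 0L)
})

test_that("degenerate and invalid traces are handled per contract", {
  flat <- tibble::tibble(time_s = seq(0, 60, 12), current_mA = rep(0.8, 6))
  f <- extract_features(flat, baseline = list(i0 = 0.8, sigma0 = 0),
                        injection_time = 0)
  expect_equal(f$delta_i, 0)
  expect_equal(f$k_secant, 0)   # delta_t == 0 yields 0, not an error
  expect_equal(f$k_all, 0)
  expect_equal(f$up, 0L)
  expect_equal(f$back, 0L)
  expect_equal(f$integral, 0.8 * 60, tolerance = 1e-12)

  short <- tibble::tibble(time_s = c(0, 12), current_mA = c(1, 1))
  expect_error(extract_features(short, injection_time = 0), "at least 3")

  uneven <- tibble::tibble(time_s = c(0, 12, 30, 36), current_mA = rep(1, 4))
  expect_error(extract_features(uneven, injection_time = 0), "uniform")
})

test_that("every feature matches the naive loop oracle on random traces", {
  set.seed(202)
  for (rep in 1:200) {
    n_post <- sample(10:30, 1)
    n_pre <- sample(0:5, 1)
    times <- seq(0, by = 12, length.out = n_pre + n_post)
    inj <- if (n_pre > 0) times[n_pre + 1] else 0
    cur <- 1 + cumsum(rnorm(n_pre + n_post, 0, 0.05))
    cur <- pmax(cur, 0.05)
    tr <- tibble::tibble(time_s = times, current_mA = cur)

    b <- estimate_baseline(tr, injection_time = inj)
    got <- as.numeric(extract_features(tr, injection_time = inj))
    want <- naive_features(times, cur, inj, b$i0, b$sigma0)
    expect_equal(got, unname(want), tolerance = 1e-9,
                 label = paste("random trace", rep))
  }
})

test_that("features are scale-equivariant and time-shift invariant", {
  set.seed(7)
  times <- seq(0, by = 12, length.out = 30)
  cur <- 1 + cumsum(rnorm(30, 0, 0.04))
  tr <- tibble::tibble(time_s = times, current_mA = cur)
  inj <- times[6]
  base <- estimate_baseline(tr, injection_time = inj)
  f <- extract_features(tr, baseline = base, injection_time = inj)

  c_scale <- 3.7
  f_scaled <- extract_features(
    tibble::tibble(time_s = times, current_mA = cur * c_scale),
    baseline = list(i0 = base$i0 * c_scale, sigma0 = base$sigma0 * c_scale),
    injection_time = inj
  )
  amps <- c("i_max", "i_min", "delta_i", "i_rise", "i_drop", "i_end",
            "integral", "k_secant", "k_max0", "k_min0", "k_all",
            "d_max", "d_min")
  for (a in amps) {
    expect_equal(f_scaled[[a]], f[[a]] * c_scale, tolerance = 1e-9, label = a)
  }
  invars <- c("delta_i_rel", "t_imax", "t_imin", "delta_t", "duration",
              "up", "back", "t_dmax", "t_dmin")
  for (a in invars) {
    expect_equal(f_scaled[[a]], f[[a]], tolerance = 1e-9, label = a)
  }

  f_shift <- extract_features(
    tibble::tibble(time_s = times + 240, current_mA = cur),
    baseline = base, injection_time = inj + 240
  )
  expect_equal(as.numeric(f_shift), as.numeric(f), tolerance = 1e-9)
})

test_that("dataset featurization is shape-stable and order-independent", {
  d <- small_dataset(n_setups = 6, n_replicates = 1)
  expect_equal(nrow(d$features), nrow(d$manifest))
  expect_equal(ncol(d$features), 23)  # sample_id + 22 features
  expect_equal(names(d$features)[-1], feature_names())

  empty <- featurize_dataset(d$sim$traces[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), c("sample_id", feature_names()))

  shuffled <- dplyr::arrange(d$sim$traces, dplyr::desc(sample_id), time_s)
  f2 <- featurize_dataset(shuffled)
  f2 <- f2[match(d$features$sample_id, f2$sample_id), ]
  expect_equal(as.data.frame(f2), as.data.frame(d$features),
               tolerance = 1e-12, ignore_attr = TRUE)
})
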