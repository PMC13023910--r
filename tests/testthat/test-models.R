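test_that("error metrics match their closed forms", {
  expect_equal(mae(c(1, 2, 4), c(1, 2, 3)), 1 / 3, tolerance = 1e-12)
  expect_equal(mae(c(5, 5), c(5, 5)), 0)
  expect_equal(mae(c(0, 0), c(-1, 1)), 1)

  expect_equal(rmse(c(1, 2, 4), c(1, 2, 3)), sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(2, 4, 6), c(2, 4, 6) + 0.3), 0.3, tolerance = 1e-12)

  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(1, 2, 3, 4)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_lt(r_squared(c(1, 2, 3, 4), c(4, 3, 2, 1)), 0)  # worse than the mean

  expect_error(mae(1:3, 1:4), "equal length")
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("metrics agree with a naive loop oracle on random vectors", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    y <- rnorm(n); p <- rnorm(n)
    s_abs <- 0; s_sq <- 0
    for (k in 1:n) {
      s_abs <- s_abs + abs(p[k] - y[k])
      s_sq <- s_sq + (p[k] - y[k])^2
    }
    expect_equal(mae(y, p), s_abs / n, tolerance = 1e-12)
    expect_equal(rmse(y, p), sqrt(s_sq / n), tolerance = 1e-12)
    ybar <- sum(y) / n
    sst <- 0
    for (k in 1:n) sst <- sst + (y[k] - ybar)^2
    expect_equal(r_squared(y, p), 1 - s_sq / sst, tolerance = 1e-12)
    expect_gte(rmse(y, p), mae(y, p))  # power-mean inequality
  }
})

test_that("model specs pin the published hyperparameters", {
  expect_equal(model_spec("knn")$hyperparams$k, 200L)
  expect_equal(model_spec("pls")$hyperparams$ncomp, 2L)
  expect_equal(model_spec("rf")$hyperparams$ntree, 100L)
  svm <- model_spec("svm")
  expect_equal(svm$hyperparams$cost, 1)
  expect_equal(svm$hyperparams$epsilon, 0.1)
  expect_equal(svm$cv_folds, 10L)
  expect_equal(svm$seed, 42L)
  expect_true(svm$standardize)
  expect_false(model_spec("rf")$standardize)
  expect_error(model_spec("rf", k = 3), "unknown hyperparameter")
})

test_that("cross-validated training is deterministic and well-shaped", {
  d <- small_dataset(n_setups = 8, n_replicates = 2)
  spec <- model_spec("rf", ntree = 30, cv_folds = 5)
  cv1 <- train_predict_cv(d$features, d$truth, spec)
  cv2 <- train_predict_cv(d$features, d$truth, spec)
  expect_identical(cv1$predictions, cv2$predictions)

  preds <- tidy(cv1)
  expect_equal(nrow(preds), nrow(d$features) * 4)
  expect_setequal(unique(preds$toxicant), default_panel()$name)
  expect_true(all(table(preds$fold) > 0))

  sc <- glance(cv1)
  expect_equal(nrow(sc), 4)
  expect_true(all(sc$rmse >= sc$mae))
})

test_that("a constant target gives near-zero error and an undefined r2", {
  d <- small_dataset(n_setups = 6, n_replicates = 2)
  truth <- d$truth
  truth$ppm_copper <- 0
  cv <- train_predict_cv(d$features, truth, model_spec("rf", ntree = 20,
                                                       cv_folds = 5))
  expect_warning(sc <- score_table(cv), "constant target")
  cu <- sc[sc$toxicant == "copper", ]
  expect_lt(cu$mae, 1e-8)
  expect_true(is.na(cu$r2))
})

test_that("knn clamps k to the training-fold size with a warning", {
  d <- small_dataset(n_setups = 6, n_replicates = 1, ec_levels = c(1, 10))
  spec <- model_spec("knn", cv_folds = 4)  # k = 200 >> fold training size
  ws <- testthat::capture_warnings(
    cv <- train_predict_cv(d$features, d$truth, spec)
  )
  expect_true(length(ws) > 0 && all(grepl("clamped", ws)))
  expect_equal(nrow(tidy(cv)), nrow(d$features) * 4)
})

test_that("raw trace matrices stack post-injection currents", {
  d <- small_dataset(n_setups = 6, n_replicates = 1)
  raw <- raw_trace_matrix(d$sim$traces)
  expect_equal(ncol(raw), 27)  # sample_id + 26 samples
  expect_equal(nrow(raw), nrow(d$manifest))

  tr <- d$sim$traces[d$sim$traces$sample_id == raw$sample_id[3], ]
  expect_equal(as.numeric(raw[3, -1]),
               tr$current_mA[tr$time_s >= 60][1:26])

  expect_error(raw_trace_matrix(d$sim$traces, n_points = 100), "fewer than")
})
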