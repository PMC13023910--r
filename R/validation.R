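#' Learning curve for one target
#'
#' Cross-validated learning curve: within each of `cv_folds` folds, the
#' training portion is subsampled (seeded) to each requested size, the
#' model is fitted, and both training RMSE and fold-validation RMSE are
#' recorded; means and standard deviations are taken over folds.
#' Convergence of the two error bands with growing sample size is the
#' classic signature of a model that is not overfitting.
#'
#' @param features,truth As for [train_predict_cv()].
#' @param target Toxicant name (a `ppm_<target>` column of `truth`).
#' @param spec Model specification (default 100-tree random forest).
#' @param sizes Increasing training sizes; default 8 steps from 100 up to
#'   the fold-training size.
#' @param cv_folds Folds used for the validation error.
#' @param seed Seed for fold assignment and subsampling.
#' @return Object of class `mectox_learning_curve`: tibble with columns
#'   `train_size`, `train_error`, `train_sd`, `val_error`, `val_sd`.
#' @export
learning_curve <- function(features, truth, target,
                           spec = model_spec("rf"), sizes = NULL,
                           cv_folds = 5, seed = 42L) {
  X <- numeric_feature_matrix(features)
  truth <- truth[match(features$sample_id, truth$sample_id), ]
  y <- truth[[paste0("ppm_", target)]]
  if (is.null(y)) abort(paste0("no ppm_", target, " column in `truth`"))
  n <- nrow(X)
  max_train <- floor(n * (cv_folds - 1) / cv_folds)
  if (is.null(sizes)) {
    sizes <- unique(round(seq(min(100, max_train), max_train, length.out = 8)))
  }
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 10)) abort("training sizes below 10 are not meaningful")
  if (max(sizes) > max_train) abort("largest size exceeds available training rows")

  set.seed(seed)
  folds <- sample(rep(seq_len(cv_folds), length.out = n))

  res <- purrr::map_dfr(sizes, function(sz) {
    errs <- purrr::map_dfr(seq_len(cv_folds), function(f) {
      tr_idx <- which(folds != f)
      set.seed(seed + 1000L * f + sz)
      sub <- sample(tr_idx, sz)
      Xtr <- X[sub, , drop = FALSE]
      Xte <- X[folds == f, , drop = FALSE]
      if (spec$standardize) {
        z <- standardizer(Xtr)
        Xtr <- z(Xtr); Xte <- z(Xte)
      }
      predict_fun <- fit_predictor(spec, Xtr, y[sub])
      tibble(
        train_error = rmse(y[sub], predict_fun(Xtr)),
        val_error = rmse(y[folds == f], predict_fun(Xte))
      )
    })
    tibble(
      train_size = sz,
      train_error = mean(errs$train_error), train_sd = sd(errs$train_error),
      val_error = mean(errs$val_error), val_sd = sd(errs$val_error)
    )
  })
  structure(res, class = c("mectox_learning_curve", class(res)),
            target = target)
}

#' Replicate-grouped train/test evaluation
#'
#' Splits by experimental condition (`setup_id` x `ec_level`) so that
#' replicates of one condition never straddle the split, stratified per
#' setup: a fraction `test_frac` of each setup's conditions is held out.
#' This is the conservative protocol — the model must generalize to
#' unseen conditions, not merely to left-out replicates. Falls back to a
#' plain random sample split (with a warning) when a setup has a single
#' condition.
#'
#' @param features,truth As for [train_predict_cv()]; `truth` must carry
#'   `setup_id` and `ec_level`.
#' @param spec Model specification.
#' @param test_frac Fraction of conditions held out per setup.
#' @param seed Split seed.
#' @return Tibble with one row per toxicant: `r2_train`, `r2_test`,
#'   `n_train`, `n_test`.
#' @export
train_test_split_eval <- function(features, truth, spec = model_spec("rf"),
                                  test_frac = 0.2, seed = 42L) {
  if (test_frac <= 0 || test_frac >= 1) abort("`test_frac` must be in (0, 1)")
  X <- numeric_feature_matrix(features)
  truth <- truth[match(features$sample_id, truth$sample_id), ]
  Y <- manifest_ppm(truth)

  cond <- paste(truth$setup_id, truth$ec_level)
  by_setup <- split(unique(cond), sub(" [^ ]*$", "", unique(cond)))
  set.seed(seed)
  if (any(lengths(by_setup) < 2)) {
    warn("some setups have a single condition; falling back to a random split")
    te <- seq_len(nrow(X)) %in% sample(nrow(X), ceiling(test_frac * nrow(X)))
  } else {
    held <- unlist(lapply(by_setup, function(g) {
      sample(g, max(1L, round(test_frac * length(g))))
    }))
    te <- cond %in% held
  }

  purrr::map_dfr(colnames(Y), function(tox) {
    y <- Y[, tox]
    Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (spec$standardize) {
      z <- standardizer(Xtr)
      Xtr <- z(Xtr); Xte <- z(Xte)
    }
    set.seed(seed)
    predict_fun <- fit_predictor(spec, Xtr, y[!te])
    tibble(
      toxicant = tox,
      r2_train = r_squared(y[!te], predict_fun(Xtr)),
      r2_test = r_squared(y[te], predict_fun(Xte)),
      n_train = sum(!te), n_test = sum(te)
    )
  })
}

#' Out-of-bag score against a held-out test score
#'
#' Fits a random forest on a random 80/20 sample split, computes the OOB
#' R-squared from the forest's out-of-bag predictions (samples never left
#' out by any tree are excluded and counted), the R-squared on the
#' held-out 20%, and their absolute gap. Close agreement is the forest's
#' internal evidence of reliable generalization.
#'
#' @param features,truth As for [train_predict_cv()].
#' @param target Toxicant name.
#' @param spec A random-forest [model_spec()].
#' @param test_frac Held-out fraction.
#' @param seed Split and forest seed.
#' @return One-row tibble: `toxicant`, `oob_score`, `r2_test`, `abs_gap`,
#'   `n_oob_undefined`.
#' @export
oob_vs_test <- function(features, truth, target, spec = model_spec("rf"),
                        test_frac = 0.2, seed = 42L) {
  if (spec$kind != "rf") abort("OOB scores are defined for random forests only")
  X <- numeric_feature_matrix(features)
  truth <- truth[match(features$sample_id, truth$sample_id), ]
  y <- truth[[paste0("ppm_", target)]]
  if (is.null(y)) abort(paste0("no ppm_", target, " column in `truth`"))

  set.seed(seed)
  te <- seq_len(nrow(X)) %in% sample(nrow(X), ceiling(test_frac * nrow(X)))
  set.seed(seed)
  fit <- randomForest::randomForest(X[!te, , drop = FALSE], y[!te],
                                    ntree = spec$hyperparams$ntree)
  oob_pred <- fit$predicted
  defined <- !is.na(oob_pred)
  oob <- r_squared(y[!te][defined], oob_pred[defined])
  r2_te <- r_squared(y[te], unname(predict(fit, X[te, , drop = FALSE])))
  tibble(
    toxicant = target,
    oob_score = oob,
    r2_test = r2_te,
    abs_gap = abs(oob - r2_te),
    n_oob_undefined = sum(!defined)
  )
}

#' Gini importance of a fitted random forest
#'
#' Mean decrease in node impurity per feature, summed over all trees and
#' normalized to sum to one, in descending order.
#'
#' @param fit A fitted `randomForest` regression object.
#' @return Tibble with columns `feature`, `importance`, `rank`.
#' @export
gini_importance <- function(fit) {
  if (!inherits(fit, "randomForest")) {
    abort("`fit` must be a fitted randomForest model")
  }
  imp <- fit$importance[, "IncNodePurity"]
  if (sum(imp) <= 0) {
    abort("forest has no positive impurity decrease; was it fitted?")
  }
  tibble(
    feature = names(imp),
    importance = unname(imp) / sum(imp)
  ) |>
    arrange(desc(.data$importance)) |>
    mutate(rank = dplyr::row_number())
}

#' Per-toxicant Gini importance table
#'
#' Fits one forest per toxicant on the full feature table and returns the
#' normalized Gini importances.
#'
#' @param features,truth As for [train_predict_cv()].
#' @param spec Random-forest specification.
#' @param seed Forest seed.
#' @return Tibble with columns `toxicant`, `feature`, `importance`, `rank`.
#' @export
importance_table <- function(features, truth, spec = model_spec("rf"),
                             seed = 42L) {
  X <- numeric_feature_matrix(features)
  truth <- truth[match(features$sample_id, truth$sample_id), ]
  Y <- manifest_ppm(truth)
  purrr::map_dfr(colnames(Y), function(tox) {
    set.seed(seed)
    fit <- randomForest::randomForest(X, Y[, tox],
                                      ntree = spec$hyperparams$ntree)
    gini_importance(fit) |> mutate(toxicant = tox, .before = 1)
  })
}
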