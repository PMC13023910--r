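#' Mean absolute error
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return `mean(abs(y_pred - y_true))`.
#' @export
mae <- function(y_true, y_pred) {
  check_paired(y_true, y_pred)
  mean(abs(y_pred - y_true))
}

#' Root mean square error
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return `sqrt(mean((y_pred - y_true)^2))`; never smaller than [mae()].
#' @export
rmse <- function(y_true, y_pred) {
  check_paired(y_true, y_pred)
  sqrt(mean((y_pred - y_true)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`. Can be negative when predictions are worse than
#' the mean of the observations.
#'
#' @param y_true,y_pred Equal-length numeric vectors; `y_true` must vary.
#' @return R-squared (scalar, may be negative).
#' @export
r_squared <- function(y_true, y_pred) {
  check_paired(y_true, y_pred)
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) abort("R^2 undefined: `y_true` has zero variance")
  1 - sum((y_pred - y_true)^2) / sst
}

# a constant or near-constant target is legitimate here (a toxicant absent
# from a whole manifest); keep the forest quiet about it
quiet_rf <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("five or fewer unique values", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

check_paired <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must be non-empty and equal length")
  }
  invisible(NULL)
}

#' Specification of a concentration-regression model
#'
#' The four model families compared by the package, with their pinned
#' hyperparameters: radial-kernel epsilon-SVR (`cost = 1`,
#' `epsilon = 0.1`, `gamma = 1/d` on standardized features), K-nearest
#' neighbours with `k = 200` and Euclidean distance, partial least squares
#' with 2 components, and a 100-tree random forest. Features are
#' standardized (z-score fit on the training portion only) for SVM, KNN
#' and PLS; trees are scale-free. Cross-validation folds are assigned with
#' the fixed seed so the whole evaluation is reproducible.
#'
#' @param method One of `"svm"`, `"knn"`, `"pls"`, `"rf"`.
#' @param ... Overrides of the kind-specific defaults (`cost`, `epsilon`,
#'   `gamma`, `k`, `ncomp`, `ntree`).
#' @param cv_folds Number of cross-validation folds.
#' @param seed Seed for fold assignment and tree growing.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(method = c("rf", "svm", "knn", "pls"), ...,
                       cv_folds = 10, seed = 42L) {
  kind <- match.arg(method)
  hp <- switch(kind,
    svm = list(cost = 1, epsilon = 0.1, gamma = NULL),
    knn = list(k = 200L),
    pls = list(ncomp = 2L),
    rf  = list(ntree = 100L)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(hp))
  if (length(unknown)) {
    abort(paste0("unknown hyperparameter(s) for ", kind, ": ",
                 paste(unknown, collapse = ", ")))
  }
  hp[names(dots)] <- dots
  if (kind == "knn" && hp$k < 1) abort("`k` must be >= 1")
  if (kind == "pls" && hp$ncomp < 1) abort("`ncomp` must be >= 1")
  if (kind == "rf" && hp$ntree < 1) abort("`ntree` must be >= 1")
  structure(
    list(kind = kind, hyperparams = hp,
         standardize = kind != "rf",
         cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparams),
              vapply(x$hyperparams, function(v) {
                if (is.null(v)) "auto" else format(v)
              }, character(1)),
              sep = "=", collapse = ", ")
  cat("<model_spec>", x$kind, "(", hp, ");",
      x$cv_folds, "folds; seed", x$seed, "\n")
  invisible(x)
}

# fit on (X, y), return closure predicting on new X rows.
# X matrices arrive already standardized when spec$standardize is TRUE.
fit_predictor <- function(spec, X, y) {
  kind <- spec$kind
  hp <- spec$hyperparams
  if (kind == "svm") {
    gamma <- hp$gamma %||% (1 / ncol(X))
    fit <- e1071::svm(X, y, kernel = "radial", cost = hp$cost,
                      epsilon = hp$epsilon, gamma = gamma, scale = FALSE)
    function(newX) unname(predict(fit, newX))
  } else if (kind == "knn") {
    k <- hp$k
    if (k > nrow(X)) {
      warn(sprintf("k = %d exceeds training size %d; clamped", k, nrow(X)))
      k <- nrow(X)
    }
    function(newX) FNN::knn.reg(train = X, test = newX, y = y, k = k)$pred
  } else if (kind == "pls") {
    # constant columns (e.g. a fixed trace duration) trigger a harmless
    # zero-sd warning in the correlation bookkeeping; silence only that
    quiet_sd <- function(expr) {
      withCallingHandlers(expr, warning = function(w) {
        if (grepl("standard deviation is zero", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    }
    fit <- quiet_sd(mixOmics::pls(X, y, ncomp = hp$ncomp, scale = FALSE,
                                  mode = "regression"))
    function(newX) {
      pr <- quiet_sd(predict(fit, newX)$predict)
      unname(pr[, 1, hp$ncomp])
    }
  } else {
    fit <- quiet_rf(randomForest::randomForest(X, y, ntree = hp$ntree))
    function(newX) unname(predict(fit, newX))
  }
}

numeric_feature_matrix <- function(features) {
  cols <- setdiff(names(features), "sample_id")
  X <- as.matrix(features[cols])
  if (!is.numeric(X)) abort("feature columns must be numeric")
  if (anyNA(X)) abort("features contain missing values")
  rownames(X) <- features$sample_id
  X
}

standardizer <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  function(newX) scale(newX, center = mu, scale = s)
}

#' Cross-validated concentration predictions
#'
#' Trains one independent single-output regressor per toxicant and
#' assembles out-of-fold predictions over `cv_folds` folds. Fold
#' assignment is drawn once with the spec's seed, shared across toxicants
#' and models, so model families are compared on identical splits.
#'
#' @param features Tibble with `sample_id` plus numeric predictor columns
#'   (22-feature table or a raw-trace matrix from [raw_trace_matrix()]).
#' @param truth Tibble with `sample_id` and one `ppm_<toxicant>` column
#'   per target.
#' @param spec A [model_spec()].
#' @return An object of class `mectox_cv`: list with `predictions` (tibble:
#'   `sample_id`, `model`, `toxicant`, `fold`, `y_true`, `y_pred`) and
#'   `spec`. Use [score_table()], [tidy()] or [glance()] on it.
#' @export
train_predict_cv <- function(features, truth, spec = model_spec("rf")) {
  X <- numeric_feature_matrix(features)
  truth <- truth[match(features$sample_id, truth$sample_id), ]
  if (anyNA(truth$sample_id)) abort("`truth` is missing some sample_ids")
  Y <- manifest_ppm(truth)
  n <- nrow(X)
  if (n < spec$cv_folds) abort("fewer samples than folds")

  set.seed(spec$seed)
  folds <- sample(rep(seq_len(spec$cv_folds), length.out = n))

  preds <- vector("list", ncol(Y) * spec$cv_folds)
  idx <- 1L
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    for (f in seq_len(spec$cv_folds)) {
      te <- folds == f
      Xtr <- X[!te, , drop = FALSE]
      Xte <- X[te, , drop = FALSE]
      if (spec$standardize) {
        z <- standardizer(Xtr)
        Xtr <- z(Xtr)
        Xte <- z(Xte)
      }
      set.seed(spec$seed + f)  # tree/SV fitting reproducible per fold
      predict_fun <- fit_predictor(spec, Xtr, y[!te])
      preds[[idx]] <- tibble(
        sample_id = features$sample_id[te],
        model = spec$kind,
        toxicant = colnames(Y)[j],
        fold = f,
        y_true = y[te],
        y_pred = as.numeric(predict_fun(Xte))
      )
      idx <- idx + 1L
    }
  }
  structure(
    list(predictions = dplyr::bind_rows(preds), spec = spec),
    class = "mectox_cv"
  )
}

#' @export
print.mectox_cv <- function(x, ...) {
  cat("<mectox_cv>", x$spec$kind, "model,",
      length(unique(x$predictions$toxicant)), "toxicants,",
      nrow(x$predictions), "out-of-fold predictions\n")
  invisible(x)
}

#' Score a set of predictions
#'
#' Pooled out-of-fold MAE, RMSE and R-squared per model and toxicant. A
#' constant target yields `r2 = NA` with a warning (the ratio is
#' undefined); MAE/RMSE are still reported.
#'
#' @param x A `mectox_cv` object or a predictions tibble with columns
#'   `model`, `toxicant`, `y_true`, `y_pred`.
#' @return Tibble with columns `model`, `toxicant`, `mae`, `rmse`, `r2`.
#' @export
score_table <- function(x) {
  preds <- if (inherits(x, "mectox_cv")) x$predictions else x
  preds |>
    group_by(.data$model, .data$toxicant) |>
    summarise(
      mae = mae(.data$y_true, .data$y_pred),
      rmse = rmse(.data$y_true, .data$y_pred),
      r2 = if (var(.data$y_true) == 0) {
        warn("constant target: r2 undefined, reported as NA")
        NA_real_
      } else {
        r_squared(.data$y_true, .data$y_pred)
      },
      .groups = "drop"
    )
}

#' @method tidy mectox_cv
#' @export
tidy.mectox_cv <- function(x, ...) x$predictions

#' @method glance mectox_cv
#' @export
glance.mectox_cv <- function(x, ...) score_table(x)

#' Raw-trace design matrix
#'
#' Resamples/truncates each trace to a common post-injection length and
#' stacks the raw currents row-wise: the direct-modelling baseline that
#' the engineered features are compared against.
#'
#' @param traces Long trace tibble.
#' @param injection_time Injection time (s).
#' @param n_points Number of post-injection samples retained per trace
#'   (the injection instant excluded).
#' @return Tibble with `sample_id` and `t1 ... t<n_points>` columns.
#' @export
raw_trace_matrix <- function(traces, injection_time = 60, n_points = 26) {
  grp <- split(seq_len(nrow(traces)), traces$sample_id)
  ids <- unique(traces$sample_id)
  rows <- lapply(ids, function(id) {
    tr <- traces[grp[[id]], ]
    y <- tr$current_mA[tr$time_s >= injection_time]
    if (length(y) < n_points) {
      abort(paste0("trace ", id, " has fewer than ", n_points,
                   " post-injection samples"))
    }
    y[seq_len(n_points)]
  })
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("t", seq_len(n_points))
  dplyr::bind_cols(tibble(sample_id = ids), as_tibble(m))
}

#' Compare the four model families under cross-validation
#'
#' Runs [train_predict_cv()] for each requested kind and binds the scores.
#'
#' @param features,truth As for [train_predict_cv()].
#' @param kinds Model kinds to fit.
#' @param cv_folds,seed Shared protocol settings.
#' @return List with `scores` (bound [score_table()] rows) and `cv`
#'   (named list of `mectox_cv` objects).
#' @export
compare_models <- function(features, truth,
                           kinds = c("svm", "knn", "pls", "rf"),
                           cv_folds = 10, seed = 42L) {
  cvs <- lapply(kinds, function(k) {
    train_predict_cv(features, truth,
                     model_spec(k, cv_folds = cv_folds, seed = seed))
  })
  names(cvs) <- kinds
  list(
    scores = dplyr::bind_rows(lapply(cvs, score_table)),
    cv = cvs
  )
}
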