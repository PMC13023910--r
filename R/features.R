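#' Names of the 22 trace features, in canonical order
#'
#' Instantaneous extremes and their times, overall and segment slopes,
#' baseline-referenced increments, endpoint descriptors, the two binary
#' stress/adaptation indicators, the curve integral, and smoothed-derivative
#' extremes with their times.
#'
#' @return Character vector of length 22.
#' @export
feature_names <- function() {
  c("i_max", "i_min", "delta_i", "delta_i_rel", "t_imax", "t_imin",
    "delta_t", "k_secant", "i_rise", "i_drop", "k_max0", "k_min0",
    "i_end", "duration", "k_all", "up", "back", "integral",
    "d_max", "d_min", "t_dmax", "t_dmin")
}

#' Estimate the pre-injection baseline current
#'
#' The initial current I0 is the mean of the samples recorded before the
#' injection, restricted to the trailing `window_s` seconds; `sigma0` is
#' their standard deviation and feeds the noise-robust thresholds of the
#' binary `up`/`back` indicators. If no pre-injection samples exist the
#' first sample is used and `sigma0` is 0.
#'
#' @param trace Trace tibble with `time_s` and `current_mA`.
#' @param injection_time Injection time (s); defaults to the trace's
#'   `injection_time` attribute, else 60.
#' @param window_s Width of the trailing baseline window (s).
#' @return A list with elements `i0` and `sigma0`.
#' @export
estimate_baseline <- function(trace, injection_time = NULL, window_s = 60) {
  if (is.null(injection_time)) {
    injection_time <- attr(trace, "injection_time") %||% 60
  }
  pre <- trace$current_mA[trace$time_s < injection_time &
                          trace$time_s >= injection_time - window_s]
  if (length(pre) == 0) {
    i0 <- trace$current_mA[1]
    sigma0 <- 0
  } else {
    i0 <- mean(pre)
    sigma0 <- if (length(pre) > 1) sd(pre) else 0
  }
  if (!is.finite(i0) || i0 <= 0) abort("baseline current must be positive")
  list(i0 = i0, sigma0 = sigma0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# centered moving average with window shrinking at the edges
moving_average <- function(y, window) {
  h <- (window - 1L) %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Extract the 22 engineered features from one trace
#'
#' All extrema and times are computed over the post-injection window only
#' (the injection instant itself included), with ties broken to the
#' earliest sample. Times are reported in seconds after injection.
#' Derivatives are central finite differences of a centered moving average
#' of the post-injection signal (window shrinks at the edges; derivative
#' extremes are taken over interior points). The binary `up` indicator
#' fires when the raw current within the first 60 s after injection
#' strictly exceeds `i0 + kappa * sigma0`; `back` fires when, after the
#' current minimum, a smoothed sample strictly exceeds
#' `i_min + kappa * sigma0` (strictness keeps both indicators at 0 on a
#' perfectly flat trace).
#'
#' @param trace Trace tibble (`time_s`, `current_mA`) on a uniform grid.
#' @param baseline Optional list from [estimate_baseline()]; computed from
#'   the trace if omitted.
#' @param injection_time Injection time (s); defaults to the trace
#'   attribute, else 60.
#' @param smooth_window Odd moving-average window (samples) for the
#'   derivative estimate.
#' @param kappa Threshold multiplier on `sigma0` for `up`/`back`.
#' @return A one-row tibble with the 22 columns of [feature_names()].
#' @examples
#' tr <- tibble::tibble(time_s = seq(0, 48, 12),
#'                      current_mA = c(1.0, 1.1, 0.9, 0.7, 0.6))
#' extract_features(tr, baseline = list(i0 = 1, sigma0 = 0),
#'                  injection_time = 0)
#' @export
extract_features <- function(trace, baseline = NULL, injection_time = NULL,
                             smooth_window = 5, kappa = 3) {
  if (is.null(injection_time)) {
    injection_time <- attr(trace, "injection_time") %||% 60
  }
  if (smooth_window %% 2 != 1 || smooth_window < 1) {
    abort("`smooth_window` must be a positive odd integer")
  }
  if (any(!is.finite(trace$current_mA))) abort("currents must be finite")
  steps <- diff(trace$time_s)
  if (any(steps <= 0) || max(steps) - min(steps) > 1e-8) {
    abort("trace times must be strictly increasing on a uniform grid")
  }
  if (is.null(baseline)) {
    baseline <- estimate_baseline(trace, injection_time)
  }
  i0 <- baseline$i0
  sigma0 <- baseline$sigma0

  post <- trace$time_s >= injection_time
  y <- trace$current_mA[post]
  t2 <- trace$time_s[post] - injection_time
  n <- length(y)
  if (n < 3) abort("need at least 3 post-injection samples")
  step <- steps[1]

  i_max <- max(y); i_min <- min(y)
  t_imax <- t2[which.max(y)]; t_imin <- t2[which.min(y)]
  delta_i <- i_max - i_min
  delta_t <- t_imax - t_imin
  duration <- t2[n]
  i_end <- y[n]

  sm <- moving_average(y, smooth_window)
  d <- (sm[3:n] - sm[1:(n - 2)]) / (2 * step)
  td <- t2[2:(n - 1)]
  d_max <- max(d); d_min <- min(d)
  t_dmax <- td[which.max(d)]; t_dmin <- td[which.min(d)]

  up <- as.integer(max(y[t2 <= 60]) > i0 + kappa * sigma0)
  later <- t2 > t_imin
  back <- as.integer(t_imin < duration &&
                     any(sm[later] > i_min + kappa * sigma0))

  tibble(
    i_max = i_max,
    i_min = i_min,
    delta_i = delta_i,
    delta_i_rel = delta_i / i0,
    t_imax = t_imax,
    t_imin = t_imin,
    delta_t = delta_t,
    k_secant = if (delta_t == 0) 0 else delta_i / delta_t,
    i_rise = i_max - i0,
    i_drop = i0 - i_min,
    k_max0 = if (t_imax == 0) 0 else (i_max - i0) / t_imax,
    k_min0 = if (t_imin == 0) 0 else (i_min - i0) / t_imin,
    i_end = i_end,
    duration = duration,
    k_all = (i_end - i0) / duration,
    up = up,
    back = back,
    integral = sum(diff(t2) * (head(y, -1) + tail(y, -1)) / 2),
    d_max = d_max,
    d_min = d_min,
    t_dmax = t_dmax,
    t_dmin = t_dmin
  )
}

#' Featurize a whole trace collection
#'
#' Applies [extract_features()] per `sample_id` of a long trace tibble.
#'
#' @param traces Long tibble (`sample_id`, `time_s`, `current_mA`), e.g.
#'   `simulate_dataset()$traces` or [read_traces_csv()].
#' @param injection_time Injection time (s) shared by all traces.
#' @param smooth_window,kappa Passed to [extract_features()].
#' @return A tibble with `sample_id` plus the 22 feature columns, one row
#'   per trace, in first-appearance order of `sample_id`.
#' @export
featurize_dataset <- function(traces, injection_time = 60,
                              smooth_window = 5, kappa = 3) {
  ids <- unique(traces$sample_id)
  if (length(ids) == 0) {
    out <- as_tibble(setNames(
      as.data.frame(matrix(numeric(0), 0, 23)),
      c("sample_id", feature_names())
    ))
    out$sample_id <- character(0)
    return(out)
  }
  grp <- split(seq_len(nrow(traces)), traces$sample_id)
  rows <- lapply(ids, function(id) {
    tr <- traces[grp[[id]], c("time_s", "current_mA")]
    if (anyDuplicated(tr$time_s)) {
      abort(paste0("duplicate sample times for sample_id ", id))
    }
    dplyr::bind_cols(
      tibble(sample_id = id),
      extract_features(tr, injection_time = injection_time,
                       smooth_window = smooth_window, kappa = kappa)
    )
  })
  dplyr::bind_rows(rows)
}
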