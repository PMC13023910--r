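#' Fixed-time toxicity responses
#'
#' The relative current loss `(I0 - I(t)) / I0` at given times after
#' injection, evaluated at the nearest grid sample (ties between two
#' equidistant samples resolve to the later one, so 30 s on a 12 s grid
#' maps to 36 s).
#'
#' @param trace Trace tibble (`time_s`, `current_mA`).
#' @param times_s Times after injection (s) at which to evaluate.
#' @param baseline Optional baseline list; estimated if omitted.
#' @param injection_time Injection time (s).
#' @return Tibble with columns `time_s` (requested), `grid_time_s` (used)
#'   and `response`.
#' @export
response_at <- function(trace, times_s = c(30, 60, 300), baseline = NULL,
                        injection_time = NULL) {
  if (is.null(injection_time)) {
    injection_time <- attr(trace, "injection_time") %||% 60
  }
  if (is.null(baseline)) baseline <- estimate_baseline(trace, injection_time)
  post <- trace$time_s >= injection_time
  t2 <- trace$time_s[post] - injection_time
  y <- trace$current_mA[post]
  grid <- vapply(times_s, function(tt) {
    dist <- abs(t2 - tt)
    cand <- which(dist == min(dist))
    t2[cand[length(cand)]]  # tie -> later sample
  }, numeric(1))
  tibble(
    time_s = times_s,
    grid_time_s = grid,
    response = (baseline$i0 - y[match(grid, t2)]) / baseline$i0
  )
}

#' Interaction Index of a mixture
#'
#' `II = mixture_response / sum(single_responses)`, the measured mixture
#' response over the additivity expectation built from single-toxicant
#' responses at the mixture's component concentrations. II > 1 indicates
#' synergy, II < 1 antagonism, II = 1 additivity. Small negative mixture
#' responses (measurement noise) are floored at zero.
#'
#' @param mixture_response Measured mixture response (ΔI/I0).
#' @param single_responses Numeric vector of single-toxicant responses at
#'   the corresponding concentrations; each must be >= 0 with positive sum.
#' @param mixture_id Optional identifier carried through.
#' @return One-row tibble: `mixture_id`, `mixture_response`,
#'   `single_response_sum`, `ii`, `classification`.
#' @examples
#' interaction_index(0.32, c(0.10, 0.10))$ii # 1.6
#' @export
interaction_index <- function(mixture_response, single_responses,
                              mixture_id = NA_character_) {
  if (any(single_responses < 0)) {
    abort("single-toxicant responses must be >= 0")
  }
  denom <- sum(single_responses)
  if (!is.finite(denom) || denom <= 0) {
    abort("Interaction Index undefined: single responses sum to zero")
  }
  mr <- max(mixture_response, 0)
  ii <- mr / denom
  tibble(
    mixture_id = mixture_id,
    mixture_response = mr,
    single_response_sum = denom,
    ii = ii,
    classification = dplyr::case_when(
      ii > 1 ~ "synergy",
      ii < 1 ~ "antagonism",
      TRUE ~ "additive"
    )
  )
}

#' Reference table of single-toxicant responses
#'
#' Mean measured response (ΔI/I0) of every single-toxicant condition,
#' keyed by toxicant and ppm, with a (0 ppm, 0 response) anchor per
#' toxicant so that interpolation below the lowest tested concentration is
#' exact for a response that vanishes at zero dose.
#'
#' @param features Feature tibble (needs `sample_id`, `delta_i_rel`).
#' @param manifest Matching manifest tibble.
#' @return Tibble with columns `toxicant`, `ppm`, `response`, `n`.
#' @export
single_response_table <- function(features, manifest) {
  ppm <- manifest_ppm(manifest)
  singles <- rowSums(ppm > 0) == 1
  if (!any(singles)) abort("manifest contains no single-toxicant rows")
  which_tox <- colnames(ppm)[apply(ppm[singles, , drop = FALSE] > 0, 1, which)]
  df <- tibble(
    sample_id = manifest$sample_id[singles],
    toxicant = which_tox,
    ppm = ppm[singles, ][cbind(seq_len(sum(singles)),
                               match(which_tox, colnames(ppm)))]
  ) |>
    inner_join(features[c("sample_id", "delta_i_rel")], by = "sample_id") |>
    group_by(.data$toxicant, .data$ppm) |>
    summarise(response = mean(.data$delta_i_rel), n = dplyr::n(),
              .groups = "drop")
  anchors <- tibble(toxicant = unique(df$toxicant), ppm = 0,
                    response = 0, n = 0L)
  dplyr::bind_rows(anchors, df) |>
    arrange(.data$toxicant, .data$ppm)
}

#' Interpolate a single-toxicant response at an arbitrary concentration
#'
#' Linear interpolation of the tabulated mean response against ppm, with
#' clamped extrapolation at the range ends.
#'
#' @param table Output of [single_response_table()].
#' @param toxicant Toxicant name.
#' @param ppm Concentration (ppm) at which to evaluate.
#' @return Interpolated response (scalar).
#' @export
single_response_lookup <- function(table, toxicant, ppm) {
  sub <- table[table$toxicant == toxicant, ]
  if (nrow(sub) == 0) abort(paste0("no single-exposure data for ", toxicant))
  if (nrow(sub) < 2) abort("need at least two concentrations to interpolate")
  approx(sub$ppm, sub$response, xout = ppm, rule = 2, ties = "ordered")$y
}

#' Interaction Index table for every mixture condition
#'
#' For each mixture setup and EC level: the replicate-mean measured
#' response, the additivity expectation from interpolated single-toxicant
#' responses at the mixture's component concentrations, and their ratio
#' (the Interaction Index).
#'
#' @param features Feature tibble from [featurize_dataset()].
#' @param manifest Matching manifest.
#' @return Tibble with one row per (mixture setup, EC level).
#' @export
interaction_table <- function(features, manifest) {
  ref <- single_response_table(features, manifest)
  ppm <- manifest_ppm(manifest)
  mixture <- rowSums(ppm > 0) > 1

  dat <- dplyr::bind_cols(
    manifest[c("sample_id", "setup_id", "ec_level")],
    as_tibble(ppm)
  )[mixture, ] |>
    inner_join(features[c("sample_id", "delta_i_rel")], by = "sample_id")

  dat |>
    group_by(.data$setup_id, .data$ec_level) |>
    summarise(across(dplyr::all_of(colnames(ppm)), ~ .x[1]),
              mixture_response = mean(.data$delta_i_rel),
              .groups = "drop") |>
    rowwise() |>
    mutate(
      single_response_sum = sum(vapply(
        colnames(ppm),
        function(tox) {
          p <- get(tox)
          if (p > 0) single_response_lookup(ref, tox, p) else 0
        },
        numeric(1)
      ))
    ) |>
    ungroup() |>
    mutate(
      ii = pmax(.data$mixture_response, 0) / .data$single_response_sum,
      classification = dplyr::case_when(
        .data$ii > 1 ~ "synergy",
        .data$ii < 1 ~ "antagonism",
        TRUE ~ "additive"
      )
    ) |>
    select(-dplyr::all_of(colnames(ppm)))
}

#' Linear calibration of response against equivalent concentration
#'
#' Ordinary least squares with intercept of response on EC.
#'
#' @param responses Tibble or data frame with columns `ec` and `response`
#'   (one row per exposure).
#' @param time_s Label: the fixed time (s) the responses were read at.
#' @return One-row tibble: `time_s`, `slope`, `intercept`, `r2`, `n`. For
#'   constant responses the slope is 0 and `r2` is reported as 0.
#' @examples
#' calibration_fit(data.frame(ec = c(1, 5, 10),
#'                            response = c(0.05, 0.21, 0.41)), 300)
#' @export
calibration_fit <- function(responses, time_s = NA_real_) {
  ec <- responses$ec
  y <- responses$response
  if (length(unique(ec)) < 3) {
    abort("need responses at >= 3 distinct EC levels")
  }
  fit <- lm(y ~ ec)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  tibble(
    time_s = time_s,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = r2,
    n = length(y)
  )
}

#' Fixed-time calibration table for single-toxicant exposures
#'
#' Reads the response at each requested time from every single-toxicant
#' trace and fits response ~ EC per toxicant and time.
#'
#' @param traces Long trace tibble.
#' @param manifest Matching manifest.
#' @param times_s Fixed read-out times after injection (s).
#' @param injection_time Injection time (s).
#' @return Tibble with one calibration row per (toxicant, time).
#' @export
calibration_table <- function(traces, manifest, times_s = c(30, 60, 300),
                              injection_time = 60) {
  ppm <- manifest_ppm(manifest)
  singles <- which(rowSums(ppm > 0) == 1)
  if (length(singles) == 0) abort("manifest contains no single-toxicant rows")

  grp <- split(seq_len(nrow(traces)), traces$sample_id)
  resp <- purrr::map_dfr(singles, function(i) {
    id <- manifest$sample_id[i]
    tr <- traces[grp[[id]], c("time_s", "current_mA")]
    r <- response_at(tr, times_s, injection_time = injection_time)
    r$toxicant <- colnames(ppm)[which(ppm[i, ] > 0)]
    r$ec <- manifest$ec_level[i]
    r
  })

  resp |>
    group_by(.data$toxicant, .data$time_s) |>
    group_modify(~ select(calibration_fit(.x), -"time_s")) |>
    ungroup()
}
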