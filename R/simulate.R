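#' Effective dose of a (possibly mixed) exposure
#'
#' Summed toxic units scaled to EC units and modulated by the interaction
#' factor: `lambda * 10 * sum(ppm_j / c_max_j)`. A single toxicant at its
#' maximum concentration with lambda = 1 has effective dose 10.
#'
#' @param ppm Named numeric vector of per-toxicant concentrations (ppm).
#' @param panel Toxicant panel supplying `c_max`.
#' @param lambda Interaction factor (> 0); 1 means additivity.
#' @return Effective dose in EC units (scalar).
#' @examples
#' effective_dose(c(formaldehyde = 200), default_panel()) # 10
#' @export
effective_dose <- function(ppm, panel, lambda = 1) {
  if (any(ppm < 0)) abort("concentrations must be >= 0")
  if (lambda <= 0) abort("`lambda` must be > 0")
  j <- match(names(ppm), panel$name)
  if (anyNA(j)) {
    abort(paste0("unknown toxicant: ",
                 paste(names(ppm)[is.na(j)], collapse = ", ")))
  }
  lambda * 10 * sum(ppm / panel$c_max[j])
}

# Deterministic components of one trace on the post-injection clock tp >= 0.
# Returns the noise-free current relative to baseline (i.e. I(t)/I0).
trace_shape <- function(tp, ppm, params, lambda) {
  k <- params$kinetics
  tu <- ppm / params$panel$c_max[match(names(ppm), params$panel$name)]

  pulse <- rep(0, length(tp))
  decline <- rep(0, length(tp))
  rebound <- rep(0, length(tp))
  for (j in seq_along(tu)) {
    if (tu[j] == 0) next
    kj <- k[k$name == names(tu)[j], ]
    if (params$stress && kj$stress_amp > 0) {
      pulse <- pulse +
        lambda * tu[j] * kj$stress_amp * (tp / kj$tau_up) * exp(1 - tp / kj$tau_up)
    }
    te <- pmax(0, tp - kj$lag)
    decline <- decline +
      kj$beta * 10 * lambda * tu[j] * (1 - exp(-te / kj$tau_decline))
    if (params$recovery && kj$recovery_amp > 0) {
      rebound <- rebound + lambda * tu[j] * kj$recovery_amp *
        (1 - exp(-pmax(0, tp - params$recovery_onset) / params$tau_recovery))
    }
  }
  (1 + pulse) * (1 - pmin(decline, params$f_cap)) + rebound
}

#' Simulate one current-time trace
#'
#' Generates a chronoamperometric trace for one manifest row: a stable
#' pre-injection baseline, then (per toxicant, additively in toxic units) a
#' transient stress pulse, an exponential inhibition decline (optionally
#' lagged), and an adaptive stimulation term, with i.i.d. Gaussian
#' measurement noise clipped at 5 sd. Identical `(row, params, seed)`
#' reproduce the trace bit for bit.
#'
#' @param manifest_row One-row tibble from [expand_manifest()].
#' @param params A [sim_params()] object.
#' @param seed Integer seed for this trace.
#' @return A tibble with columns `sample_id`, `time_s`, `current_mA`;
#'   attributes `injection_time` (s) and `truth` (one-row tibble with the
#'   drawn baseline, effective dose, lambda and noise-free relative current
#'   change).
#' @export
simulate_trace <- function(manifest_row, params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"), nrow(manifest_row) == 1)
  validate_sim_params(params)

  ppm <- manifest_ppm(manifest_row)[1, ]
  lambda <- lambda_for(params, manifest_row$setup_id)
  dose <- effective_dose(ppm, params$panel, lambda)

  times <- seq(0, params$baseline_s + params$duration_s, by = params$step_s)
  post <- times >= params$baseline_s
  tp <- pmax(times - params$baseline_s, 0)

  set.seed(as.integer(seed))
  i0 <- rnorm(1, params$i0_mean, params$i0_sd)
  if (i0 <= 0) i0 <- params$i0_mean  # degenerate draw guard

  shape <- rep(1, length(times))
  shape[post] <- trace_shape(tp[post], ppm, params, lambda)
  noise <- rnorm(length(times), 0, params$noise_sd)
  noise <- pmax(pmin(noise, 5 * params$noise_sd), -5 * params$noise_sd)
  current <- i0 * shape + noise

  clean <- i0 * shape
  di_rel_true <- (max(clean[post]) - min(clean[post])) / i0

  out <- tibble(
    sample_id = manifest_row$sample_id,
    time_s = times,
    current_mA = current
  )
  attr(out, "injection_time") <- params$baseline_s
  attr(out, "truth") <- dplyr::bind_cols(
    manifest_row,
    tibble(i0 = i0, lambda = lambda, effective_dose = dose,
           delta_i_rel_true = di_rel_true)
  )
  out
}

#' Simulate a full trace dataset from a manifest
#'
#' One trace per manifest row; per-row seeds are drawn deterministically
#' from the master seed, so the whole dataset is reproducible and
#' individual rows can be re-simulated independently.
#'
#' @param manifest Manifest tibble from [expand_manifest()].
#' @param params A [sim_params()] object.
#' @param seed Master seed (defaults to `params$seed`).
#' @return A list with elements `traces` (long tibble: `sample_id`,
#'   `time_s`, `current_mA`), `truth` (one row per sample: manifest columns
#'   plus `i0`, `lambda`, `effective_dose`, `delta_i_rel_true`), and
#'   `injection_time`.
#' @export
simulate_dataset <- function(manifest, params = sim_params(),
                             seed = params$seed) {
  if (nrow(manifest) == 0) abort("empty manifest")
  set.seed(as.integer(seed))
  row_seeds <- sample.int(.Machine$integer.max - 1L, nrow(manifest))

  traces <- vector("list", nrow(manifest))
  truths <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    tr <- simulate_trace(manifest[i, ], params, seed = row_seeds[i])
    truths[[i]] <- attr(tr, "truth")
    traces[[i]] <- tr
  }
  list(
    traces = dplyr::bind_rows(traces),
    truth = dplyr::bind_rows(truths),
    injection_time = params$baseline_s
  )
}

#' Read traces from a long-format CSV
#'
#' Expects columns `sample_id`, `time_s`, `current_mA`, the interchange
#' format used for both simulated and measured traces.
#'
#' @param path CSV file path.
#' @return A long trace tibble.
#' @export
read_traces_csv <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("sample_id", "time_s", "current_mA")
  if (!all(need %in% names(df))) {
    abort("trace CSV must have columns sample_id, time_s, current_mA")
  }
  df
}
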