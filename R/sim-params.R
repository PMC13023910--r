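#' Default per-toxicant kinetic profiles
#'
#' Each toxicant is given its own response kinetics so that mixture traces
#' carry recoverable information about their composition, mirroring the
#' mechanistic picture of an anode biofilm in which organics trigger a
#' stress transient, protein-synthesis inhibitors act with a delay, free
#' heavy-metal ions shut down electron transfer almost instantly, and
#' copper elicits an adaptive stimulation phase:
#'
#' * `beta` — inhibition slope per effective EC unit (fractional current
#'   loss at full decline per unit of effective dose);
#' * `tau_decline` — e-folding time (s) of the inhibition onset;
#' * `lag` — delay (s) before inhibition starts;
#' * `stress_amp` — stress-transient amplitude per toxic unit (fraction of
#'   baseline current);
#' * `tau_up` — timescale (s) of the stress pulse;
#' * `recovery_amp` — adaptive stimulation amplitude per toxic unit.
#'
#' @return A tibble keyed by toxicant `name`.
#' @export
default_kinetics <- function() {
  tibble(
    name         = c("formaldehyde", "tetracycline", "silver", "copper"),
    beta         = c(0.035, 0.055, 0.050, 0.012),
    tau_decline  = c(70, 200, 13, 45),
    lag          = c(0, 60, 0, 0),
    stress_amp   = c(0.45, 0.30, 0.15, 0.35),
    tau_up       = c(22, 90, 12, 160),
    recovery_amp = c(0, 0, 0, 0.50)
  )
}

#' Default mixture-interaction map
#'
#' Interaction factors (lambda) applied to selected setups: lambda > 1 is
#' synergy, lambda < 1 antagonism, 1 additivity. The defaults encode a
#' strongly synergistic formaldehyde-tetracycline 2:1 binary (lambda 1.6)
#' and a strongly antagonistic equal-ratio quaternary (lambda 0.18); all
#' other setups are additive.
#'
#' @return Named numeric vector of lambda overrides (setups not listed
#'   default to 1).
#' @export
default_lambda_map <- function() {
  c(
    "formaldehyde+tetracycline:2:1" = 1.6,
    "copper+formaldehyde+silver+tetracycline:1:1:1:1" = 0.18
  )
}

#' Simulation parameters for synthetic current traces
#'
#' Bundles every tunable of the trace generator. Three presets cover the
#' package's standard analyses:
#'
#' * `"full"` — the default dataset conditions: per-toxicant kinetics with
#'   stress transients and adaptive stimulation enabled, baseline spread
#'   and measurement noise on;
#' * `"additive"` — pure-inhibition configuration used for interaction
#'   analysis and calibration: stress and recovery disabled, noise off, so
#'   mixture responses are exactly the sum of single-toxicant responses
#'   (concentration addition holds to machine precision);
#' * `"stress_coupled"` — an isolation configuration in which the stress
#'   amplitude is the only toxicant-specific mechanism (shared pulse and
#'   decline timescales), used to validate that importance analysis
#'   surfaces the stress-amplitude feature.
#'
#' @param profile One of `"full"`, `"additive"`, `"stress_coupled"`.
#' @param panel Toxicant panel; kinetics rows must cover its members.
#' @param kinetics Per-toxicant kinetics tibble (see [default_kinetics()]).
#' @param lambda_map Named numeric vector of interaction factors per
#'   `setup_id`; missing setups default to 1.
#' @param i0_mean,i0_sd Baseline current mean and spread (mA).
#' @param f_cap Maximum inhibition fraction (0 <= f_cap < 1).
#' @param stress,recovery Logical switches for the stress transient and the
#'   adaptive stimulation term.
#' @param recovery_onset Delay (s) after injection before adaptive
#'   stimulation starts.
#' @param tau_recovery Timescale (s) of adaptive stimulation.
#' @param noise_sd Gaussian measurement noise sd (mA); draws are clipped at
#'   5 sd.
#' @param step_s Sampling interval (s).
#' @param baseline_s Pre-injection baseline duration (s).
#' @param duration_s Post-injection exposure duration (s).
#' @param seed Default master seed used by [simulate_dataset()].
#' @return An object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params()
#' p$noise_sd
#' @export
sim_params <- function(profile = c("full", "additive", "stress_coupled"),
                       panel = default_panel(),
                       kinetics = NULL,
                       lambda_map = default_lambda_map(),
                       i0_mean = 1.0, i0_sd = 0.03,
                       f_cap = 0.95,
                       stress = TRUE, recovery = TRUE,
                       recovery_onset = 100, tau_recovery = 70,
                       noise_sd = 0.005,
                       step_s = 12, baseline_s = 60, duration_s = 300,
                       seed = 42L) {
  profile <- match.arg(profile)
  if (is.null(kinetics)) {
    kinetics <- default_kinetics()
    if (!all(panel$name %in% kinetics$name)) {
      abort("no default kinetics for this panel; supply `kinetics`")
    }
    kinetics <- kinetics[match(panel$name, kinetics$name), ]
  }

  if (profile == "additive") {
    stress <- FALSE
    recovery <- FALSE
    noise_sd <- 0
  } else if (profile == "stress_coupled") {
    kinetics <- tibble(
      name         = panel$name,
      beta         = rep(0.04, nrow(panel)),
      tau_decline  = rep(60, nrow(panel)),
      lag          = rep(0, nrow(panel)),
      stress_amp   = c(0.35, 0.75, 0.15, 0.55)[seq_len(nrow(panel))],
      tau_up       = rep(22, nrow(panel)),
      recovery_amp = rep(0, nrow(panel))
    )
    recovery <- FALSE
    i0_sd <- 0.08
  }

  p <- structure(
    list(
      profile = profile, panel = panel, kinetics = kinetics,
      lambda_map = lambda_map,
      i0_mean = i0_mean, i0_sd = i0_sd, f_cap = f_cap,
      stress = stress, recovery = recovery,
      recovery_onset = recovery_onset, tau_recovery = tau_recovery,
      noise_sd = noise_sd,
      step_s = step_s, baseline_s = baseline_s, duration_s = duration_s,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  k <- p$kinetics
  need <- c("name", "beta", "tau_decline", "lag", "stress_amp", "tau_up",
            "recovery_amp")
  if (!all(need %in% names(k))) abort("kinetics tibble is missing columns")
  if (!setequal(k$name, p$panel$name)) {
    abort("kinetics must cover exactly the panel toxicants")
  }
  if (any(k$tau_decline <= 0) || any(k$tau_up <= 0) ||
      p$tau_recovery <= 0 || p$step_s <= 0) {
    abort("all timescales must be positive")
  }
  if (any(k$lag < 0) || any(k$beta < 0) || any(k$stress_amp < 0) ||
      any(k$recovery_amp < 0)) {
    abort("kinetic coefficients must be non-negative")
  }
  if (p$f_cap < 0 || p$f_cap >= 1) abort("`f_cap` must lie in [0, 1)")
  if (p$noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (p$i0_mean <= 0 || p$i0_sd < 0) abort("baseline current must be positive")
  if (any(p$lambda_map <= 0)) abort("interaction factors lambda must be > 0")
  if (p$duration_s < 3 * p$step_s) {
    abort("duration must allow at least 3 post-injection samples")
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>", x$profile, "profile;",
      nrow(x$panel), "toxicants;",
      "noise_sd =", x$noise_sd,
      "; stress =", x$stress, "; recovery =", x$recovery, "\n")
  invisible(x)
}

lambda_for <- function(params, setup_id) {
  if (!is.null(params$lambda_map) && setup_id %in% names(params$lambda_map)) {
    unname(params$lambda_map[[setup_id]])
  } else {
    1
  }
}
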