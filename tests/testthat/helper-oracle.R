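# Independent brute-force reimplementation of the 22-feature extraction,
# written with explicit loops and kept deliberately naive: it is the oracle
# the vectorized implementation is checked against, not a copy of it.
naive_features <- function(time_s, current_mA, injection_time, i0, sigma0,
                           smooth_window = 5, kappa = 3) {
  post_t <- c(); post_y <- c()
  for (i in seq_along(time_s)) {
    if (time_s[i] >= injection_time) {
      post_t <- c(post_t, time_s[i] - injection_time)
      post_y <- c(post_y, current_mA[i])
    }
  }
  n <- length(post_y)
  step <- post_t[2] - post_t[1]

  i_max <- -Inf; i_min <- Inf; t_imax <- NA; t_imin <- NA
  for (i in 1:n) {
    if (post_y[i] > i_max) { i_max <- post_y[i]; t_imax <- post_t[i] }
    if (post_y[i] < i_min) { i_min <- post_y[i]; t_imin <- post_t[i] }
  }
  delta_i <- i_max - i_min
  delta_t <- t_imax - t_imin
  duration <- post_t[n]
  i_end <- post_y[n]

  h <- (smooth_window - 1) / 2
  sm <- numeric(n)
  for (i in 1:n) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    s <- 0
    for (j in lo:hi) s <- s + post_y[j]
    sm[i] <- s / (hi - lo + 1)
  }
  d <- numeric(n - 2)
  for (i in 2:(n - 1)) d[i - 1] <- (sm[i + 1] - sm[i - 1]) / (2 * step)
  d_max <- -Inf; d_min <- Inf; t_dmax <- NA; t_dmin <- NA
  for (i in seq_along(d)) {
    if (d[i] > d_max) { d_max <- d[i]; t_dmax <- post_t[i + 1] }
    if (d[i] < d_min) { d_min <- d[i]; t_dmin <- post_t[i + 1] }
  }

  early_max <- -Inf
  for (i in 1:n) if (post_t[i] <= 60 && post_y[i] > early_max) early_max <- post_y[i]
  up <- if (early_max > i0 + kappa * sigma0) 1L else 0L
  back <- 0L
  if (t_imin < duration) {
    for (i in 1:n) {
      if (post_t[i] > t_imin && sm[i] > i_min + kappa * sigma0) back <- 1L
    }
  }

  integral <- 0
  for (i in 1:(n - 1)) {
    integral <- integral + (post_t[i + 1] - post_t[i]) *
      (post_y[i] + post_y[i + 1]) / 2
  }

  c(
    i_max = i_max, i_min = i_min, delta_i = delta_i,
    delta_i_rel = delta_i / i0,
    t_imax = t_imax, t_imin = t_imin, delta_t = delta_t,
    k_secant = if (delta_t == 0) 0 else delta_i / delta_t,
    i_rise = i_max - i0, i_drop = i0 - i_min,
    k_max0 = if (t_imax == 0) 0 else (i_max - i0) / t_imax,
    k_min0 = if (t_imin == 0) 0 else (i_min - i0) / t_imin,
    i_end = i_end, duration = duration,
    k_all = (i_end - i0) / duration,
    up = up, back = back, integral = integral,
    d_max = d_max, d_min = d_min, t_dmax = t_dmax, t_dmin = t_dmin
  )
}
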