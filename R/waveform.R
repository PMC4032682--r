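# Pulsatile velocity waveform synthesis and landmark extraction.
#
# A minimal Doppler velocity waveform model: each cardiac cycle carries a
# systolic pulse peaking at V_p and a smaller diastolic pulse peaking at
# V_m, on an end-diastolic floor V_ed, plus white measurement noise. The
# extractor inverts this: it finds the cycle length by autocorrelation and
# reads the three landmarks per cycle.

#' Waveform synthesis configuration
#'
#' @param sampling_rate Samples per second (>= 50).
#' @param n_cycles Number of cardiac cycles to synthesize (>= 2).
#' @param noise_sd Gaussian measurement noise SD in cm/s (>= 0).
#' @param systolic_fraction Fraction of the cycle occupied by the systolic
#'   upstroke/pulse (default 0.3); the systolic pulse is centered inside
#'   it, the diastolic pulse inside the remainder.
#' @return Object of class `waveform_config`.
#' @export
waveform_config <- function(sampling_rate = 200, n_cycles = 10,
                            noise_sd = 0, systolic_fraction = 0.3) {
  if (sampling_rate < 50) stop("`sampling_rate` must be >= 50 Hz", call. = FALSE)
  if (n_cycles < 2) stop("`n_cycles` must be >= 2", call. = FALSE)
  .check_nonnegative(noise_sd, "noise_sd")
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    stop("`systolic_fraction` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      sampling_rate = sampling_rate, n_cycles = n_cycles,
      noise_sd = noise_sd, systolic_fraction = systolic_fraction
    ),
    class = "waveform_config"
  )
}

#' Synthesize a pulsatile Doppler velocity waveform
#'
#' Builds a periodic velocity time series with, per cycle, one global
#' maximum at the peak-systolic velocity `v_p`, a secondary diastolic peak
#' at `v_m`, and an end-diastolic floor `v_ed`, as two raised-Gaussian
#' pulses on the floor, plus optional Gaussian noise.
#'
#' @param v_p,v_m,v_ed Velocity landmarks in cm/s with
#'   `v_p > v_m > v_ed >= 0`.
#' @param heart_rate Heart rate in Hz (> 0).
#' @param config A [waveform_config()].
#' @return Data frame with columns `t_s` (seconds) and `v_cm_s`.
#' @export
#' @examples
#' w <- synthesize_waveform(100, 35, 20, 1.0)
#' max(w$v_cm_s)
synthesize_waveform <- function(v_p, v_m, v_ed, heart_rate,
                                config = waveform_config()) {
  stopifnot(inherits(config, "waveform_config"))
  .check_positive(heart_rate, "heart_rate")
  if (!(v_p > v_m && v_m > v_ed && v_ed >= 0)) {
    stop("landmarks must satisfy v_p > v_m > v_ed >= 0", call. = FALSE)
  }
  sf <- config$systolic_fraction
  n <- round(config$n_cycles * config$sampling_rate / heart_rate)
  t <- (seq_len(n) - 1) / config$sampling_rate
  u <- (t * heart_rate) %% 1 # phase within the cycle, [0, 1)
  u_sys <- sf / 2
  u_dia <- sf + 0.35 * (1 - sf)
  sd_sys <- sf / 6
  sd_dia <- (1 - sf) / 8
  # circular phase distance so pulses wrap across cycle boundaries
  dphi <- function(u, center) pmin(abs(u - center), 1 - abs(u - center))
  v <- v_ed +
    (v_p - v_ed) * exp(-dphi(u, u_sys)^2 / (2 * sd_sys^2)) +
    (v_m - v_ed) * exp(-dphi(u, u_dia)^2 / (2 * sd_dia^2))
  if (config$noise_sd > 0) v <- v + rnorm(n, 0, config$noise_sd)
  data.frame(t_s = t, v_cm_s = v)
}

# Indices of strict local maxima of a numeric vector.
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) {
    return(integer(0))
  }
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Extract velocity landmarks from a pulsatile waveform
#'
#' Recovers `(V_p, V_m, V_ed, heart_rate)` from a velocity time series
#' covering at least two cardiac cycles. The cycle length is the dominant
#' autocorrelation lag; the series is then segmented between consecutive
#' systolic peaks, and per cycle the maximum (systolic peak), the largest
#' secondary local maximum (diastolic peak) and the minimum (end-diastolic
#' floor) are taken, with medians across cycles for robustness. The series
#' is lightly smoothed before peak picking when it is noisy.
#'
#' @param v Velocity series in cm/s (numeric vector, or the data frame from
#'   [synthesize_waveform()]).
#' @param sampling_rate Samples per second.
#' @return List with `v_p`, `v_m`, `v_ed` (cm/s) and `heart_rate` (Hz).
#' @export
extract_velocity_landmarks <- function(v, sampling_rate) {
  if (is.data.frame(v)) v <- v$v_cm_s
  .check_positive(sampling_rate, "sampling_rate")
  n <- length(v)
  if (n < sampling_rate) {
    stop("series too short for landmark extraction", call. = FALSE)
  }
  if (stats::sd(v) < 1e-8) {
    stop("no periodicity found: series is constant", call. = FALSE)
  }
  # dominant period by autocorrelation, restricted to plausible heart rates
  # (0.4--4 Hz)
  max_lag <- min(n - 1L, ceiling(sampling_rate / 0.4))
  ac <- stats::acf(v, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  lo <- max(2L, floor(sampling_rate / 4))
  lags <- lo:max_lag
  peaks <- .local_maxima(ac[lags + 1L])
  if (!length(peaks)) {
    stop("no periodicity found in the series", call. = FALSE)
  }
  cand <- lags[peaks]
  period <- cand[which.max(ac[cand + 1L])]
  if (ac[period + 1L] < 0.1) {
    stop("no periodicity found in the series", call. = FALSE)
  }
  heart_rate <- sampling_rate / period
  # light smoothing for peak picking on noisy traces
  win <- max(3L, round(period / 20))
  if (win %% 2L == 0L) win <- win + 1L
  vs <- stats::filter(v, rep(1 / win, win), sides = 2)
  vs[is.na(vs)] <- v[is.na(vs)]
  vs <- as.numeric(vs)
  # systolic peaks: prominent local maxima separated by >= 0.6 periods
  lm <- .local_maxima(vs)
  lm <- lm[order(vs[lm], decreasing = TRUE)]
  threshold <- stats::median(vs) + 0.5 * (max(vs) - stats::median(vs))
  sys_peaks <- integer(0)
  for (i in lm) {
    if (vs[i] < threshold) break
    if (!length(sys_peaks) || all(abs(sys_peaks - i) >= 0.6 * period)) {
      sys_peaks <- c(sys_peaks, i)
    }
  }
  sys_peaks <- sort(sys_peaks)
  if (length(sys_peaks) < 2L) {
    stop("fewer than two systolic peaks found; need >= 2 cycles",
      call. = FALSE
    )
  }
  v_p_cycles <- numeric(0)
  v_m_cycles <- numeric(0)
  v_ed_cycles <- numeric(0)
  guard <- max(2L, round(0.08 * period)) # exclude the systolic peak itself
  for (k in seq_len(length(sys_peaks) - 1L)) {
    a <- sys_peaks[k]
    b <- sys_peaks[k + 1L]
    seg <- vs[a:b]
    v_p_cycles <- c(v_p_cycles, max(v[a:b]))
    v_ed_cycles <- c(v_ed_cycles, min(seg))
    interior <- .local_maxima(seg)
    interior <- interior[interior > guard & interior < (b - a + 1L - guard)]
    if (length(interior)) {
      v_m_cycles <- c(v_m_cycles, max(seg[interior]))
    }
  }
  if (!length(v_m_cycles)) {
    stop("no diastolic peak found between systolic peaks", call. = FALSE)
  }
  list(
    v_p = stats::median(v_p_cycles),
    v_m = stats::median(v_m_cycles),
    v_ed = stats::median(v_ed_cycles),
    heart_rate = heart_rate
  )
}
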