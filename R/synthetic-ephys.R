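#' Generate a synthetic local field potential recording
#'
#' Emulates a carbachol-induced gamma-band LFP: a pure sinusoid of the
#' requested frequency and amplitude plus additive Gaussian noise,
#' digitized at `sample_rate`.
#'
#' @param frequency oscillator frequency, Hz (gamma band is 20-80 Hz).
#' @param amplitude sinusoid amplitude, mV.
#' @param noise_sd Gaussian noise SD, mV.
#' @param duration recording length, s.
#' @param sample_rate sampling rate, Hz (default 5 kHz; must be at least
#'   twice the oscillator frequency).
#' @param seed integer seed.
#' @return an `lfp_recording`: list with `samples` (mV), `sample_rate`,
#'   `duration` and the generating `truth`.
#' @export
gen_lfp <- function(frequency = 40, amplitude = 0.1, noise_sd = 0.05,
                    duration = 300, sample_rate = 5000, seed = 1) {
  if (sample_rate < 2 * frequency) {
    mito_stop("sample_rate must be at least twice the oscillator frequency")
  }
  n <- as.integer(round(duration * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  samples <- with_seed(seed, {
    amplitude * sin(2 * pi * frequency * t) + rnorm(n, 0, noise_sd)
  })
  structure(
    list(samples = samples, sample_rate = sample_rate, duration = duration,
         truth = list(osc_frequency = frequency, osc_amplitude = amplitude,
                      noise_sd = noise_sd)),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat("LFP recording:", x$duration, "s at", x$sample_rate, "Hz\n")
  invisible(x)
}

#' Generate a synthetic voltage-clamp trace with PSC events
#'
#' Renders each postsynaptic current as a difference-of-exponentials
#' transient (rise and decay time constants in ms) scaled so its peak
#' equals the requested amplitude, at the requested polarity (inward
#' events deflect negative), plus additive Gaussian noise. Events closer
#' together than the rise time are allowed and flagged as overlapping in
#' the returned truth.
#'
#' @param event_times event onset times, s (strictly increasing).
#' @param event_amplitudes peak amplitudes, pA (> 0).
#' @param rise_tau_ms,decay_tau_ms kinetic time constants, ms.
#' @param noise_sd Gaussian noise SD, pA.
#' @param duration trace length, s.
#' @param sample_rate sampling rate, Hz (default 10 kHz).
#' @param polarity `"inward"` (negative deflections) or `"outward"`.
#' @param seed integer seed.
#' @return a `vc_trace`: list with `current_pA`, `sample_rate`, `duration`
#'   and `truth` (event table with `overlapping` flags and the kinetic
#'   parameters).
#' @export
gen_psc_trace <- function(event_times, event_amplitudes, rise_tau_ms = 0.5,
                          decay_tau_ms = 5, noise_sd = 2, duration = 10,
                          sample_rate = 10000,
                          polarity = c("inward", "outward"), seed = 1) {
  polarity <- match.arg(polarity)
  if (length(event_times) != length(event_amplitudes)) {
    mito_stop("event_times and event_amplitudes lengths differ")
  }
  if (length(event_times) && any(diff(event_times) <= 0)) {
    mito_stop("event_times must be strictly increasing")
  }
  if (any(event_amplitudes <= 0)) mito_stop("amplitudes must be positive")
  if (rise_tau_ms >= decay_tau_ms) {
    mito_stop("rise_tau_ms must be smaller than decay_tau_ms")
  }
  n <- as.integer(round(duration * sample_rate))
  tr <- rise_tau_ms / 1000
  td <- decay_tau_ms / 1000
  # difference-of-exponentials kernel, normalized to unit peak on the
  # sampling grid so rendered peaks hit the requested amplitude exactly
  k_len <- min(n, as.integer(round(10 * td * sample_rate)))
  kt <- (seq_len(k_len) - 1) / sample_rate
  kernel <- exp(-kt / td) - exp(-kt / tr)
  kernel <- kernel / max(kernel)
  cur <- numeric(n)
  sgn <- if (polarity == "inward") -1 else 1
  for (i in seq_along(event_times)) {
    j <- as.integer(round(event_times[i] * sample_rate)) + 1L
    if (j > n) next
    span <- j:min(n, j + k_len - 1L)
    cur[span] <- cur[span] + sgn * event_amplitudes[i] * kernel[seq_along(span)]
  }
  if (noise_sd > 0) {
    cur <- cur + with_seed(seed, rnorm(n, 0, noise_sd))
  }
  overlapping <- if (length(event_times)) {
    c(FALSE, diff(event_times) < tr)
  } else logical(0)
  structure(
    list(current_pA = cur, sample_rate = sample_rate, duration = duration,
         truth = list(
           events = data.frame(time_s = event_times,
                               amplitude_pA = event_amplitudes,
                               overlapping = overlapping),
           rise_tau_ms = rise_tau_ms, decay_tau_ms = decay_tau_ms,
           noise_sd = noise_sd, polarity = polarity)),
    class = "vc_trace"
  )
}

#' Poisson event train helper
#'
#' Draws homogeneous Poisson event times with a refractory gap and
#' log-normal-ish amplitude jitter, for feeding [gen_psc_trace()].
#'
#' @param rate event rate, Hz.
#' @param duration time span, s.
#' @param amplitude_mean,amplitude_sd amplitude distribution, pA
#'   (truncated at 1 pA).
#' @param refractory minimum inter-event interval, s.
#' @param seed integer seed.
#' @return data.frame `time_s`, `amplitude_pA`.
#' @export
gen_psc_events <- function(rate, duration, amplitude_mean = 50,
                           amplitude_sd = 5, refractory = 0.003, seed = 1) {
  with_seed(seed, {
    t <- cumsum(rexp(ceiling(rate * duration * 3), rate) + refractory)
    t <- t[t < duration - 0.05]
    data.frame(time_s = t,
               amplitude_pA = pmax(1, rnorm(length(t), amplitude_mean,
                                            amplitude_sd)))
  })
}

#' Generate synthetic current-clamp step sweeps
#'
#' A leaky integrate-and-fire style cell: subthreshold responses follow RC
#' charging with the given input resistance and membrane time constant;
#' when the voltage crosses `threshold_mV` a stereotyped action-potential
#' waveform is pasted in and the voltage resets. Ground truth (R, tau,
#' threshold, rheobase) is returned for estimator validation.
#'
#' @param steps_pA vector of current steps, pA (include hyperpolarizing and
#'   suprathreshold steps).
#' @param r_mohm input resistance, MOhm.
#' @param tau_ms membrane time constant, ms.
#' @param e_rest_mV resting potential, mV.
#' @param threshold_mV spike threshold, mV.
#' @param step_on,step_off step window, s.
#' @param duration sweep length, s.
#' @param sample_rate Hz.
#' @param noise_sd voltage noise SD, mV.
#' @param seed integer seed.
#' @return a `cc_sweeps`: list with `time_s`, `voltage_mV` (samples x
#'   sweeps), `current_pA`, `step_window`, `sample_rate` and `truth`.
#' @export
gen_cc_sweeps <- function(steps_pA = seq(-100, 500, by = 20), r_mohm = 100,
                          tau_ms = 10, e_rest_mV = -70, threshold_mV = -40,
                          step_on = 0.1, step_off = 0.6, duration = 0.8,
                          sample_rate = 20000, noise_sd = 0, seed = 1) {
  n <- as.integer(round(duration * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  dt <- 1 / sample_rate
  tau <- tau_ms / 1000
  # stereotyped AP: 0.4 ms rise to +30 mV, 0.6 ms fall to reset
  ap_rise <- as.integer(round(0.0004 * sample_rate))
  ap_fall <- as.integer(round(0.0006 * sample_rate))
  ap_peak <- 30
  reset <- threshold_mV - 15
  v_mat <- with_seed(seed, {
    vapply(steps_pA, function(I) {
      v <- numeric(n)
      v[1] <- e_rest_mV
      i <- 1L
      while (i < n) {
        inj <- if (t[i] >= step_on && t[i] < step_off) I else 0
        v_inf <- e_rest_mV + inj * r_mohm / 1000  # pA * MOhm = 1e-3 mV
        v[i + 1L] <- v_inf + (v[i] - v_inf) * exp(-dt / tau)
        i <- i + 1L
        if (v[i] >= threshold_mV) {
          up <- seq(threshold_mV, ap_peak, length.out = ap_rise)
          down <- seq(ap_peak, reset, length.out = ap_fall)
          wave <- c(up[-1], down[-1])
          span <- i:min(n, i + length(wave) - 1L)
          v[span] <- wave[seq_along(span)]
          i <- max(span)
        }
      }
      if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
      v
    }, numeric(n))
  })
  structure(
    list(time_s = t, voltage_mV = v_mat, current_pA = steps_pA,
         step_window = c(step_on, step_off), sample_rate = sample_rate,
         truth = list(r_mohm = r_mohm, tau_ms = tau_ms,
                      threshold_mV = threshold_mV, e_rest_mV = e_rest_mV)),
    class = "cc_sweeps"
  )
}

#' Generate a synthetic field EPSP trace
#'
#' A stimulus artifact (brief square pulse) followed after a synaptic
#' delay by an alpha-function field response of known amplitude and time
#' constant, plus optional noise.
#'
#' @param amplitude response amplitude, mV (positive number; rendered as a
#'   negative-going field potential).
#' @param tau_ms alpha-function time constant, ms.
#' @param stim_time artifact time, s.
#' @param delay_ms synaptic delay from artifact to response onset, ms.
#' @param duration,sample_rate trace geometry.
#' @param noise_sd noise SD, mV.
#' @param seed integer seed.
#' @return list with `t_s`, `v_mV`, `stim_time` and `truth`.
#' @export
gen_fepsp <- function(amplitude = 1, tau_ms = 4, stim_time = 0.01,
                      delay_ms = 2, duration = 0.08, sample_rate = 20000,
                      noise_sd = 0, seed = 1) {
  n <- as.integer(round(duration * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  v <- numeric(n)
  v[t >= stim_time & t < stim_time + 0.0005] <- 5  # artifact
  t0 <- stim_time + delay_ms / 1000
  tau <- tau_ms / 1000
  tr <- t - t0
  resp <- ifelse(tr > 0, -amplitude * (tr / tau) * exp(1 - tr / tau), 0)
  v <- v + resp
  if (noise_sd > 0) v <- v + with_seed(seed, rnorm(n, 0, noise_sd))
  list(t_s = t, v_mV = v, stim_time = stim_time,
       truth = list(amplitude = amplitude, tau_ms = tau_ms,
                    onset_s = t0))
}
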