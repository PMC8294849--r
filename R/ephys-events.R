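#' Detect spontaneous postsynaptic currents
#'
#' The trace is zero-phase low-pass filtered (4th-order Butterworth,
#' `lp_cutoff`), median-baseline subtracted and rectified into the stated
#' polarity. Candidate events are local maxima exceeding the initial
#' threshold (3 pA); candidates whose peak amplitude is below
#' `noise_mult` times the noise SD are then excluded. The noise SD is
#' estimated robustly as `1.4826 * MAD` of the raw, baseline-subtracted
#' trace outside candidate event windows, so large events do not inflate
#' it and the floor reflects the acquisition noise itself. Every
#' returned amplitude therefore satisfies both the 3 pA floor and the
#' 5 x SD(noise) floor.
#'
#' @param trace a `vc_trace` from [gen_psc_trace()], or a list with
#'   `current_pA` and `sample_rate`.
#' @param polarity `"inward"` (events deflect negative) or `"outward"`.
#' @param init_threshold initial detection threshold, pA.
#' @param noise_mult multiple of the noise SD an event must exceed.
#' @param lp_cutoff low-pass corner frequency, Hz (sample rate must exceed
#'   twice this).
#' @param min_iei_ms minimum separation between detected peaks, ms.
#' @return a `psc_events` object: data.frame `time_s`, `amplitude_pA`
#'   (positive magnitudes), with `median_iei_s`, `median_amplitude_pA` and
#'   `noise_sd_pA` as attributes (also via `summary()`).
#' @export
detect_pscs <- function(trace, polarity = NULL, init_threshold = 3,
                        noise_mult = 5, lp_cutoff = 1000, min_iei_ms = 2) {
  fs <- trace$sample_rate
  if (fs <= 2 * lp_cutoff) mito_stop("sample rate must exceed 2 * lp_cutoff")
  x <- trace$current_pA
  if (length(x) < 4 * as.integer(fs / lp_cutoff) + 20) {
    mito_stop("trace too short for filtering")
  }
  if (is.null(polarity)) {
    polarity <- trace$truth$polarity %||% "inward"
  }
  bf <- signal::butter(4, lp_cutoff / (fs / 2), type = "low")
  xf <- signal::filtfilt(bf, x)
  xf <- xf - median(xf)
  y <- if (polarity == "inward") -xf else xf

  guard <- as.integer(round(0.005 * fs))
  cand <- y > init_threshold
  if (any(cand)) {
    r <- rle(cand)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    mask <- logical(length(y))
    for (i in which(r$values)) {
      mask[max(1, starts[i] - guard):min(length(y), ends[i] + guard)] <- TRUE
    }
  } else {
    mask <- logical(length(y))
  }
  # noise SD of the recording itself (robust MAD of the unfiltered,
  # baseline-subtracted trace outside event windows), so the 5 x SD floor
  # reflects the acquisition noise rather than its low-passed remnant
  noise_sd <- if (all(mask)) mad(x - median(x)) else mad((x - median(x))[!mask])
  amp_floor <- max(init_threshold, noise_mult * noise_sd)

  # one candidate per suprathreshold run; superimposed events within a run
  # are split at local maxima whose rise from the preceding valley clears
  # the amplitude floor (so ripple on decay tails is not double-counted)
  times <- numeric(0)
  amps <- numeric(0)
  min_gap <- max(1L, as.integer(round(min_iei_ms / 1000 * fs)))
  if (any(cand)) {
    r <- rle(cand)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      s <- starts[i]
      e <- ends[i]
      seg <- y[s:e]
      base <- if (s > 1) {
        median(y[max(1, s - as.integer(round(0.005 * fs))):(s - 1)])
      } else 0
      if (length(seg) < 3) {
        pk <- which.max(seg)
      } else {
        pk <- which(diff(sign(diff(seg))) < 0) + 1L
        if (!length(pk)) pk <- which.max(seg)
      }
      last_pk <- NA_integer_
      for (p in pk) {
        ref <- if (is.na(last_pk)) base else min(seg[last_pk:p])
        a <- seg[p] - ref
        if (a >= amp_floor && (is.na(last_pk) || p - last_pk >= min_gap)) {
          times <- c(times, (s + p - 2) / fs)
          amps <- c(amps, a)
          last_pk <- p
        }
      }
    }
  }
  events <- data.frame(time_s = times, amplitude_pA = amps)
  structure(events,
            class = c("psc_events", "data.frame"),
            median_iei_s = if (nrow(events) > 1) median(diff(events$time_s)) else NA_real_,
            median_amplitude_pA = if (nrow(events)) median(events$amplitude_pA) else NA_real_,
            noise_sd_pA = noise_sd, polarity = polarity)
}

#' @export
summary.psc_events <- function(object, ...) {
  list(n_events = nrow(object),
       median_iei_s = attr(object, "median_iei_s"),
       median_amplitude_pA = attr(object, "median_amplitude_pA"),
       noise_sd_pA = attr(object, "noise_sd_pA"))
}

#' @export
print.psc_events <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("%d PSC events; median IEI %.4g s, median amplitude %.4g pA (noise SD %.3g pA)\n",
              s$n_events, s$median_iei_s, s$median_amplitude_pA, s$noise_sd_pA))
  invisible(x)
}

# peak amplitude of a response in a window, relative to a 5 ms pre-baseline
response_amplitude <- function(y, fs, t0, window) {
  i0 <- as.integer(round(t0 * fs)) + 1L
  i1 <- min(length(y), i0 + as.integer(round(window * fs)))
  if (i0 >= i1) return(NA_real_)
  pre <- y[max(1, i0 - as.integer(round(0.005 * fs))):max(1, i0 - 1)]
  max(y[i0:i1]) - median(pre)
}

#' Recovery of synaptic responses after train stimulation
#'
#' For each stimulus train, the response amplitude at each probe time is
#' normalized to the amplitude of the first peak in that train
#' (`100 * probe / first`), and the percentages are averaged across
#' trains. Trains whose first peak is undetectable (below `min_first_pA`)
#' are excluded with a warning.
#'
#' @param trace a `vc_trace` (or list with `current_pA`, `sample_rate`).
#' @param train_times onset times of the first pulse of each train, s.
#' @param probe_offsets probe times relative to each train onset, s.
#' @param window response search window after each time point, s.
#' @param polarity deflection polarity of the responses.
#' @param min_first_pA smallest usable first-peak amplitude, pA.
#' @return list: `mean_percent` (named by probe offset), `per_train`
#'   (matrix trains x probes), `first_peak_pA`.
#' @export
train_recovery <- function(trace, train_times, probe_offsets,
                           window = 0.05, polarity = "inward",
                           min_first_pA = 1) {
  fs <- trace$sample_rate
  y <- trace$current_pA - median(trace$current_pA)
  if (polarity == "inward") y <- -y
  per <- matrix(NA_real_, length(train_times), length(probe_offsets))
  first <- numeric(length(train_times))
  for (i in seq_along(train_times)) {
    first[i] <- response_amplitude(y, fs, train_times[i], window)
    if (!is.finite(first[i]) || first[i] < min_first_pA) {
      warning("train ", i, ": first peak undetectable; excluded")
      first[i] <- NA_real_
      next
    }
    for (j in seq_along(probe_offsets)) {
      per[i, j] <- 100 * response_amplitude(y, fs, train_times[i] +
                                              probe_offsets[j], window) / first[i]
    }
  }
  colnames(per) <- signif(probe_offsets, 4)
  list(mean_percent = colMeans(per, na.rm = TRUE), per_train = per,
       first_peak_pA = first)
}

#' Intrinsic membrane properties from current-clamp step sweeps
#'
#' Estimates passive and active properties from a family of square
#' current steps: input resistance as the slope of the steady-state
#' voltage deflection versus injected current over hyperpolarizing steps;
#' membrane time constant from a single-exponential fit to the onset of
#' the largest hyperpolarizing step; spike threshold as the voltage where
#' dV/dt first exceeds `dvdt_thresh` (20 V/s); action-potential amplitude
#' from threshold to peak and half-width at half that height; rheobase as
#' the smallest step evoking at least one spike; and the spike rate on the
#' sweep closest to rheobase + 40 pA.
#'
#' @param sweeps a `cc_sweeps` object (see [gen_cc_sweeps()]) or a list
#'   with `time_s`, `voltage_mV` (samples x sweeps), `current_pA`,
#'   `step_window`, `sample_rate`.
#' @param dvdt_thresh spike-threshold criterion on dV/dt, V/s.
#' @return list: `input_resistance_mohm`, `tau_m_ms`, `threshold_mV`,
#'   `ap_amplitude_mV`, `ap_halfwidth_ms`, `rheobase_pA`,
#'   `spike_rate_rheo40_hz`. Active properties are `NA` (with rheobase
#'   flagged) when no sweep spikes.
#' @export
intrinsic_properties <- function(sweeps, dvdt_thresh = 20) {
  t <- sweeps$time_s
  v <- sweeps$voltage_mV
  I <- sweeps$current_pA
  fs <- sweeps$sample_rate
  on <- sweeps$step_window[1]
  off <- sweeps$step_window[2]
  base_idx <- t < on
  steady_idx <- t >= on + (off - on) * 0.7 & t < off

  spike_counts <- vapply(seq_along(I), function(k) {
    count_spikes(v[, k], fs, dvdt_thresh)$n
  }, integer(1))

  hyp <- which(I < 0 & spike_counts == 0)
  if (length(hyp) < 2) mito_stop("need at least two hyperpolarizing sweeps")
  dv <- vapply(hyp, function(k) {
    mean(v[steady_idx, k]) - mean(v[base_idx, k])
  }, numeric(1))
  rin <- unname(coef(lm(dv ~ I[hyp]))[2]) * 1000  # mV/pA -> MOhm

  k_tau <- hyp[which.min(I[hyp])]
  on_i <- which(t >= on)[1]
  seg_idx <- on_i:min(length(t), on_i + as.integer(0.1 * fs))
  ts <- t[seg_idx] - t[on_i]
  vs <- v[seg_idx, k_tau]
  v0 <- mean(v[base_idx, k_tau])
  v_inf0 <- mean(v[steady_idx, k_tau])
  fit <- tryCatch(
    minpack.lm::nlsLM(vs ~ vi + (v0f - vi) * exp(-ts / tau),
                      start = list(vi = v_inf0, v0f = v0, tau = 0.01)),
    error = function(e) NULL
  )
  tau_ms <- if (is.null(fit)) NA_real_ else 1000 * coef(fit)[["tau"]]

  out <- list(input_resistance_mohm = rin, tau_m_ms = tau_ms,
              threshold_mV = NA_real_, ap_amplitude_mV = NA_real_,
              ap_halfwidth_ms = NA_real_, rheobase_pA = NA_real_,
              spike_rate_rheo40_hz = NA_real_)
  spk <- which(spike_counts > 0 & I > 0)
  if (!length(spk)) {
    attr(out, "rheobase_undefined") <- TRUE
    return(out)
  }
  rheo_k <- spk[which.min(I[spk])]
  out$rheobase_pA <- I[rheo_k]
  sp <- count_spikes(v[, rheo_k], fs, dvdt_thresh)
  thr_i <- sp$threshold_idx[1]
  out$threshold_mV <- v[thr_i, rheo_k]
  pk_i <- sp$peak_idx[1]
  out$ap_amplitude_mV <- v[pk_i, rheo_k] - out$threshold_mV
  half <- out$threshold_mV + out$ap_amplitude_mV / 2
  above <- which(v[, rheo_k] >= half)
  above <- above[above >= thr_i & above <= thr_i + as.integer(0.005 * fs)]
  out$ap_halfwidth_ms <- if (length(above)) 1000 * length(above) / fs else NA_real_
  k40 <- which.min(abs(I - (out$rheobase_pA + 40)))
  out$spike_rate_rheo40_hz <- spike_counts[k40] / (off - on)
  out
}

# spikes as upward dV/dt threshold crossings followed by a local peak
count_spikes <- function(v, fs, dvdt_thresh = 20) {
  dvdt <- c(0, diff(v)) * fs / 1000  # mV/sample -> V/s
  up <- which(dvdt >= dvdt_thresh & c(0, head(dvdt, -1)) < dvdt_thresh)
  # merge crossings within 2 ms (same AP)
  if (length(up) > 1) up <- up[c(TRUE, diff(up) > 0.002 * fs)]
  peaks <- vapply(up, function(i) {
    i + which.max(v[i:min(length(v), i + as.integer(0.003 * fs))]) - 1L
  }, integer(1))
  # dV/dt at sample i is the step from i-1, so the last subthreshold
  # voltage sits one sample earlier
  list(n = length(up), threshold_idx = pmax(1L, up - 1L), peak_idx = peaks)
}

#' Field EPSP slope
#'
#' Measures the initial slope of a field EPSP: the stimulus artifact is
#' blanked, the response peak found, and a line fitted over the 20-80%
#' span of the initial phase between response onset and peak. If no
#' deflection exceeds `noise_floor`, a zero slope is returned with
#' attribute `no_response = TRUE`.
#'
#' @param trace list with `t_s` and `v_mV` (or a [gen_fepsp()] output).
#' @param stim_time stimulus artifact time, s.
#' @param blank_ms artifact blanking interval after `stim_time`, ms.
#' @param window response search window after blanking, s.
#' @param noise_floor smallest deflection treated as a response, mV.
#' @return slope in mV/ms (negative for negative-going fields).
#' @export
fepsp_slope <- function(trace, stim_time = trace$stim_time, blank_ms = 1.5,
                        window = 0.03, noise_floor = 0.05) {
  t <- trace$t_s
  v <- trace$v_mV
  fs <- 1 / (t[2] - t[1])
  base <- median(v[t < stim_time])
  v <- v - base
  t0 <- stim_time + blank_ms / 1000
  sel <- which(t >= t0 & t <= t0 + window)
  if (max(abs(v[sel])) < noise_floor) {
    return(structure(0, no_response = TRUE))
  }
  sgn <- if (abs(min(v[sel])) >= abs(max(v[sel]))) -1 else 1
  y <- sgn * v[sel]  # response now positive-going
  pk <- which.max(y)
  amp <- y[pk]
  rise <- y[1:pk]
  i20 <- which(rise >= 0.2 * amp)[1]
  i80 <- which(rise >= 0.8 * amp)[1]
  if (is.na(i20) || is.na(i80) || i80 <= i20) {
    return(structure(0, no_response = TRUE))
  }
  seg <- i20:i80
  fit <- lm(y[seg] ~ t[sel][seg])
  sgn * unname(coef(fit)[2]) / 1000  # mV/s -> mV/ms
}

#' Input-output curve of fEPSP slopes
#'
#' @param traces list of fEPSP traces (see [fepsp_slope()]).
#' @param intensities stimulation intensities, one per trace.
#' @param ... passed to [fepsp_slope()].
#' @return data.frame `intensity`, `slope_mv_ms`.
#' @export
io_curve <- function(traces, intensities, ...) {
  stopifnot(length(traces) == length(intensities))
  data.frame(
    intensity = intensities,
    slope_mv_ms = vapply(traces, function(tr) as.numeric(fepsp_slope(tr, ...)),
                         numeric(1))
  )
}
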