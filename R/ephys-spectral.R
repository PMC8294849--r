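#' Power spectrum of an LFP recording
#'
#' Computes the normalized magnitude-squared FFT power spectrum of the
#' first `window` seconds of the recording. The default estimator is
#' Welch's method (Hann-windowed segments, 50% overlap; 2-s segments give
#' 0.5 Hz resolution), which stabilizes peak statistics; a single FFT over
#' the whole window is available with `method = "single_fft"`. The
#' normalization satisfies Parseval's relation: the power summed over all
#' frequency bins equals the signal variance. Frequencies inside
#' `mains_exclusion` (49-51 Hz by default, around the 50 Hz mains) are
#' flagged and ignored by all band statistics.
#'
#' @param lfp an `lfp_recording`, or a list with `samples` and
#'   `sample_rate`.
#' @param window analysis period, s (default 300 s; must not exceed the
#'   recording).
#' @param segment_s Welch segment length, s.
#' @param overlap Welch segment overlap fraction.
#' @param mains_exclusion `(lo, hi)` Hz band excluded from band
#'   statistics, or `NULL` to keep everything.
#' @param method `"welch"` or `"single_fft"`.
#' @return a `power_spectrum` data.frame: `freq_hz`, `power`, `excluded`
#'   (logical), with the excluded band in attribute `excluded_band`.
#' @export
power_spectrum <- function(lfp, window = 300, segment_s = 2, overlap = 0.5,
                           mains_exclusion = c(49, 51),
                           method = c("welch", "single_fft")) {
  method <- match.arg(method)
  fs <- lfp$sample_rate
  x <- lfp$samples
  n_want <- as.integer(round(window * fs))
  if (n_want > length(x)) {
    mito_stop("analysis window (", window, " s) exceeds the recording")
  }
  x <- x[seq_len(n_want)]
  if (method == "single_fft") {
    seg_len <- n_want
    starts <- 1L
    w <- rep(1, seg_len)
  } else {
    seg_len <- as.integer(round(segment_s * fs))
    if (seg_len > n_want) mito_stop("segment_s exceeds the analysis window")
    hop <- max(1L, as.integer(round(seg_len * (1 - overlap))))
    starts <- seq(1L, n_want - seg_len + 1L, by = hop)
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / seg_len)  # Hann
  }
  norm <- seg_len * sum(w^2)
  acc <- numeric(seg_len)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- seg - mean(seg)
    acc <- acc + Mod(fft(seg * w))^2 / norm
  }
  p_full <- acc / length(starts)
  # fold to one-sided; total power over returned bins = variance
  half <- floor(seg_len / 2)
  p <- p_full[1:(half + 1)]
  if (seg_len %% 2 == 0) {
    p[2:half] <- p[2:half] + rev(p_full[(half + 2):seg_len])
  } else {
    p[2:(half + 1)] <- p[2:(half + 1)] + rev(p_full[(half + 2):seg_len])
  }
  freq <- (0:half) * fs / seg_len
  excluded <- if (is.null(mains_exclusion)) rep(FALSE, length(freq)) else {
    freq >= mains_exclusion[1] & freq <= mains_exclusion[2]
  }
  structure(data.frame(freq_hz = freq, power = p, excluded = excluded),
            class = c("power_spectrum", "data.frame"),
            excluded_band = mains_exclusion, sample_rate = fs)
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat("power spectrum:", nrow(x), "bins, resolution",
      signif(x$freq_hz[2] - x$freq_hz[1], 3), "Hz\n")
  invisible(x)
}

#' Gamma-band summary metrics of a power spectrum
#'
#' Peak power is the maximum in-band power (mains-excluded bins ignored),
#' peak frequency the frequency at which it occurs, and power area the
#' trapezoidal integral of the in-band spectrum.
#'
#' @param spec a `power_spectrum`, or a data.frame with `freq_hz` and
#'   `power` columns (an `excluded` column is honored when present).
#' @param band analysis band in Hz (default the 20-80 Hz gamma range).
#' @return list of class `gamma_metrics`: `peak_frequency` (Hz),
#'   `peak_power`, `power_area`.
#' @export
gamma_metrics <- function(spec, band = c(20, 80)) {
  excl <- if ("excluded" %in% names(spec)) spec$excluded else FALSE
  sel <- spec$freq_hz >= band[1] & spec$freq_hz <= band[2] & !excl
  if (!any(sel)) mito_stop("spectrum does not cover the requested band")
  f <- spec$freq_hz[sel]
  p <- spec$power[sel]
  if (all(p == 0)) {
    mito_stop("all-zero spectrum in band: peak undefined",
              class = "mitodyn_undefined")
  }
  i <- which.max(p)
  structure(list(peak_frequency = f[i], peak_power = p[i],
                 power_area = pracma::trapz(f, p)),
            class = "gamma_metrics")
}

#' @export
print.gamma_metrics <- function(x, ...) {
  cat(sprintf("gamma metrics: peak %.3g at %.4g Hz, area %.3g\n",
              x$peak_power, x$peak_frequency, x$power_area))
  invisible(x)
}

#' 50% width of the spectral peak from a Gaussian fit
#'
#' Fits `baseline + a * exp(-(f - mu)^2 / (2 sigma^2))` to the in-band
#' spectrum by Levenberg-Marquardt least squares and reports the full
#' width at half maximum, `2 * sqrt(2 * ln 2) * sigma` (~2.355 sigma), a
#' measure of oscillation frequency dispersion. Mains-excluded bins are
#' dropped before fitting. Non-convergence raises an error (class
#' `mitodyn_fit_error`) rather than returning a default.
#'
#' @inheritParams gamma_metrics
#' @return width at 50% height, Hz, with the fit in attribute `fit`.
#' @export
spectrum_width50 <- function(spec, band = c(20, 80)) {
  excl <- if ("excluded" %in% names(spec)) spec$excluded else FALSE
  sel <- spec$freq_hz >= band[1] & spec$freq_hz <= band[2] & !excl
  f <- spec$freq_hz[sel]
  p <- spec$power[sel]
  if (length(f) < 5) mito_stop("too few in-band bins for a Gaussian fit")
  b0 <- min(p)
  a0 <- max(p) - b0
  if (a0 <= 0) mito_stop("no spectral peak in band", class = "mitodyn_fit_error")
  mu0 <- f[which.max(p)]
  above <- f[p - b0 > a0 / 2]
  s0 <- max(diff(range(above)) / 2.3548, diff(f)[1])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      p ~ b + a * exp(-(f - mu)^2 / (2 * sigma^2)),
      start = list(b = b0, a = a0, mu = mu0, sigma = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      mito_stop("Gaussian fit did not converge: ", conditionMessage(e),
                class = "mitodyn_fit_error")
    }
  )
  sigma <- abs(coef(fit)[["sigma"]])
  structure(2 * sqrt(2 * log(2)) * sigma, fit = fit)
}

#' Autocorrelogram of an LFP recording
#'
#' Normalized autocorrelation (1 at lag zero) out to `max_lag` seconds,
#' mirrored to negative lags, used to assess the rhythmicity of an
#' oscillation: a rhythmic signal shows side peaks at multiples of its
#' period.
#'
#' @inheritParams power_spectrum
#' @param max_lag largest lag, s (must be below the recording duration).
#' @return data.frame `lag_s`, `correlation`, symmetric in lag.
#' @export
autocorrelogram <- function(lfp, max_lag = 0.5) {
  fs <- lfp$sample_rate
  n_lag <- as.integer(round(max_lag * fs))
  if (n_lag >= length(lfp$samples)) {
    mito_stop("max_lag must be shorter than the recording")
  }
  a <- acf(lfp$samples, lag.max = n_lag, plot = FALSE, demean = TRUE)
  r <- as.numeric(a$acf)
  data.frame(lag_s = c(rev(-seq_len(n_lag)), 0, seq_len(n_lag)) / fs,
             correlation = c(rev(r[-1]), r))
}
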