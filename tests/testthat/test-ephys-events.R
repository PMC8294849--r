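test_that("synthetic PSC traces have the stated peak and polarity", {
  tr <- gen_psc_trace(2, 50, noise_sd = 0, duration = 4, seed = 1)
  expect_equal(min(tr$current_pA), -50, tolerance = 1e-9)
  expect_equal(tr$truth$events$amplitude_pA, 50)
  none <- gen_psc_trace(numeric(0), numeric(0), noise_sd = 1, duration = 2,
                        seed = 2)
  expect_equal(sd(none$current_pA), 1, tolerance = 0.05)
  # close events are allowed but flagged
  close <- gen_psc_trace(c(1, 1.0003), c(30, 30), noise_sd = 0, duration = 2)
  expect_equal(close$truth$events$overlapping, c(FALSE, TRUE))
})

test_that("isolated events are detected with accurate amplitudes", {
  tr <- gen_psc_trace(c(1, 3, 5), rep(50, 3), noise_sd = 2, duration = 7,
                      seed = 1)
  ev <- detect_pscs(tr)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$amplitude_pA, rep(50, 3), tolerance = 50 * 0.05)
  expect_equal(ev$time_s, c(1, 3, 5) + 0.001, tolerance = 0.003)
})

test_that("the 3 pA and 5xSD floors govern inclusion", {
  # 8 pA event, 2 pA noise: 5 x SD = 10 pA -> excluded
  tr8 <- gen_psc_trace(2, 8, noise_sd = 2, duration = 4, seed = 1)
  expect_equal(nrow(detect_pscs(tr8)), 0)
  # 2 pA event, almost no noise: below the 3 pA initial threshold
  tr2 <- gen_psc_trace(2, 2, noise_sd = 1e-6, duration = 4, seed = 1)
  expect_equal(nrow(detect_pscs(tr2)), 0)
  # 8 pA with low noise passes both floors
  tr_ok <- gen_psc_trace(2, 8, noise_sd = 0.5, duration = 4, seed = 1)
  expect_equal(nrow(detect_pscs(tr_ok)), 1)
})

test_that("every returned amplitude satisfies both floors", {
  for (s in 1:5) {
    ev_t <- gen_psc_events(8, 8, amplitude_mean = 30, amplitude_sd = 15,
                           seed = s)
    tr <- gen_psc_trace(ev_t$time_s, ev_t$amplitude_pA, noise_sd = 2,
                        duration = 8, seed = s)
    ev <- detect_pscs(tr)
    floor_ <- max(3, 5 * attr(ev, "noise_sd_pA"))
    expect_true(all(ev$amplitude_pA >= floor_))
  }
})

test_that("detection keeps precision and recall at 0.95 on high-SNR trains", {
  stats <- vapply(1:100, function(s) {
    ev_t <- gen_psc_events(10, 5, amplitude_mean = 50, amplitude_sd = 5,
                           seed = s)
    tr <- gen_psc_trace(ev_t$time_s, ev_t$amplitude_pA, noise_sd = 2,
                        duration = 5, seed = s)
    ev <- detect_pscs(tr)
    tp <- sum(vapply(ev_t$time_s, function(t0) {
      any(abs(ev$time_s - t0) < 0.005)
    }, logical(1)))
    c(recall = tp / nrow(ev_t), precision = tp / max(1, nrow(ev)))
  }, numeric(2))
  expect_gte(mean(stats["recall", ]), 0.95)
  expect_gte(mean(stats["precision", ]), 0.95)
})

test_that("summary statistics reflect the generating process", {
  ev_t <- gen_psc_events(10, 20, amplitude_mean = 60, seed = 3)
  tr <- gen_psc_trace(ev_t$time_s, ev_t$amplitude_pA, noise_sd = 2,
                      duration = 20, seed = 3)
  s <- summary(detect_pscs(tr))
  expect_equal(s$median_amplitude_pA, median(ev_t$amplitude_pA),
               tolerance = 0.1 * 60)
  expect_equal(s$median_iei_s, median(diff(ev_t$time_s)), tolerance = 0.02)
  expect_equal(s$noise_sd_pA, 2, tolerance = 0.2)
})

test_that("train recovery normalizes probes to the first peak", {
  tr <- gen_psc_trace(c(1, 1.5), c(100, 80), noise_sd = 0.1, duration = 3,
                      seed = 1)
  rec <- train_recovery(tr, train_times = 1, probe_offsets = 0.5)
  expect_equal(unname(rec$mean_percent), 80, tolerance = 2)
  # equal probe: 100%
  tr2 <- gen_psc_trace(c(1, 2), c(60, 60), noise_sd = 0.1, duration = 3.5,
                       seed = 2)
  rec2 <- train_recovery(tr2, 1, 1)
  expect_equal(unname(rec2$mean_percent), 100, tolerance = 2)
})

test_that("a known depression model is recovered across 10 trains", {
  # per-train first peak 100 pA; probes at 60/80/90% recovery
  frac <- c(0.6, 0.8, 0.9)
  onsets <- seq(1, by = 3, length.out = 10)
  times <- c(outer(c(0, 0.8, 1.6, 2.4), onsets, `+`))
  amps <- rep(c(100, 100 * frac), 10)
  tr <- gen_psc_trace(sort(times), amps[order(times)], noise_sd = 0.2,
                      duration = 32, seed = 4)
  rec <- train_recovery(tr, onsets, c(0.8, 1.6, 2.4))
  expect_equal(unname(rec$mean_percent), 100 * frac, tolerance = 3)
})

test_that("intrinsic properties recover the generating cell parameters", {
  sw <- gen_cc_sweeps(r_mohm = 100, tau_ms = 10, threshold_mV = -40,
                      seed = 1)
  ip <- intrinsic_properties(sw)
  expect_equal(ip$input_resistance_mohm, 100, tolerance = 0.01)
  expect_equal(ip$tau_m_ms, 10, tolerance = 0.1)
  expect_equal(ip$threshold_mV, -40, tolerance = 1)
  expect_gt(ip$ap_amplitude_mV, 50)
  expect_gt(ip$spike_rate_rheo40_hz, 0)
  # Ohm check: rheobase ~ (threshold - rest) / R
  expect_equal(ip$rheobase_pA, 300, tolerance = 25)
  # no suprathreshold sweeps: rheobase undefined
  sub <- gen_cc_sweeps(steps_pA = seq(-100, 100, 20), seed = 1)
  ip2 <- intrinsic_properties(sub)
  expect_true(is.na(ip2$rheobase_pA))
  expect_true(isTRUE(attr(ip2, "rheobase_undefined")))
  expect_equal(ip2$input_resistance_mohm, 100, tolerance = 0.01)
})

test_that("fEPSP slopes are linear in amplitude and match the alpha-function chord", {
  fe <- gen_fepsp(amplitude = 1, tau_ms = 4)
  s1 <- as.numeric(fepsp_slope(fe))
  s2 <- as.numeric(fepsp_slope(gen_fepsp(amplitude = 2, tau_ms = 4)))
  expect_equal(s2, 2 * s1, tolerance = 1e-6)
  expect_lt(s1, 0)  # negative-going field
  # closed-form 20-80% chord of the alpha function a*(t/tau)e^(1-t/tau)
  tau <- 0.004
  t20 <- uniroot(function(t) (t / tau) * exp(1 - t / tau) - 0.2,
                 c(1e-6, tau))$root
  t80 <- uniroot(function(t) (t / tau) * exp(1 - t / tau) - 0.8,
                 c(1e-6, tau))$root
  chord <- -1 * (0.8 - 0.2) / (t80 - t20) / 1000  # mV/ms
  expect_equal(s1, chord, tolerance = abs(chord) * 0.05)
  # flat trace: zero slope with flag
  flat <- list(t_s = seq(0, 0.08, 5e-5), v_mV = rep(0, 1601), stim_time = 0.01)
  expect_true(isTRUE(attr(fepsp_slope(flat), "no_response")))
  # io curve is monotone for increasing amplitudes
  tr_list <- lapply(c(0.5, 1, 2), function(a) gen_fepsp(amplitude = a))
  io <- io_curve(tr_list, c(1, 2, 3))
  expect_true(all(diff(abs(io$slope_mv_ms)) > 0))
})
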