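# kymograph wrapper around a plain matrix
as_kymo <- function(m, bin_um = 3.5, dt_s = 45) {
  structure(list(intensity = m, count = NULL, bin_width_px = 10,
                 bin_width_um = bin_um, pixel_size_um = 0.35,
                 frame_interval_s = dt_s), class = "kymograph")
}

test_that("inflections land on the steepest point of a step profile", {
  bins <- 1:60
  x0_bin <- 25
  prof <- 1 / (1 + exp(-(bins - x0_bin) / 2))
  kymo <- as_kymo(matrix(prof, ncol = 3, nrow = 60))
  pts <- find_inflections(kymo, smooth_sigma_bins = 2)
  expect_equal(nrow(pts), 3)
  # x* within half a bin of the logistic centre, in physical units
  expect_true(all(abs(pts$x_um - (x0_bin - 0.5) * 3.5) <= 0.5 * 3.5))
  # a uniform profile emits no inflection
  expect_equal(nrow(find_inflections(as_kymo(matrix(1, 60, 3)))), 0)
  expect_error(find_inflections(kymo, smooth_sigma_bins = 0), "sigma")
})

test_that("boundary slope recovers the configured onset advance", {
  cfg <- niche_config(duration_min = 150, onset_advance_um_min = 0.3,
                      rng_seed = 5)
  truth <- simulate_transcription(simulate_camp_field(cfg), preset_carA())
  kymo <- build_kymograph(truth$txn_rate, bin_width_px = 10,
                          pixel_size_um = cfg$pixel_size_um,
                          frame_interval_s = cfg$frame_interval_s)
  pts <- find_inflections(kymo)
  fit <- fit_boundary(pts)
  expect_equal(fit$slope_um_min, -0.3, tolerance = 0.1 * 0.3)
})

test_that("boundary comparison measures spatial offsets with a bootstrap CI", {
  pts <- data.frame(frame = 1:40, t_min = (0:39) * 0.75,
                    x_um = 70 - 0.3 * (0:39) * 0.75 + rnorm(40, 0, 1))
  same <- compare_boundaries(pts, pts)
  expect_equal(same$offset_um, 0)
  shifted <- pts; shifted$x_um <- shifted$x_um + 20
  off <- compare_boundaries(shifted, pts)
  expect_equal(off$offset_um, 20)
  expect_true(off$ci[1] <= 20 && off$ci[2] >= 20)
})

test_that("transcription and signalling boundaries overlap for one-step but not for shifted zones", {
  cfg <- niche_config(duration_min = 150, rng_seed = 9)
  truth <- simulate_transcription(simulate_camp_field(cfg), preset_carA())
  mk <- function(m) build_kymograph(m, 10, pixel_size_um = cfg$pixel_size_um,
                                    frame_interval_s = cfg$frame_interval_s)
  pts_txn <- find_inflections(mk(truth$txn_rate))
  pts_sig <- find_inflections(mk(truth$camp))
  ov <- compare_boundaries(pts_txn, pts_sig)
  # substantial overlap: offset within one kymograph bin (3.5 um)
  expect_lt(abs(ov$offset_um), 3.5)
  # a transcription zone wider than the oscillation zone: offset CI
  # excludes zero (boundaries do not overlap)
  cfg2 <- niche_config(duration_min = 150, rng_seed = 9,
                       onset_boundary_start_px = 260)
  truth2 <- simulate_transcription(simulate_camp_field(cfg2), preset_carA())
  pts_sig2 <- find_inflections(mk(truth2$camp))
  apart <- compare_boundaries(pts_txn, pts_sig2)
  expect_true(apart$ci[2] < 0)
  expect_gt(abs(apart$offset_um), 10)
})

test_that("period estimation matches closed forms and flags aperiodic traces", {
  t <- seq(0, 3600, by = 45)
  per <- estimate_period(sin(2 * pi * t / 360), 45)
  expect_true(per$detected)
  expect_equal(per$period_s, 360, tolerance = 22.5 / 360)
  set.seed(1)
  noise <- estimate_period(rnorm(200), 45)
  expect_false(noise$detected)
  expect_true(is.na(noise$period_s))
  # early window of the wildtype fixture: period near the configured mean
  truth <- small_niche_truth()
  z <- zone_mean_traces(truth)
  early <- z$time_min <= 45
  cfg <- truth$config
  T_mean <- mean(c(cfg$wave_period_start_min,
                   cfg$wave_period_start_min -
                     (cfg$wave_period_start_min - cfg$wave_period_end_min) *
                     45 / cfg$duration_min))
  per_wt <- estimate_period(z$signal[early], 45)
  expect_true(per_wt$detected)
  expect_equal(per_wt$period_s / 60, T_mean, tolerance = 0.1)
})

test_that("lag estimation agrees with the exhaustive-shift oracle", {
  set.seed(3)
  base <- sin(2 * pi * seq(0, 10000, by = 45) / 380) + rnorm(223, 0, 0.1)
  shifted <- c(rep(0, 6), base)[1:223]
  est <- estimate_lag(base, shifted, max_lag_s = 450)
  expect_equal(est$lag_frames, 6L)
  expect_equal(est$lag_s, 270, tolerance = 23 / 270)
  # independent oracle: stats::ccf argmax at integer frame resolution
  occ <- ccf(nichejump:::detrend_z(shifted), nichejump:::detrend_z(base),
             lag.max = 10, plot = FALSE)
  expect_equal(occ$lag[which.max(occ$acf)], est$lag_frames)
  # identical traces: zero lag
  expect_equal(estimate_lag(base, base)$lag_s, 0)
  expect_error(estimate_lag(base[1:10], shifted[1:10], max_lag_s = 450),
               "shorter")
  expect_error(estimate_lag(base, shifted[-1]), "equal length")
})

test_that("lag estimation is antisymmetric and amplitude-invariant", {
  truth <- small_niche_truth()
  z <- zone_mean_traces(truth)
  ab <- estimate_lag(z$signal, z$txn)
  ba <- estimate_lag(z$txn, z$signal)
  expect_equal(ab$lag_s, -ba$lag_s, tolerance = 45 / abs(ab$lag_s))
  for (k in c(0.01, 3, 250)) {
    expect_equal(estimate_lag(z$signal * k, z$txn)$lag_s, ab$lag_s)
    expect_equal(estimate_lag(z$signal, z$txn * k)$lag_s, ab$lag_s)
  }
})

test_that("noiseless one-step lags are recovered across the physiological range", {
  cfg <- small_niche_cfg()
  field <- simulate_camp_field(cfg)
  for (tau in c(45, 90, 180, 270, 360)) {
    p <- gene_preset("g", "one_step", lag_s = tau, burst_rate_per_h = 0)
    tr <- simulate_transcription(field, p, noise_sd = 0)
    z <- zone_mean_traces(tr)
    est <- estimate_lag(z$signal, z$txn, max_lag_s = 450)
    expect_lte(abs(est$lag_s - tau), 45 / 2)
  }
})

test_that("induction detection finds sustained threshold crossings", {
  expect_false(detect_induction(rep(1, 100))$induced)
  set.seed(2)
  tr <- rnorm(100, 1, 0.05)
  tr[40:100] <- tr[40:100] + 10 * 0.05
  res <- detect_induction(tr, baseline_window = 1:30, k_sigma = 3,
                          m_frames = 5)
  expect_true(res$induced)
  expect_equal(res$onset_frame, 40L)
  # onset of carA induction under 6-min pulsing sits near the priming delay
  cfg <- niche_config(mode = "bpac", pulse_interval_min = 6,
                      duration_min = 120, rng_seed = 4)
  tr2 <- simulate_transcription(simulate_camp_field(cfg), preset_carA())
  z <- zone_mean_traces(tr2)
  ind <- detect_induction(z$txn, frame_interval_s = 45)
  expect_true(ind$induced)
  expect_true(ind$onset_min >= 25 && ind$onset_min <= 40)
})

test_that("frequency-response classification separates the coupling models", {
  run <- function(preset, interval) {
    cfg <- niche_config(mode = "bpac", pulse_interval_min = interval,
                        duration_min = 150, rng_seed = 6)
    tr <- simulate_transcription(simulate_camp_field(cfg), preset)
    detect_induction(zone_mean_traces(tr)$txn)
  }
  expect_equal(classify_frequency_response(run(preset_carA(), 6),
                                           run(preset_carA(), 10)),
               "one_step")
  expect_equal(classify_frequency_response(run(preset_cafA(), 6),
                                           run(preset_cafA(), 10)),
               "two_step")
  # acaA-null cells without pulses respond to neither regime
  cfg0 <- niche_config(mode = "acaA_null", duration_min = 150, rng_seed = 6)
  tr0 <- simulate_transcription(simulate_camp_field(cfg0), preset_carA())
  ind0 <- detect_induction(zone_mean_traces(tr0)$txn)
  expect_equal(classify_frequency_response(ind0, ind0), "unresponsive")
  expect_warning(out <- classify_frequency_response(TRUE, FALSE), "short")
  expect_equal(out, "anomalous")
})

test_that("signalling inflections are evaluated at wave maxima only", {
  cfg <- niche_config(duration_min = 120, rng_seed = 12)
  truth <- simulate_camp_field(cfg)
  kymo <- build_kymograph(truth$camp, 10,
                          pixel_size_um = cfg$pixel_size_um,
                          frame_interval_s = cfg$frame_interval_s)
  pts <- find_inflections(kymo, signal_diff = TRUE)
  expect_gt(nrow(pts), 3)
  mean_tr <- colMeans(kymo$intensity)
  peaks <- which(diff(sign(diff(mean_tr))) == -2) + 1L
  expect_true(all(pts$frame %in% peaks))
  n_bins <- nrow(kymo$intensity)
  expect_true(all(pts$x_um >= 0 & pts$x_um <= n_bins * kymo$bin_width_um))
})
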