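# reference raised-cosine pulse used by the gating oracle
raised_cosine_test <- function(u, duty) {
  out <- numeric(length(u))
  inside <- u >= 0 & u < duty
  out[inside] <- 0.5 * (1 - cos(2 * pi * u[inside] / duty))
  out
}

test_that("acaA-null mode produces a zero cAMP field that propagates to basal transcription", {
  cfg <- niche_config(mode = "acaA_null", field_length_px = 100,
                      duration_min = 30, rng_seed = 1)
  truth <- simulate_camp_field(cfg)
  expect_true(all(truth$camp == 0))
  tr <- simulate_transcription(truth,
                               gene_preset("g", "one_step", lag_s = 270,
                                           burst_rate_per_h = 0,
                                           basal_rate = 0.05),
                               noise_sd = 0)
  expect_true(all(tr$txn_rate == 0.05))
})

test_that("wildtype field oscillates at the configured period", {
  # fixed 6-min period, 60-min window: exactly 10 pulse maxima at one position
  cfg <- niche_config(duration_min = 70, wave_period_start_min = 6,
                      wave_period_end_min = 6, onset_advance_um_min = 0,
                      rng_seed = 1)
  truth <- simulate_camp_field(cfg)
  x <- truth$camp[500, truth$time_min < 60]
  peaks <- sum(diff(sign(diff(x))) == -2 & x[2:(length(x) - 1)] > 0.5)
  expect_equal(peaks, 10)
  # left of the onset boundary the field is silent
  expect_true(all(truth$camp[1:100, ] == 0))
})

test_that("bpac mode is a spatially uniform pulse train at the configured interval", {
  cfg <- niche_config(mode = "bpac", pulse_interval_min = 6,
                      duration_min = 60, rng_seed = 1)
  truth <- simulate_camp_field(cfg)
  expect_true(all(apply(truth$camp, 2, function(col) diff(range(col)) == 0)))
  tr <- truth$camp[1, ]
  pk <- which(diff(sign(diff(tr))) == -2) + 1
  spacing <- diff(truth$time_min[pk])
  expect_true(all(abs(spacing - 6) < 1e-9))
})

test_that("one-step transcription lags the field by the preset delay", {
  truth <- simulate_camp_field(small_niche_cfg())
  tr <- simulate_transcription(truth,
                               gene_preset("g", "one_step", lag_s = 270,
                                           burst_rate_per_h = 0),
                               noise_sd = 0)
  z <- zone_mean_traces(tr)
  # exhaustive integer-shift oracle: argmax must be 6 frames (270 s / 45 s)
  n <- length(z$signal)
  cc <- vapply(0:12, function(k) {
    cor(z$signal[1:(n - k)], z$txn[(1 + k):n])
  }, numeric(1))
  expect_equal(which.max(cc) - 1L, 6L)
})

test_that("two-step gating silences high-frequency pulsing and passes low-frequency pulsing", {
  means <- vapply(c(4, 6, 8, 10, 12), function(d) {
    cfg <- niche_config(mode = "bpac", pulse_interval_min = d,
                        duration_min = 180, rng_seed = 2)
    tr <- simulate_transcription(simulate_camp_field(cfg), preset_cafA(),
                                 noise_sd = 0)
    z <- zone_mean_traces(tr)
    mean(z$txn[z$time_min > 40])
  }, numeric(1))
  basal_like <- preset_cafA()$basal_rate * 3
  # below the critical interval: silenced, non-increasing with frequency
  expect_lt(means[1], basal_like)
  expect_lt(means[2], basal_like)
  expect_lte(means[1], means[2] + 1e-6)
  # above: induced
  expect_gt(means[4], 5 * means[2])
  expect_gt(means[5], 5 * means[2])

  # independent oracle: continuous-time integration of the gating model at
  # fine resolution reproduces the induced/silenced contrast
  oracle_mean <- function(interval) {
    p <- preset_cafA()
    dt <- 0.01
    t <- seq(0, 180, by = dt)
    camp <- raised_cosine_test((t %% interval) / interval, 3 / interval)
    act <- c(rep(0, round(p$lag_s / 60 / dt)), camp)[seq_along(t)]
    drv <- c(rep(0, round(p$repressor_lag_min / dt)), camp)[seq_along(t)]
    rho <- 0; gate <- numeric(length(t))
    decay <- exp(-dt / p$repressor_decay_min)
    for (i in seq_along(t)) {
      rho <- rho * decay + drv[i] * dt
      gate[i] <- rho < p$repressor_threshold
    }
    mean((p$basal_rate + p$gain * act * gate)[t > 40])
  }
  expect_gt(oracle_mean(10), 5 * oracle_mean(6))
})

test_that("simulations are bit-identical under identical config and seed", {
  a <- simulate_transcription(simulate_camp_field(small_niche_cfg()),
                              preset_carA())
  b <- simulate_transcription(simulate_camp_field(small_niche_cfg()),
                              preset_carA())
  expect_identical(a$camp, b$camp)
  expect_identical(a$txn_rate, b$txn_rate)
  expect_identical(a$cell_positions, b$cell_positions)
  c2 <- simulate_camp_field(small_niche_cfg(rng_seed = 8L))
  expect_false(identical(a$cell_positions, c2$cell_positions))
})

test_that("reporter to biosensor cell ratio is 1:2 within rounding", {
  for (n in c(30, 31, 90, 91)) {
    truth <- simulate_camp_field(
      niche_config(field_length_px = 240, duration_min = 10, n_cells = n,
                   rng_seed = 7L))
    n_rep <- sum(truth$cell_positions$channel == "reporter")
    expect_lte(abs(n_rep - n / 3), 1)
  }
})

test_that("invalid niche configurations are rejected", {
  expect_error(niche_config(duration_min = -1), "duration")
  expect_error(niche_config(pixel_size_um = 0), "pixel_size")
  expect_error(niche_config(wave_period_start_min = 5,
                            wave_period_end_min = 8), "period")
  expect_error(simulate_camp_field(list()), "niche_config")
  truth <- simulate_camp_field(small_niche_cfg())
  expect_error(simulate_transcription(truth, list()), "gene_preset")
})

test_that("bpac priming and responsive zone restrict the response", {
  cfg <- niche_config(mode = "bpac", pulse_interval_min = 6,
                      duration_min = 90, rng_seed = 3)
  p <- preset_carA()
  tr <- simulate_transcription(simulate_camp_field(cfg), p, noise_sd = 0)
  pre <- tr$txn_rate[, tr$time_min < p$priming_delay_min]
  expect_true(max(pre) <= p$basal_rate + 2 * p$burst_amplitude + 1e-9)
  # outside the responsive zone (left of the colony) only basal + bursts
  outside <- tr$x_um < (1 - p$responsive_zone_fraction) * max(tr$x_um)
  late <- tr$txn_rate[outside, tr$time_min > 40]
  expect_true(all(late <= p$basal_rate + 2 * p$burst_amplitude + 1e-9))
})

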