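#' Configuration for a synthetic developmental-niche simulation
#'
#' Describes the 1-D differentiation axis of a *Dictyostelium* colony and the
#' collective cAMP signalling regime imposed on it.  Space is the axis running
#' from undifferentiated, feeding cells (left, x = 0) toward the forming
#' aggregate (right).  Three modes are supported: `wildtype` (self-organised
#' cAMP waves, oscillatory right of a moving onset boundary, with the period
#' shortening over time), `acaA_null` (adenylyl-cyclase-A mutant: no collective
#' cAMP at all) and `bpac` (optogenetic adenylyl cyclase driven by periodic
#' light pulses: a spatially uniform cAMP pulse train of chosen interval).
#'
#' @param field_length_px length of the axis in pixels.
#' @param pixel_size_um physical pixel size (um); 0.35 matches the confocal
#'   setup the kymograph binning convention is built on.
#' @param frame_interval_s imaging interval in seconds (stacks every 45 s).
#' @param duration_min total simulated time in minutes.
#' @param mode one of `"wildtype"`, `"acaA_null"`, `"bpac"`.
#' @param wave_period_start_min,wave_period_end_min oscillation period at the
#'   start/end of the movie (minutes); the instantaneous period interpolates
#'   linearly in time.  Collective oscillations accelerate as aggregation
#'   approaches, so the end period must not exceed the start period.
#' @param wave_speed_um_min propagation speed of the cAMP relay wave (um/min).
#' @param onset_boundary_start_px initial position (px) of the oscillation
#'   onset boundary; only cells right of the boundary oscillate.
#' @param onset_advance_um_min speed (um/min) at which the onset boundary
#'   advances toward the undifferentiated side (leftward).
#' @param pulse_interval_min interval of the optogenetic pulse train
#'   (`bpac` mode); the two experimentally used values are 6 and 10 min.
#' @param pulse_width_min width of each optogenetic cAMP pulse (minutes).
#' @param duty_cycle fraction of the oscillation cycle occupied by a cAMP
#'   pulse in `wildtype` mode.
#' @param amplitude peak cAMP concentration (arbitrary units).  Ignored in
#'   `acaA_null` mode, where the field is identically zero.
#' @param n_cells number of cells scattered along the axis (transcription
#'   reporter and Flamindo2 biosensor cells, mixed at a 1:2 ratio).
#' @param rng_seed integer seed; all randomness in the simulation derives
#'   from it.
#' @return an object of class `niche_config`.
#' @export
niche_config <- function(field_length_px = 600,
                         pixel_size_um = 0.35,
                         frame_interval_s = 45,
                         duration_min = 180,
                         mode = c("wildtype", "acaA_null", "bpac"),
                         wave_period_start_min = 8,
                         wave_period_end_min = 5,
                         wave_speed_um_min = 300,
                         onset_boundary_start_px = round(field_length_px / 3),
                         onset_advance_um_min = 0.3,
                         pulse_interval_min = 6,
                         pulse_width_min = 3,
                         duty_cycle = 0.5,
                         amplitude = 1,
                         n_cells = 90,
                         rng_seed = 1L) {
  mode <- match.arg(mode)
  if (pixel_size_um <= 0) stop_config("pixel_size_um must be > 0")
  if (frame_interval_s <= 0) stop_config("frame_interval_s must be > 0")
  if (duration_min <= 0) stop_config("duration_min must be > 0")
  if (field_length_px < 2) stop_config("field_length_px must be >= 2")
  if (wave_period_end_min > wave_period_start_min)
    stop_config("wave_period_end_min must not exceed wave_period_start_min")
  if (wave_period_end_min <= 0) stop_config("wave periods must be > 0")
  if (mode == "bpac") {
    if (pulse_interval_min <= 0) stop_config("pulse_interval_min must be > 0")
    if (pulse_width_min <= 0 || pulse_width_min > pulse_interval_min)
      stop_config("pulse_width_min must be in (0, pulse_interval_min]")
  }
  if (duty_cycle <= 0 || duty_cycle > 1) stop_config("duty_cycle must be in (0, 1]")
  structure(list(
    field_length_px = as.integer(field_length_px),
    pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s,
    duration_min = duration_min,
    mode = mode,
    wave_period_start_min = wave_period_start_min,
    wave_period_end_min = wave_period_end_min,
    wave_speed_um_min = wave_speed_um_min,
    onset_boundary_start_px = onset_boundary_start_px,
    onset_advance_um_min = onset_advance_um_min,
    pulse_interval_min = pulse_interval_min,
    pulse_width_min = pulse_width_min,
    duty_cycle = duty_cycle,
    amplitude = amplitude,
    n_cells = as.integer(n_cells),
    rng_seed = as.integer(rng_seed)
  ), class = "niche_config")
}

#' Gene coupling preset
#'
#' Parameterises how a gene's transcription rate couples to the cAMP field.
#' Two models are supported. `one_step`: transcription mirrors the cAMP level
#' with a fixed lag (carA-like; not silenced at high pulse frequencies).
#' `two_step`: an activator tracks cAMP with a short lag while a repressor
#' integrates cAMP with a longer lag and a finite memory; transcription
#' requires the activator to be on while the integrated repressor is still
#' below threshold.  The net effect is a frequency gate: pulse trains with
#' intervals shorter than `critical_interval_min` keep the repressor loaded
#' and silence the gene, while longer intervals let the repressor decay and
#' permit induction (cafA-like).
#'
#' @param name label for the preset.
#' @param model `"one_step"` or `"two_step"`.
#' @param lag_s response delay between a cAMP rise and the transcription
#'   rise, seconds.
#' @param gain transcription rate per unit cAMP.
#' @param basal_rate cAMP-independent transcription rate.
#' @param burst_rate_per_h frequency of sporadic, signalling-independent
#'   transcription bursts (per cell-position per hour).
#' @param burst_amplitude,burst_frames amplitude (rate units) and duration
#'   (frames) of a sporadic burst.
#' @param critical_interval_min pulse interval at which the two-step gate
#'   switches between silenced and induced.
#' @param repressor_decay_min decay time of the integrated repressor, minutes.
#' @param repressor_lag_min delay of the repressive arm relative to the cAMP
#'   pulse (repression acts at a later stage of the oscillation cycle).
#' @param repressor_threshold gate threshold on the integrated repressor.  If
#'   `NULL` it is calibrated so that, under a unit-amplitude reference pulse
#'   train of 2-min pulses, the gate sits exactly at `critical_interval_min`.
#' @param priming_delay_min minutes of pulsing required before cells become
#'   responsive under optogenetic stimulation.
#' @param responsive_zone_fraction fraction of the axis, measured from the
#'   differentiated (right) side, whose cells can respond to optogenetic
#'   pulses; cells outside respond at basal rate only.
#' @return an object of class `gene_preset`.
#' @export
gene_preset <- function(name,
                        model = c("one_step", "two_step"),
                        lag_s = 270,
                        gain = 1,
                        basal_rate = 0.02,
                        burst_rate_per_h = 0.5,
                        burst_amplitude = 1,
                        burst_frames = 2L,
                        critical_interval_min = 8,
                        repressor_decay_min = 4,
                        repressor_lag_min = 3,
                        repressor_threshold = NULL,
                        priming_delay_min = 30,
                        responsive_zone_fraction = 0.6) {
  model <- match.arg(model)
  if (lag_s < 0) stop_config("lag_s must be >= 0")
  if (gain < 0 || basal_rate < 0) stop_config("gain and basal_rate must be >= 0")
  if (model == "two_step") {
    if (repressor_decay_min <= 0) stop_config("repressor_decay_min must be > 0")
    if (is.null(repressor_threshold)) {
      # steady-state repressor level at the midpoint of the activator window
      # under the reference stimulus (amplitude 1, 3-min raised-cosine pulses
      # at the critical interval); the gate then flips exactly there.
      w <- 3; q <- w / 2
      tau <- repressor_decay_min
      rho_end <- q / (1 - exp(-critical_interval_min / tau))
      elapsed <- (lag_s / 60 + w / 2) + critical_interval_min -
        (repressor_lag_min + w)
      if (elapsed < 0) elapsed <- 0
      repressor_threshold <- rho_end * exp(-elapsed / tau)
    }
    if (repressor_threshold <= 0) stop_config("repressor_threshold must be > 0")
  }
  structure(list(
    name = name, model = model, lag_s = lag_s, gain = gain,
    basal_rate = basal_rate, burst_rate_per_h = burst_rate_per_h,
    burst_amplitude = burst_amplitude, burst_frames = as.integer(burst_frames),
    critical_interval_min = critical_interval_min,
    repressor_decay_min = repressor_decay_min,
    repressor_lag_min = repressor_lag_min,
    repressor_threshold = repressor_threshold,
    priming_delay_min = priming_delay_min,
    responsive_zone_fraction = responsive_zone_fraction
  ), class = "gene_preset")
}

#' Built-in gene presets
#'
#' `preset_carA()` is the one-step reference gene: transcription mirrors cAMP
#' with a 270 s (4.5 min) lag and is induced by 6-min optogenetic pulsing
#' after a ~30 min priming delay.  `preset_cafA()` is the two-step reference
#' gene: a short (60 s) activation lag combined with delayed repression, so
#' 6-min pulse trains silence it while 10-min trains induce it.
#'
#' @return a `gene_preset`.
#' @export
preset_carA <- function() {
  gene_preset("carA", model = "one_step", lag_s = 270, gain = 1,
              basal_rate = 0.02, burst_rate_per_h = 0.5,
              priming_delay_min = 30, responsive_zone_fraction = 0.6)
}

#' @rdname preset_carA
#' @export
preset_cafA <- function() {
  gene_preset("cafA", model = "two_step", lag_s = 60, gain = 2,
              basal_rate = 0.01, burst_rate_per_h = 0.5,
              critical_interval_min = 8, repressor_decay_min = 4,
              repressor_lag_min = 3, priming_delay_min = 30,
              responsive_zone_fraction = 0.7)
}

# position of the oscillation onset boundary (um) at time t (min)
onset_boundary_um <- function(cfg, t_min) {
  cfg$onset_boundary_start_px * cfg$pixel_size_um -
    cfg$onset_advance_um_min * t_min
}

# cumulative phase (in cycles) at retarded time u (min) for a period that
# interpolates linearly from T0 to T1 over the movie
phase_cycles <- function(u, T0, T1, duration) {
  if (T1 == T0) return(u / T0)
  rate <- (T1 - T0) / duration
  # integral of 1/(T0 + rate * s) ds from 0 to u, clamping T at [T1, T0]
  u_end <- pmin(u, duration)
  ph <- log((T0 + rate * u_end) / T0) / rate
  extra <- pmax(u - duration, 0) / T1
  ph + extra
}

#' Simulate the collective cAMP concentration field
#'
#' Generates the ground-truth cAMP field c(x, t) over the differentiation
#' axis.  In `wildtype` mode the field is a travelling raised-cosine pulse
#' train right of a leftward-moving onset boundary, with the instantaneous
#' period shortening linearly from `wave_period_start_min` to
#' `wave_period_end_min`; left of the boundary the field is zero.  In `bpac`
#' mode the field is a spatially uniform pulse train at `pulse_interval_min`.
#' In `acaA_null` mode the field is identically zero.  Cell positions
#' (transcription reporter : Flamindo2 biosensor at 1:2) are drawn uniformly
#' along the axis under the config seed.
#'
#' @param cfg a [niche_config()].
#' @return an object of class `signal_truth`: list with `camp` (matrix,
#'   space positions x frames), `x_um`, `time_min`, `cell_positions`
#'   (data.frame `x_um`, `channel`), and the `config`.
#' @export
simulate_camp_field <- function(cfg) {
  if (!inherits(cfg, "niche_config")) stop_config("cfg must be a niche_config")
  n_frames <- floor(cfg$duration_min * 60 / cfg$frame_interval_s) + 1L
  t_min <- (seq_len(n_frames) - 1L) * cfg$frame_interval_s / 60
  x_um <- (seq_len(cfg$field_length_px) - 1L) * cfg$pixel_size_um

  camp <- matrix(0, nrow = cfg$field_length_px, ncol = n_frames)
  if (cfg$mode == "wildtype") {
    xb <- onset_boundary_um(cfg, t_min)                  # per frame
    for (j in seq_len(n_frames)) {
      right <- x_um >= xb[j]
      if (!any(right)) next
      u <- t_min[j] - (x_um[right] - xb[j]) / cfg$wave_speed_um_min
      ok <- u >= 0
      if (!any(ok)) next
      ph <- phase_cycles(u[ok], cfg$wave_period_start_min,
                         cfg$wave_period_end_min, cfg$duration_min)
      vals <- cfg$amplitude * raised_cosine(ph - floor(ph), cfg$duty_cycle)
      camp[which(right)[ok], j] <- vals
    }
  } else if (cfg$mode == "bpac") {
    s <- t_min %% cfg$pulse_interval_min
    trace <- cfg$amplitude *
      raised_cosine(s / cfg$pulse_interval_min,
                    cfg$pulse_width_min / cfg$pulse_interval_min)
    camp <- matrix(trace, nrow = cfg$field_length_px, ncol = n_frames,
                   byrow = TRUE)
  }                                                       # acaA_null: zeros

  cells <- withr::with_seed(cfg$rng_seed, {
    n_rep <- round(cfg$n_cells / 3)
    ch <- c(rep("reporter", n_rep), rep("flamindo", cfg$n_cells - n_rep))
    data.frame(
      x_um = runif(cfg$n_cells, 0, max(x_um)),
      channel = sample(ch),
      stringsAsFactors = FALSE
    )
  })

  structure(list(camp = camp, txn_rate = NULL, x_um = x_um, time_min = t_min,
                 cell_positions = cells, config = cfg, preset = NULL),
            class = "signal_truth")
}

# sample a space x frames matrix at a shifted time (linear interpolation,
# zero before t = 0)
shift_in_time <- function(mat, time_min, shift_min) {
  if (shift_min == 0) return(mat)
  tq <- time_min - shift_min
  out <- matrix(0, nrow = nrow(mat), ncol = ncol(mat))
  inside <- tq >= time_min[1]
  if (!any(inside)) return(out)
  for (i in seq_len(nrow(mat))) {
    out[i, inside] <- approx(time_min, mat[i, ], xout = tq[inside],
                             rule = 2)$y
  }
  out
}

#' Simulate transcription rates coupled to the cAMP field
#'
#' Adds the per-position transcription-rate layer r(x, t) to a
#' [simulate_camp_field()] truth object, under the given [gene_preset()].
#' One-step genes follow `basal + gain * c(x, t - lag)`.  Two-step genes
#' multiply the lagged activator by a repressor gate: the repressor
#' integrates the cAMP input (delayed by `repressor_lag_min`, decaying with
#' `repressor_decay_min`) and transcription only proceeds while it is below
#' `repressor_threshold`.  Sporadic signalling-independent bursts occur
#' everywhere at `burst_rate_per_h`.  In `bpac` mode, cells respond at basal
#' rate before `priming_delay_min` and outside the responsive zone (a
#' fraction of the axis measured from the differentiated side).
#'
#' @param truth a `signal_truth` from [simulate_camp_field()].
#' @param preset a [gene_preset()].
#' @param rng_seed seed for bursts and measurement noise; defaults to the
#'   config seed + 1.
#' @param noise_sd additive Gaussian noise on the rate (clamped at 0).
#' @return the `signal_truth` with `txn_rate` filled in.
#' @export
simulate_transcription <- function(truth, preset, rng_seed = NULL,
                                   noise_sd = 0.02) {
  if (!inherits(truth, "signal_truth")) stop_config("truth must be a signal_truth")
  if (!inherits(preset, "gene_preset")) stop_config("preset must be a gene_preset")
  if (is.null(truth$camp)) stop_config("truth has no cAMP layer")
  cfg <- truth$config
  if (is.null(rng_seed)) rng_seed <- cfg$rng_seed + 1L
  dt_min <- cfg$frame_interval_s / 60
  camp <- truth$camp
  n_frames <- ncol(camp)

  drive <- camp
  if (cfg$mode == "bpac") {
    # spatial restriction of the optogenetic response
    zone_start <- (1 - preset$responsive_zone_fraction) *
      max(truth$x_um)
    drive[truth$x_um < zone_start, ] <- 0
  }

  act <- shift_in_time(drive, truth$time_min, preset$lag_s / 60)
  if (preset$model == "one_step") {
    r <- preset$basal_rate + preset$gain * act
  } else {
    rep_drive <- shift_in_time(drive, truth$time_min, preset$repressor_lag_min)
    decay <- exp(-dt_min / preset$repressor_decay_min)
    rho <- matrix(0, nrow = nrow(camp), ncol = n_frames)
    for (j in 2:n_frames) {
      rho[, j] <- rho[, j - 1] * decay + rep_drive[, j] * dt_min
    }
    gate <- rho < preset$repressor_threshold
    r <- preset$basal_rate + preset$gain * act * gate
  }
  if (cfg$mode == "bpac") {
    # priming acts downstream: cells respond at basal rate until they have
    # experienced priming_delay_min of pulsing
    r[, truth$time_min < preset$priming_delay_min] <- preset$basal_rate
  }

  r <- withr::with_seed(as.integer(rng_seed), {
    if (preset$burst_rate_per_h > 0) {
      expected <- preset$burst_rate_per_h * cfg$duration_min / 60
      for (i in seq_len(nrow(r))) {
        nb <- rpois(1, expected)
        if (nb > 0) {
          starts <- sample.int(n_frames, nb, replace = TRUE)
          for (s in starts) {
            idx <- s:min(n_frames, s + preset$burst_frames - 1L)
            r[i, idx] <- r[i, idx] + preset$burst_amplitude
          }
        }
      }
    }
    if (noise_sd > 0) r <- r + rnorm(length(r), 0, noise_sd)
    r
  })
  r[r < 0] <- 0
  truth$txn_rate <- r
  truth$preset <- preset
  truth
}

#' Mean signalling and transcription traces over the analysed zone
#'
#' Averages the cAMP field and transcription-rate layer over the zone the
#' coupling analyses use: the oscillatory zone (right of the initial onset
#' boundary) in `wildtype` mode, the responsive zone in `bpac` mode, and the
#' whole field in `acaA_null` mode.
#'
#' @param truth a `signal_truth` with the transcription layer filled in.
#' @return list with `signal`, `txn` (numeric traces), `time_min` and
#'   `frame_interval_s`.
#' @export
zone_mean_traces <- function(truth) {
  if (is.null(truth$txn_rate)) stop_config("truth has no transcription layer")
  cfg <- truth$config
  zone <- switch(cfg$mode,
    wildtype = truth$x_um >= onset_boundary_um(cfg, 0),
    bpac = truth$x_um >=
      (1 - truth$preset$responsive_zone_fraction) * max(truth$x_um),
    acaA_null = rep(TRUE, length(truth$x_um))
  )
  if (!any(zone)) stop_config("analysis zone is empty")
  list(signal = colMeans(truth$camp[zone, , drop = FALSE]),
       txn = colMeans(truth$txn_rate[zone, , drop = FALSE]),
       time_min = truth$time_min,
       frame_interval_s = cfg$frame_interval_s)
}
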