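#' Configuration for a synthetic colony time-lapse
#'
#' Low-magnification view of a developmental colony: a bright bacterial lawn
#' cleared from right to left by the advancing feeding front at constant
#' speed, with bright mound-formation events appearing at discrete times in
#' the recently starved (cleared) zone.  Per 150-px section of the front,
#' inter-mound intervals follow a Gamma distribution (shape 4) with the
#' stated median, truncated at the stated maximum.
#'
#' @param field_length_px,field_height_px image size.
#' @param pixel_size_um low-magnification pixel size; 4.2 um/px makes a
#'   150-px section 0.63 mm wide.
#' @param frame_interval_min frames every 5 min.
#' @param duration_h movie length (up to 25 h).
#' @param front_speed_um_min feeding-front speed (1.9 um/min by default).
#' @param front_start_px initial front position (px).
#' @param mound_median_interval_h,mound_max_interval_h median and maximum of
#'   the per-section inter-mound interval distribution (the printed "once
#'   every 4 h" is the median of the pooled box statistics).
#' @param mound_shape Gamma shape of the interval distribution.
#' @param section_width_px width of the sections the renewal process runs in.
#' @param min_event_separation_px minimum spatial separation between mound
#'   centres (aggregation drains cells locally, so adjacent centres exclude
#'   each other).
#' @param lawn_level,cleared_level,mound_peak rendered intensity levels.
#' @param mound_sigma_px mound blob size.
#' @param edge_width_px width of the lawn/cleared transition.
#' @param noise_sd pixel noise.
#' @param rng_seed integer seed.
#' @return an object of class `colony_config`.
#' @export
colony_config <- function(field_length_px = 900, field_height_px = 60,
                          pixel_size_um = 4.2, frame_interval_min = 5,
                          duration_h = 24, front_speed_um_min = 1.9,
                          front_start_px = 2 * section_width_px,
                          mound_median_interval_h = 4,
                          mound_max_interval_h = 10,
                          mound_shape = 4,
                          section_width_px = 150,
                          min_event_separation_px = 12,
                          lawn_level = 1, cleared_level = 0.15,
                          mound_peak = 1.6, mound_sigma_px = 5,
                          edge_width_px = 4, noise_sd = 0.05,
                          rng_seed = 1L) {
  if (pixel_size_um <= 0 || frame_interval_min <= 0 || duration_h <= 0)
    stop_config("resolution and duration must be positive")
  if (mound_median_interval_h <= 0 ||
      mound_median_interval_h > mound_max_interval_h)
    stop_config("need 0 < median interval <= max interval")
  if (front_speed_um_min < 0) stop_config("front_speed_um_min must be >= 0")
  structure(as.list(environment()), class = "colony_config")
}

# truncated Gamma intervals (hours): inverse-CDF sampling on (0, F(max)],
# with the scale chosen so the untruncated median equals median_h
sample_intervals <- function(n, shape, median_h, max_h) {
  rate <- qgamma(0.5, shape, 1) / median_h
  u <- runif(n, 0, pgamma(max_h, shape, rate))
  qgamma(u, shape, rate)
}

#' Simulate a colony time-lapse with feeding front and mound events
#'
#' Generates ground truth (front position per frame; mound events as
#' (x, t) pairs) and, optionally, the rendered image stack.  The front
#' moves leftward at constant speed; each section of the axis starts its
#' mound renewal process once the front has cleared it, with
#' Gamma-distributed intervals between events.  Mounds appear at full
#' brightness on the first frame at or after their event time and persist.
#'
#' @param cfg a [colony_config()].
#' @param render render the image stack (set `FALSE` for truth-only runs).
#' @return list with `truth` (`front`: data.frame `frame`, `t_min`, `x_px`,
#'   `x_um`; `events`: data.frame `x_px`, `x_um`, `y_px`, `t_min`, `frame`,
#'   `section`) and `stack` (height x width x frames array or `NULL`).
#' @export
simulate_colony <- function(cfg, render = TRUE) {
  if (!inherits(cfg, "colony_config")) stop_config("cfg must be a colony_config")
  n_frames <- floor(cfg$duration_h * 60 / cfg$frame_interval_min) + 1L
  t_min <- (seq_len(n_frames) - 1L) * cfg$frame_interval_min
  front_um <- cfg$front_start_px * cfg$pixel_size_um -
    cfg$front_speed_um_min * t_min
  front <- data.frame(frame = seq_len(n_frames), t_min = t_min,
                      x_px = front_um / cfg$pixel_size_um, x_um = front_um)

  events <- withr::with_seed(cfg$rng_seed, {
    n_sec <- floor(cfg$field_length_px / cfg$section_width_px)
    placed_x <- numeric(0)
    evs <- list()
    for (s in seq_len(n_sec)) {
      left <- (s - 1) * cfg$section_width_px
      right <- s * cfg$section_width_px
      t_clear_min <- if (cfg$front_speed_um_min > 0) {
        max(0, (cfg$front_start_px - left) * cfg$pixel_size_um /
              cfg$front_speed_um_min)
      } else if (cfg$front_start_px <= left) 0 else Inf
      if (t_clear_min > cfg$duration_h * 60) next
      t_h <- t_clear_min / 60
      repeat {
        t_h <- t_h + sample_intervals(1, cfg$mound_shape,
                                      cfg$mound_median_interval_h,
                                      cfg$mound_max_interval_h)
        if (t_h > cfg$duration_h) break
        x <- NA_real_
        for (try in 1:50) {
          cand <- runif(1, left + cfg$mound_sigma_px,
                        right - cfg$mound_sigma_px)
          if (!length(placed_x) ||
              min(abs(placed_x - cand)) >= cfg$min_event_separation_px) {
            x <- cand; break
          }
        }
        if (is.na(x)) next
        placed_x <- c(placed_x, x)
        y <- runif(1, 0.25 * cfg$field_height_px, 0.75 * cfg$field_height_px)
        evs[[length(evs) + 1L]] <- data.frame(
          x_px = x, x_um = x * cfg$pixel_size_um, y_px = y,
          t_min = t_h * 60,
          frame = min(n_frames, ceiling(t_h * 60 / cfg$frame_interval_min) + 1L),
          section = s)
      }
    }
    if (length(evs)) do.call(rbind, evs) else
      data.frame(x_px = numeric(), x_um = numeric(), y_px = numeric(),
                 t_min = numeric(), frame = integer(), section = integer())
  })

  stack <- NULL
  if (render) {
    stack <- withr::with_seed(cfg$rng_seed + 1L, {
      xs <- seq_len(cfg$field_length_px) - 1L
      arr <- array(0, dim = c(cfg$field_height_px, cfg$field_length_px,
                              n_frames))
      mound_total <- (cfg$mound_peak - cfg$cleared_level) *
        2 * pi * cfg$mound_sigma_px^2
      for (f in seq_len(n_frames)) {
        prof <- cfg$cleared_level + (cfg$lawn_level - cfg$cleared_level) /
          (1 + exp((xs - front$x_px[f]) / cfg$edge_width_px))
        img <- matrix(prof, cfg$field_height_px, cfg$field_length_px,
                      byrow = TRUE)
        on <- events$frame <= f
        if (any(on)) {
          for (e in which(on)) {
            img <- add_gaussian(img, events$x_px[e], events$y_px[e],
                                cfg$mound_sigma_px, mound_total)
          }
        }
        arr[, , f] <- img
      }
      if (cfg$noise_sd > 0)
        arr <- arr + array(rnorm(length(arr), 0, cfg$noise_sd), dim = dim(arr))
      arr
    })
  }
  list(truth = list(front = front, events = events), stack = stack,
       config = cfg)
}
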