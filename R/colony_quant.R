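#' Track the feeding front in a colony time-lapse
#'
#' Per sampled frame, the column-wise median intensity profile is smoothed
#' and the front is the position where it crosses the midpoint between the
#' bacterial-lawn and cleared-zone plateau levels (linear sub-pixel
#' interpolation).  Frames whose profile has lost contrast (front outside
#' the field) are dropped.  A least-squares line over the sampled positions
#' gives the speed, reported as a magnitude with the direction of motion.
#'
#' @param stack 3-D array (height x width x frames), single channel.
#' @param pixel_size_um,frame_interval_min calibration.
#' @param sample_every track every k-th frame (positions were tracked every
#'   five frames).
#' @param smooth_px Gaussian smoothing of the spatial profile.
#' @param min_contrast minimum plateau difference for a frame to be usable.
#' @return object of class `front_track`: data.frame `track` (`frame`,
#'   `t_min`, `x_px`, `x_um`), `speed_um_min`, `intercept_um`, `r_squared`,
#'   `direction`.
#' @export
track_front <- function(stack, pixel_size_um = 4.2, frame_interval_min = 5,
                        sample_every = 5, smooth_px = 3,
                        min_contrast = 0.3) {
  if (length(dim(stack)) != 3) stop("stack must be a 3-D array")
  n_frames <- dim(stack)[3]
  frames <- seq(1L, n_frames, by = sample_every)
  rows <- lapply(frames, function(f) {
    prof <- gauss_smooth1d(apply(stack[, , f], 2, median), smooth_px)
    hi <- quantile(prof, 0.98, names = FALSE)
    lo <- quantile(prof, 0.02, names = FALSE)
    if (hi - lo < min_contrast) return(NULL)
    mid <- (hi + lo) / 2
    below <- which(prof < mid)
    if (!length(below) || below[1] == 1) return(NULL)
    j <- below[1]
    # linear interpolation between the bracketing pixels (0-based centres)
    x <- (j - 2) + (prof[j - 1] - mid) / (prof[j - 1] - prof[j])
    data.frame(frame = f, t_min = (f - 1) * frame_interval_min,
               x_px = x, x_um = x * pixel_size_um)
  })
  track <- do.call(rbind, rows)
  if (is.null(track) || nrow(track) < 2) stop("front not trackable")
  fit <- lm(x_um ~ t_min, data = track)
  slope <- unname(coef(fit)[2])
  structure(list(
    track = track,
    speed_um_min = abs(slope),
    intercept_um = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    direction = if (slope <= 0) "leftward" else "rightward"
  ), class = "front_track")
}

#' Detect mound-formation events in a colony time-lapse
#'
#' Mounds are dense, bright aggregates: pixels above `threshold` are
#' labelled into connected components per frame and component centroids are
#' linked across frames by proximity.  A track persisting for at least
#' `min_frames` frames is an event; its time and position are the first
#' qualifying frame and centroid.
#'
#' @param stack 3-D array.
#' @param threshold intensity threshold separating mounds from the lawn
#'   (matched to the synthetic renderer's levels).
#' @param link_radius_px maximum centroid movement between frames.
#' @param min_frames persistence required to call an event.
#' @param pixel_size_um,frame_interval_min calibration.
#' @return data.frame with `x_px`, `y_px`, `x_um`, `t_min`, `frame` per
#'   event.
#' @export
detect_mound_events <- function(stack, threshold = 1.3, link_radius_px = 8,
                                min_frames = 2, pixel_size_um = 4.2,
                                frame_interval_min = 5) {
  if (length(dim(stack)) != 3) stop("stack must be a 3-D array")
  n_frames <- dim(stack)[3]
  tracks <- data.frame(x = numeric(), y = numeric(), first = integer(),
                       last = integer())
  for (f in seq_len(n_frames)) {
    mask <- stack[, , f] > threshold
    if (!any(mask)) next
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    labm <- as.matrix(EBImage::imageData(lab))
    ids <- setdiff(unique(as.vector(labm)), 0)
    for (id in ids) {
      px <- which(labm == id, arr.ind = TRUE)
      if (nrow(px) < 3) next                      # reject single-pixel noise
      cy <- mean(px[, 1]) - 1; cx <- mean(px[, 2]) - 1
      if (nrow(tracks)) {
        d <- sqrt((tracks$x - cx)^2 + (tracks$y - cy)^2)
        j <- which.min(d)
      }
      if (nrow(tracks) && d[j] <= link_radius_px) {
        tracks$last[j] <- f
      } else {
        tracks <- rbind(tracks, data.frame(x = cx, y = cy, first = f,
                                           last = f))
      }
    }
  }
  keep <- tracks$last - tracks$first + 1L >= min_frames
  ev <- tracks[keep, , drop = FALSE]
  data.frame(x_px = ev$x, y_px = ev$y, x_um = ev$x * pixel_size_um,
             t_min = (ev$first - 1) * frame_interval_min, frame = ev$first,
             row.names = NULL)
}

#' Inter-mound interval statistics per front section
#'
#' Assigns events to fixed-width sections of the axis by their x position,
#' computes successive inter-event intervals within each section (sections
#' with fewer than two events emit none), and summarises the pooled
#' intervals as box statistics: median, quartiles, IQR, whiskers (extreme
#' values within the fences) and outliers under the 1.5 x IQR rule.
#'
#' @param events data.frame with `x_px` (or `x_um`) and `t_min`.
#' @param section_width_px section width (150 px, i.e. 0.63 mm).
#' @param pixel_size_um calibration used when only `x_um` is present.
#' @return list with `per_section` (named list of interval vectors, hours),
#'   `pooled` (vector, hours), `stats` (box statistics) and `n_sections`.
#' @export
interval_stats <- function(events, section_width_px = 150,
                           pixel_size_um = 4.2) {
  if (section_width_px < 1) stop_config("section_width_px must be >= 1")
  x_px <- if ("x_px" %in% names(events)) events$x_px else
    events$x_um / pixel_size_um
  sec <- floor(x_px / section_width_px) + 1L
  per_section <- lapply(split(events$t_min, sec), function(t) {
    t <- sort(t)
    if (length(t) < 2) numeric(0) else diff(t) / 60
  })
  pooled <- unname(unlist(per_section))
  list(per_section = per_section, pooled = pooled,
       stats = if (length(pooled)) box_stats(pooled) else NULL,
       n_sections = length(per_section))
}
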