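#' Locate the spatial inflection of a kymograph profile per frame
#'
#' Operationalises the "inflection" of a spatial intensity profile as the
#' position of maximum-magnitude spatial derivative after Gaussian smoothing.
#' For transcription kymographs the profile is the binned intensity at each
#' frame.  For signalling kymographs (`signal_diff = TRUE`) the profile is
#' the frame-to-frame intensity difference, evaluated only at frames that
#' are cAMP wave maxima (peaks of the spatial-mean trace), mirroring how
#' oscillatory biosensor data are reduced.
#'
#' @param kymo a [build_kymograph()] object.
#' @param smooth_sigma_bins Gaussian smoothing sigma, in bins.
#' @param frames optional integer vector restricting evaluated frames.
#' @param signal_diff treat the kymograph as a signalling record (see above).
#' @param deriv_tol frames whose maximum absolute smoothed derivative falls
#'   below this tolerance emit no point (flat profiles).
#' @param min_deriv_frac frames whose maximum absolute derivative falls
#'   below this fraction of the strongest frame also emit no point; this
#'   drops frames caught between waves, where the profile carries no
#'   boundary information.
#' @return data.frame with `frame`, `t_min` and `x_um` of the inflection.
#' @export
find_inflections <- function(kymo, smooth_sigma_bins = 3, frames = NULL,
                             signal_diff = FALSE, deriv_tol = 1e-6,
                             min_deriv_frac = 0.3) {
  if (!inherits(kymo, "kymograph")) stop_config("kymo must be a kymograph")
  if (smooth_sigma_bins <= 0) stop_config("smooth_sigma_bins must be > 0")
  m <- kymo$intensity
  if (length(m) == 0) stop("empty kymograph")
  dt_min <- kymo$frame_interval_s / 60
  if (signal_diff) {
    d <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
    mean_tr <- colMeans(m)
    pk <- which(diff(sign(diff(mean_tr))) == -2) + 1L
    frames_use <- if (is.null(frames)) pk else intersect(pk, frames)
    frames_use <- frames_use[frames_use > 1 & frames_use <= ncol(m)]
    profiles <- d
    pick <- frames_use - 1L              # diff column f-1 is change into frame f
  } else {
    profiles <- m
    frames_use <- if (is.null(frames)) seq_len(ncol(m)) else frames
    pick <- frames_use
  }
  smoothed <- lapply(seq_along(frames_use), function(i) {
    diff(gauss_smooth1d(profiles[, pick[i]], smooth_sigma_bins))
  })
  dmax <- vapply(smoothed, function(dp) if (length(dp)) max(abs(dp)) else 0,
                 numeric(1))
  floor_frame <- max(deriv_tol, min_deriv_frac * max(dmax, 0))
  out <- lapply(seq_along(frames_use), function(i) {
    dp <- smoothed[[i]]
    if (!length(dp) || dmax[i] < floor_frame) return(NULL)
    j <- which.max(abs(dp))
    # derivative lives between bins j and j+1; refine with the parabola
    offs <- if (j > 1 && j < length(dp)) {
      parabolic_offset(abs(dp[j - 1]), abs(dp[j]), abs(dp[j + 1]))
    } else 0
    x_bins <- j + 0.5 + offs             # bin centre convention, 1-based
    data.frame(frame = frames_use[i],
               t_min = (frames_use[i] - 1) * dt_min,
               x_um = (x_bins - 0.5) * kymo$bin_width_um)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(), t_min = numeric(), x_um = numeric())
  out
}

#' Fit a robust space-time line through inflection points
#'
#' Summarises per-frame inflection positions with a Theil-Sen regression of
#' position on time, the convention used to draw boundary lines on
#' kymographs.
#'
#' @param points data.frame from [find_inflections()] (`t_min`, `x_um`).
#' @return object of class `boundary_fit`: the points plus `slope_um_min`,
#'   `intercept_um` and the median absolute residual (`residual_scale`).
#'   The line is only fitted when at least 3 points are available.
#' @export
fit_boundary <- function(points) {
  if (nrow(points) < 3) {
    return(structure(list(points = points, slope_um_min = NA_real_,
                          intercept_um = NA_real_, residual_scale = NA_real_),
                     class = "boundary_fit"))
  }
  ts <- theil_sen(points$t_min, points$x_um)
  res <- points$x_um - (ts$intercept + ts$slope * points$t_min)
  structure(list(points = points, slope_um_min = ts$slope,
                 intercept_um = ts$intercept,
                 residual_scale = median(abs(res))),
            class = "boundary_fit")
}

#' Spatial offset between two inflection boundaries
#'
#' Computes the mean spatial offset `x_A - x_B` over the shared time range
#' of two boundary point sets (positions interpolated onto the shared
#' times), with a bootstrap confidence interval obtained by resampling
#' time points.
#'
#' @param a,b `boundary_fit` objects or inflection data.frames.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param rng_seed seed for the bootstrap.
#' @return list with `offset_um`, `ci` (length 2) and `n_shared`.
#' @export
compare_boundaries <- function(a, b, n_boot = 500, conf = 0.95,
                               rng_seed = 1L) {
  pa <- if (inherits(a, "boundary_fit")) a$points else a
  pb <- if (inherits(b, "boundary_fit")) b$points else b
  lo <- max(min(pa$t_min), min(pb$t_min))
  hi <- min(max(pa$t_min), max(pb$t_min))
  if (hi <= lo) stop("boundaries share no time range")
  ta <- pa$t_min[pa$t_min >= lo & pa$t_min <= hi]
  if (length(ta) < 2) stop("too few shared time points")
  xa <- pa$x_um[pa$t_min >= lo & pa$t_min <= hi]
  xb <- approx(pb$t_min, pb$x_um, xout = ta, rule = 2)$y
  diffs <- xa - xb
  boots <- withr::with_seed(as.integer(rng_seed), {
    vapply(seq_len(n_boot), function(i) {
      mean(diffs[sample.int(length(diffs), replace = TRUE)])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  list(offset_um = mean(diffs),
       ci = unname(quantile(boots, c(alpha, 1 - alpha))),
       n_shared = length(diffs))
}

#' Estimate the oscillation period of a trace
#'
#' The period is the lag of the first autocorrelation peak after lag zero,
#' refined with a 3-point parabola.  A peak is only accepted above a
#' significance floor of `2 / sqrt(n)` (the large-sample null level for an
#' uncorrelated series); traces without such a peak have no detectable
#' period and return `NA` with `detected = FALSE`.
#'
#' @param trace numeric trace, regularly sampled.
#' @param frame_interval_s sampling interval.
#' @param detrend linearly detrend before autocorrelation.
#' @return list with `period_s` (NA when undetected), `detected`, and the
#'   autocorrelation peak height.
#' @export
estimate_period <- function(trace, frame_interval_s = 45, detrend = TRUE) {
  n <- length(trace)
  if (n < 8) stop("trace too short")
  x <- if (detrend) detrend_z(trace) else trace
  if (sd(x) == 0)
    return(list(period_s = NA_real_, detected = FALSE, peak = NA_real_))
  ac <- as.numeric(acf(x, lag.max = floor(n / 2), plot = FALSE)$acf)
  floor_sig <- 2 / sqrt(n)
  # first local maximum after lag 0
  k <- NA_integer_
  for (j in 2:(length(ac) - 1)) {
    if (ac[j] > ac[j - 1] && ac[j] > ac[j + 1] && ac[j] > floor_sig) {
      k <- j; break
    }
  }
  if (is.na(k))
    return(list(period_s = NA_real_, detected = FALSE, peak = NA_real_))
  offs <- parabolic_offset(ac[k - 1], ac[k], ac[k + 1])
  list(period_s = (k - 1 + offs) * frame_interval_s, detected = TRUE,
       peak = ac[k])
}

# correlation between a and b with b shifted left by k frames (k may be
# negative); computed on the overlap
shift_cor <- function(a, b, k) {
  n <- length(a)
  if (k >= 0) {
    ia <- 1:(n - k); ib <- (1 + k):n
  } else {
    ia <- (1 - k):n; ib <- 1:(n + k)
  }
  if (length(ia) < 3) return(NA_real_)
  sa <- a[ia]; sb <- b[ib]
  if (sd(sa) == 0 || sd(sb) == 0) return(NA_real_)
  cor(sa, sb)
}

#' Cross-correlation lag between signalling and transcription traces
#'
#' Both traces are linearly detrended and z-normalised, then correlated over
#' all integer frame shifts up to `max_lag_s`.  The returned lag is the
#' argmax refined with a 3-point parabola; ties break toward smaller
#' absolute lag.  Positive lag means transcription follows signalling.
#'
#' @param signal_trace,txn_trace equal-length traces.
#' @param max_lag_s maximum search lag, seconds.
#' @param frame_interval_s sampling interval.
#' @return object of class `lag_estimate`: list with `lag_s`, `lag_frames`
#'   (unrefined integer argmax), `cc` (correlation per shift), `shifts_s`,
#'   `period_s` (from the signal autocorrelation) and `peak_cor`.
#' @export
estimate_lag <- function(signal_trace, txn_trace, max_lag_s = 450,
                         frame_interval_s = 45) {
  if (length(signal_trace) != length(txn_trace))
    stop("traces must have equal length")
  max_lag <- floor(max_lag_s / frame_interval_s)
  n <- length(signal_trace)
  if (n < 2 * max_lag) stop("traces shorter than twice the maximum lag")
  a <- detrend_z(signal_trace)
  b <- detrend_z(txn_trace)
  shifts <- -max_lag:max_lag
  cc <- vapply(shifts, function(k) shift_cor(a, b, k), numeric(1))
  ok <- which(is.finite(cc))
  if (!length(ok)) stop("degenerate traces")
  best <- ok[order(-cc[ok], abs(shifts[ok]))][1]   # ties -> smaller |lag|
  offs <- if (best > 1 && best < length(shifts) &&
              is.finite(cc[best - 1]) && is.finite(cc[best + 1])) {
    parabolic_offset(cc[best - 1], cc[best], cc[best + 1])
  } else 0
  per <- estimate_period(signal_trace, frame_interval_s)
  structure(list(
    lag_s = (shifts[best] + offs) * frame_interval_s,
    lag_frames = shifts[best],
    cc = cc, shifts_s = shifts * frame_interval_s,
    period_s = per$period_s, peak_cor = cc[best]
  ), class = "lag_estimate")
}

#' Detect sustained induction of a transcription trace
#'
#' A trace is induced when it exceeds `baseline mean + k_sigma * baseline
#' SD` for at least `m_frames` consecutive frames; the onset is the first
#' frame of the first qualifying run.
#'
#' @param trace numeric trace.
#' @param baseline_window frames used for the baseline; default the first
#'   10\% (at least 5 frames).
#' @param k_sigma threshold in baseline SDs.
#' @param m_frames minimum consecutive frames above threshold.
#' @param frame_interval_s sampling interval.
#' @return list with `induced`, `onset_frame` (NA when not induced),
#'   `onset_min` and `threshold`.
#' @export
detect_induction <- function(trace, baseline_window = NULL, k_sigma = 3,
                             m_frames = 3, frame_interval_s = 45) {
  n <- length(trace)
  if (is.null(baseline_window)) baseline_window <- seq_len(max(5L, floor(0.1 * n)))
  bl <- trace[baseline_window]
  thr <- mean(bl) + k_sigma * sd(bl)
  above <- trace > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= m_frames)
  if (!length(hit)) {
    return(list(induced = FALSE, onset_frame = NA_integer_,
                onset_min = NA_real_, threshold = thr))
  }
  onset <- starts[hit[1]]
  list(induced = TRUE, onset_frame = onset,
       onset_min = (onset - 1) * frame_interval_s / 60, threshold = thr)
}

#' Classify a gene's frequency response from two pulse-train experiments
#'
#' Compares induction under a 6-min and a 10-min optogenetic pulse train.
#' Genes induced at both intervals follow simple lagged activation
#' (`one_step`, carA-like); genes induced only at the longer interval are
#' frequency-gated (`two_step`, cafA-like); genes induced at neither are
#' `unresponsive`.  Induction at the short but not the long interval has no
#' model under this scheme and is flagged `anomalous`.
#'
#' @param induced_short,induced_long logical induction calls (or results of
#'   [detect_induction()]) at the short (6 min) and long (10 min) intervals.
#' @return one of `"one_step"`, `"two_step"`, `"unresponsive"`,
#'   `"anomalous"`.
#' @export
classify_frequency_response <- function(induced_short, induced_long) {
  g <- function(x) if (is.list(x)) isTRUE(x$induced) else isTRUE(x)
  s <- g(induced_short); l <- g(induced_long)
  if (s && l) "one_step"
  else if (!s && l) "two_step"
  else if (!s && !l) "unresponsive"
  else {
    warning("induced at the short but not the long pulse interval")
    "anomalous"
  }
}
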