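# strict 8-neighbour local maxima of a matrix, returned as (row, col) indices
local_maxima <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (h < 3 || w < 3) return(cbind(integer(), integer()))
  core <- m[2:(h - 1), 2:(w - 1)]
  ok <- core > m[1:(h - 2), 2:(w - 1)] & core > m[3:h, 2:(w - 1)] &
    core > m[2:(h - 1), 1:(w - 2)] & core > m[2:(h - 1), 3:w] &
    core > m[1:(h - 2), 1:(w - 2)] & core > m[1:(h - 2), 3:w] &
    core > m[3:h, 1:(w - 2)] & core > m[3:h, 3:w]
  idx <- which(ok, arr.ind = TRUE)
  cbind(idx[, 1] + 1L, idx[, 2] + 1L)
}

#' Detect nascent-transcription spots in an image stack
#'
#' Band-pass spot detection: each frame is filtered with a
#' difference-of-Gaussians (`sigma_small` minus `sigma_large`), candidate
#' spots are strict local maxima of the filtered frame exceeding
#' `median + k_mad * MAD`, and spot intensity is the sum of
#' background-subtracted pixels in a disc of `radius_px` around the peak
#' (local background = median of an annulus just outside the disc).
#'
#' @param stack 3-D array (height x width x frames), single channel.
#' @param sigma_small,sigma_large band-pass sigmas in px
#'   (`sigma_small < sigma_large`).
#' @param k_mad detection threshold in MADs of the filtered frame.
#' @param radius_px integration disc radius.
#' @param min_intensity minimum integrated intensity for a spot; suppresses
#'   residual responses from diffuse cell bodies.
#' @return data.frame (`frame`, `x_px`, `y_px`, `intensity`), sorted by
#'   (frame, x); coordinates are 0-based pixel centres.
#' @export
detect_spots <- function(stack, sigma_small = 1, sigma_large = 3,
                         k_mad = 6, radius_px = 4, min_intensity = 3) {
  if (length(dim(stack)) != 3 || any(dim(stack) == 0))
    stop("empty or non 3-D stack")
  if (sigma_small >= sigma_large) stop_config("sigma_small must be < sigma_large")
  h <- dim(stack)[1]; w <- dim(stack)[2]; n_frames <- dim(stack)[3]

  off <- expand.grid(dy = -(radius_px + 3):(radius_px + 3),
                     dx = -(radius_px + 3):(radius_px + 3))
  rr <- sqrt(off$dx^2 + off$dy^2)
  disc <- off[rr <= radius_px, ]
  annulus <- off[rr > radius_px & rr <= radius_px + 3, ]

  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    frame <- stack[, , f]
    dog <- EBImage::gblur(frame, sigma = sigma_small) -
      EBImage::gblur(frame, sigma = sigma_large)
    thr <- median(dog) + k_mad * mad(dog)
    pk <- local_maxima(dog)
    if (nrow(pk) == 0) next
    keep <- dog[pk] > thr
    pk <- pk[keep, , drop = FALSE]
    if (nrow(pk) == 0) next
    res <- data.frame(frame = f, x_px = numeric(nrow(pk)),
                      y_px = numeric(nrow(pk)), intensity = numeric(nrow(pk)))
    ok <- logical(nrow(pk))
    for (i in seq_len(nrow(pk))) {
      py <- pk[i, 1]; px <- pk[i, 2]
      dy <- py + disc$dy; dx <- px + disc$dx
      din <- dy >= 1 & dy <= h & dx >= 1 & dx <= w
      ay <- py + annulus$dy; ax <- px + annulus$dx
      ain <- ay >= 1 & ay <= h & ax >= 1 & ax <= w
      bg <- median(frame[cbind(ay[ain], ax[ain])])
      intens <- sum(frame[cbind(dy[din], dx[din])] - bg)
      if (intens > min_intensity) {
        ok[i] <- TRUE
        res$x_px[i] <- px - 1
        res$y_px[i] <- py - 1
        res$intensity[i] <- intens
      }
    }
    out[[f]] <- res[ok, , drop = FALSE]
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
                      intensity = numeric())
  out <- out[order(out$frame, out$x_px), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Otsu threshold guarded against structure-free frames: returns Inf when the
# threshold sits within the noise of the background (estimated from the
# dimmer half of the frame, so bright cells covering a large area do not
# inflate it).
guarded_otsu <- function(frame, guard_mads = 6) {
  rng <- range(frame)
  if (diff(rng) == 0) return(Inf)
  thr <- EBImage::otsu(frame, range = rng, levels = 256)
  lower <- frame[frame <= median(frame)]
  noise <- mad(lower)
  if (thr <= median(lower) + guard_mads * max(noise, 1e-12)) return(Inf)
  thr
}

#' Mask reporter cells and extract the biosensor signalling trace
#'
#' Reporter cells are more variable in background intensity than the
#' Flamindo2 biosensor cells, so their pixels are masked out before
#' averaging the biosensor channel.  The reporter-cell mask is an Otsu
#' threshold on the smoothed time-maximum projection of the reporter
#' channel plus a 2-px dilation (the maximum catches cells whose spots
#' flicker); cell-containing pixels are an Otsu threshold on the smoothed
#' time-median projection of the biosensor channel.  The trace is the
#' per-frame mean biosensor intensity over cell-containing, non-reporter
#' pixels.  Because Flamindo2 dims when cAMP binds, the inverted trace
#' `median(trace) - trace` rises with cAMP.
#'
#' @param stack_reporter,stack_flamindo aligned 3-D arrays with equal
#'   dimensions.
#' @param dilate_px dilation of the reporter mask.
#' @return list with `trace`, `inverted`, `mask` (logical matrix) and
#'   `n_masked_px` per frame.
#' @export
mask_and_trace <- function(stack_reporter, stack_flamindo, dilate_px = 2) {
  if (!identical(dim(stack_reporter), dim(stack_flamindo)))
    stop("channels must have identical dimensions")
  n_frames <- dim(stack_flamindo)[3]
  kern <- EBImage::makeBrush(2 * dilate_px + 1, shape = "disc")
  rep_s <- EBImage::gblur(apply(stack_reporter, c(1, 2), max), sigma = 2)
  fla_s <- EBImage::gblur(apply(stack_flamindo, c(1, 2), median), sigma = 2)
  repmask <- rep_s > guarded_otsu(rep_s)
  if (any(repmask)) {
    repmask <- EBImage::dilate(EBImage::Image(repmask * 1), kern) > 0.5
  }
  cellmask <- fla_s > guarded_otsu(fla_s)
  if (!any(cellmask)) stop("no cell-containing pixels")
  use <- cellmask & !repmask
  if (!any(use)) stop("all cell pixels masked; degenerate input")
  trace <- vapply(seq_len(n_frames),
                  function(f) mean(stack_flamindo[, , f][use]), numeric(1))
  list(trace = trace, inverted = median(trace) - trace,
       mask = repmask, n_masked_px = rep(sum(repmask), n_frames))
}

#' Build a space-time kymograph
#'
#' Averages spot intensities (or a space-resolved signal matrix) into
#' spatial bins per frame.  Entry (j, t) is the mean intensity of spots with
#' x in bin j at frame t, or 0 if the bin is empty; bin j covers pixels
#' `[(j-1) * bin_width_px, j * bin_width_px)`.
#'
#' @param x either a spot table (data.frame with `frame`, `x_px`,
#'   `intensity`) or a matrix (space positions x frames, one row per pixel).
#' @param bin_width_px spatial bin width in pixels (>= 1).
#' @param field_length_px axis length; required for spot tables.
#' @param n_frames frame count; required for spot tables.
#' @param pixel_size_um,frame_interval_s physical calibration carried in the
#'   metadata.
#' @return object of class `kymograph`: list with `intensity` (bins x
#'   frames), `count` (spots per bin, spot input only), `bin_width_px`,
#'   `bin_width_um`, `pixel_size_um`, `frame_interval_s`.
#' @export
build_kymograph <- function(x, bin_width_px = 10, field_length_px = NULL,
                            n_frames = NULL, pixel_size_um = 0.35,
                            frame_interval_s = 45) {
  if (bin_width_px < 1) stop_config("bin_width_px must be >= 1")
  if (is.data.frame(x)) {
    if (is.null(field_length_px) || is.null(n_frames))
      stop_config("field_length_px and n_frames are required for spot tables")
    n_bins <- ceiling(field_length_px / bin_width_px)
    intensity <- matrix(0, n_bins, n_frames)
    count <- matrix(0L, n_bins, n_frames)
    if (nrow(x) > 0) {
      bin <- pmin(floor(x$x_px / bin_width_px) + 1L, n_bins)
      for (i in seq_len(nrow(x))) {
        b <- bin[i]; f <- x$frame[i]
        count[b, f] <- count[b, f] + 1L
        intensity[b, f] <- intensity[b, f] + x$intensity[i]
      }
      nz <- count > 0
      intensity[nz] <- intensity[nz] / count[nz]
    }
  } else {
    m <- as.matrix(x)
    n_bins <- ceiling(nrow(m) / bin_width_px)
    bin <- floor((seq_len(nrow(m)) - 1L) / bin_width_px) + 1L
    intensity <- apply(m, 2, function(col) tapply(col, bin, mean))
    intensity <- matrix(intensity, nrow = n_bins)
    count <- NULL
  }
  structure(list(intensity = intensity, count = count,
                 bin_width_px = bin_width_px,
                 bin_width_um = bin_width_px * pixel_size_um,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "kymograph")
}
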