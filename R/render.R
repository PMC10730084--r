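# add a 2-D Gaussian of integrated intensity `total` at (x, y) (0-based px)
add_gaussian <- function(img, x, y, sigma, total) {
  h <- nrow(img); w <- ncol(img)
  half <- ceiling(4 * sigma)
  cx <- round(x); cy <- round(y)
  xs <- max(0, cx - half):min(w - 1, cx + half)
  ys <- max(0, cy - half):min(h - 1, cy + half)
  if (!length(xs) || !length(ys)) return(img)
  amp <- total / (2 * pi * sigma^2)
  gx <- exp(-0.5 * ((xs - x) / sigma)^2)
  gy <- exp(-0.5 * ((ys - y) / sigma)^2)
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amp * outer(gy, gx)
  img
}

#' Render a two-channel imaging stack from a niche simulation
#'
#' Produces synthetic microscopy of the simulated niche: a transcription
#' reporter channel (dim cell bodies plus bright nascent-transcription
#' puncta whose integrated intensity is proportional to the local
#' transcription rate) and a Flamindo2 biosensor channel (cell bodies whose
#' fluorescence dims as cAMP rises: pixel value
#' `F0 * (1 - gamma * c / c_max)` plus Gaussian read noise).  Coordinates
#' are 0-based pixel centres; x is the differentiation axis.
#'
#' @param truth a `signal_truth` with the transcription layer filled in.
#' @param height_px image height.
#' @param f0 baseline Flamindo2 fluorescence of a biosensor cell.
#' @param gamma fractional dimming at peak cAMP (`c = amplitude`).
#' @param body_sigma_px,body_amplitude cell-body Gaussian footprint.
#' @param spot_sigma_px spot point-spread sigma.
#' @param spot_gain integrated spot counts per unit transcription rate.
#' @param spot_min_rate transcription rate below which no spot is rendered
#'   (and none is listed in the truth table).
#' @param background,noise_sd camera offset and read-noise sd.
#' @param rng_seed seed for cell y-positions and noise (default: config
#'   seed + 2).
#' @return list with `reporter` and `flamindo` (arrays, height x width x
#'   frames), `spots` (truth table: `frame`, `x_px`, `y_px`, `intensity`),
#'   `cells` (positions and channel labels) and rendering parameters.
#' @export
render_stack <- function(truth, height_px = 60, f0 = 1, gamma = 0.4,
                         body_sigma_px = 4, body_amplitude = 0.12,
                         spot_sigma_px = 1.2, spot_gain = 50,
                         spot_min_rate = 0.1, background = 0.05,
                         noise_sd = 0.02, rng_seed = NULL) {
  if (!inherits(truth, "signal_truth")) stop_config("truth must be a signal_truth")
  if (is.null(truth$txn_rate)) stop_config("truth has no transcription layer")
  cfg <- truth$config
  w <- cfg$field_length_px
  n_frames <- ncol(truth$camp)
  n_cells <- nrow(truth$cell_positions)
  if (w * height_px < 40 * n_cells)
    stop_config("field too small for %d cells", n_cells)
  if (is.null(rng_seed)) rng_seed <- cfg$rng_seed + 2L

  withr::with_seed(as.integer(rng_seed), {
    cells <- truth$cell_positions
    cells$x_px <- cells$x_um / cfg$pixel_size_um
    cells$y_px <- runif(n_cells, 0.15 * height_px, 0.85 * height_px)
    col_idx <- pmin(pmax(round(cells$x_px) + 1L, 1L), w)
    is_rep <- cells$channel == "reporter"

    reporter <- array(background, dim = c(height_px, w, n_frames))
    flamindo <- array(background, dim = c(height_px, w, n_frames))
    spots <- vector("list", n_frames)
    body_total <- body_amplitude * 2 * pi * body_sigma_px^2

    for (f in seq_len(n_frames)) {
      rep_f <- matrix(0, height_px, w)
      fla_f <- matrix(0, height_px, w)
      c_here <- truth$camp[col_idx, f]
      r_here <- truth$txn_rate[col_idx, f]
      fla_level <- f0 * (1 - gamma * c_here / max(cfg$amplitude, .Machine$double.eps))
      sp <- list()
      for (i in seq_len(n_cells)) {
        if (is_rep[i]) {
          rep_f <- add_gaussian(rep_f, cells$x_px[i], cells$y_px[i],
                                body_sigma_px, body_total)
          # reporter cells show weak bleed-through in the biosensor channel
          fla_f <- add_gaussian(fla_f, cells$x_px[i], cells$y_px[i],
                                body_sigma_px, 0.3 * body_total)
          if (r_here[i] > spot_min_rate) {
            intensity <- spot_gain * r_here[i]
            rep_f <- add_gaussian(rep_f, cells$x_px[i], cells$y_px[i],
                                  spot_sigma_px, intensity)
            sp[[length(sp) + 1L]] <- data.frame(
              frame = f, x_px = cells$x_px[i], y_px = cells$y_px[i],
              intensity = intensity)
          }
        } else {
          # peak pixel value of a biosensor cell tracks F0 * (1 - gamma c/cmax)
          fla_f <- add_gaussian(fla_f, cells$x_px[i], cells$y_px[i],
                                body_sigma_px,
                                fla_level[i] * 2 * pi * body_sigma_px^2)
        }
      }
      reporter[, , f] <- reporter[, , f] + rep_f
      flamindo[, , f] <- flamindo[, , f] + fla_f
      if (length(sp)) spots[[f]] <- do.call(rbind, sp)
    }
    if (noise_sd > 0) {
      reporter <- reporter + array(rnorm(length(reporter), 0, noise_sd),
                                   dim = dim(reporter))
      flamindo <- flamindo + array(rnorm(length(flamindo), 0, noise_sd),
                                   dim = dim(flamindo))
    }
    spots <- if (any(!vapply(spots, is.null, logical(1)))) {
      do.call(rbind, spots)
    } else {
      data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
                 intensity = numeric())
    }
    rownames(spots) <- NULL
    list(reporter = reporter, flamindo = flamindo, spots = spots,
         cells = cells,
         params = list(height_px = height_px, f0 = f0, gamma = gamma,
                       body_sigma_px = body_sigma_px,
                       body_amplitude = body_amplitude,
                       spot_sigma_px = spot_sigma_px, spot_gain = spot_gain,
                       spot_min_rate = spot_min_rate,
                       background = background, noise_sd = noise_sd),
         config = cfg)
  })
}
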