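#' @keywords internal
"_PACKAGE"

#' @importFrom stats acf coef cor dist lm median prcomp quantile resid rnbinom
#'   rnorm rpois runif sd setNames var approx pgamma qgamma cutree hclust
#'   as.dist rlnorm mad
#' @importFrom utils head tail read.csv write.csv
NULL

# raised-cosine pulse on cycle fraction u in [0, 1); duty = fraction of the
# cycle occupied by the pulse.  Peak value 1 at u = duty/2.
raised_cosine <- function(u, duty) {
  stopifnot(duty > 0, duty <= 1)
  out <- numeric(length(u))
  inside <- u >= 0 & u < duty
  out[inside] <- 0.5 * (1 - cos(2 * pi * u[inside] / duty))
  out
}

# 1-D Gaussian smoothing with reflected boundaries; sigma in sample units.
gauss_smooth1d <- function(x, sigma) {
  if (sigma <= 0) stop("smoothing sigma must be positive")
  n <- length(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  xp <- c(x[pmin(half:1, n)], x, x[pmax(n - (1:half) + 1, 1)])
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

# Theil-Sen line: median of pairwise slopes, intercept = median(y - slope x).
# Robust to sporadic-transcription outliers; small-n exact implementation.
theil_sen <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 finite points")
  ij <- utils::combn(length(x), 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- dx != 0
  slope <- median(dy[keep] / dx[keep])
  intercept <- median(y - slope * x)
  list(slope = slope, intercept = intercept)
}

# Parabolic (3-point) refinement of a discrete argmax.  `v` are values at
# integer positions `idx - 1, idx, idx + 1`; returns fractional offset in
# [-0.5, 0.5].  Degenerate (flat) triplets refine to 0, i.e. ties break
# toward the unrefined peak.
parabolic_offset <- function(vm1, v0, vp1) {
  denom <- vm1 - 2 * v0 + vp1
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * 10) return(0)
  off <- 0.5 * (vm1 - vp1) / denom
  max(-0.5, min(0.5, off))
}

# linear detrend + z-normalisation used before correlation analyses
detrend_z <- function(x) {
  t <- seq_along(x)
  r <- resid(lm(x ~ t))
  s <- sd(r)
  if (s == 0) return(rep(0, length(x)))
  as.numeric(r / s)
}

# quartile-based box statistics with the 1.5 x IQR outlier rule
# (quartiles are type-7 quantiles)
box_stats <- function(x) {
  x <- x[is.finite(x)]
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  list(
    median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
    whisker_low = if (any(inside)) min(x[inside]) else NA_real_,
    whisker_high = if (any(inside)) max(x[inside]) else NA_real_,
    outliers = sort(x[!inside]), n = length(x)
  )
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
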