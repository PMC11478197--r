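# Peak processing: Savitzky-Golay smoothing, morphological baseline,
# noise estimation, peak detection/bounding/integration, LOD/LOQ.

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing with symmetric window; edge
#' samples (half a window at each end) are left unsmoothed.
#'
#' @param y numeric vector.
#' @param window odd window length in samples (default 11).
#' @param order polynomial order (default 3; must be < window).
#' @return smoothed numeric vector, same length.
#' @export
savgol_smooth <- function(y, window = 11, order = 3) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (order >= window) stop("order must be < window")
  if (length(y) < window) return(y)
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:order, `^`)
  w <- (A %*% solve(crossprod(A), t(A)))[h + 1L, ]
  ys <- as.numeric(stats::filter(y, w, sides = 2))
  bad <- is.na(ys)
  ys[bad] <- y[bad]
  ys
}

# rolling min/max by shifted pmin/pmax; edges padded with end values
roll_extreme <- function(y, half, fun) {
  n <- length(y)
  out <- y
  for (s in seq_len(half)) {
    right <- c(y[-seq_len(s)], rep(y[n], s))
    left <- c(rep(y[1], s), y[seq_len(n - s)])
    out <- fun(out, left, right)
  }
  out
}

#' Morphological baseline (rolling-minimum opening)
#'
#' Erosion (rolling minimum) followed by dilation (rolling maximum) with a
#' structuring window wider than any chromatographic peak, lightly smoothed.
#' Tracks low-order drift while passing under the peaks.
#'
#' @param y intensity vector.
#' @param half_width half window in samples; choose > 4 peak sigmas
#'   (default 50, i.e. 1 min at a 0.02-min grid).
#' @return baseline vector, same length as `y`.
#' @export
estimate_baseline <- function(y, half_width = 50) {
  op <- roll_extreme(roll_extreme(y, half_width, pmin),
                     half_width, pmax)
  # light mean filter to remove opening plateaus
  k <- max(3L, half_width %/% 2L)
  sm <- as.numeric(stats::filter(op, rep(1 / (2 * k + 1), 2 * k + 1),
                                 sides = 2))
  sm[is.na(sm)] <- op[is.na(sm)]
  sm
}

#' Estimate detector noise in a peak-free region
#'
#' Standard deviation of the linearly detrended intensity over a stated
#' peak-free time interval.
#'
#' @param chrom a [chromatogram()].
#' @param region c(start, end) in minutes, within the grid, containing at
#'   least 20 samples.
#' @param peaks optional peak list (as from [detect_peaks()]); if any apex
#'   falls inside `region`, the call is rejected.
#' @return object of class `noise_estimate`: list with `sd` (counts) and
#'   `region`.
#' @export
estimate_noise <- function(chrom, region, peaks = NULL) {
  stopifnot(inherits(chrom, "chromatogram"), length(region) == 2)
  region <- sort(as.numeric(region))
  tt <- chrom$time
  if (region[1] < tt[1] || region[2] > tt[length(tt)])
    stop("region outside the time grid")
  idx <- which(tt >= region[1] & tt <= region[2])
  if (length(idx) < 20L) stop("region shorter than 20 samples")
  if (!is.null(peaks) && nrow(peaks) > 0 &&
      any(peaks$apex_time >= region[1] & peaks$apex_time <= region[2]))
    stop("noise region overlaps a detected peak")
  fit <- stats::lm.fit(cbind(1, tt[idx]), chrom$intensity[idx])
  structure(list(sd = stats::sd(fit$residuals), region = region),
            class = "noise_estimate")
}

# prominence of local maximum at index i of signal s, given all candidate
# maxima indices
peak_prominence <- function(s, i, maxima) {
  h <- s[i]
  n <- length(s)
  higher <- maxima[s[maxima] > h]
  lo <- higher[higher < i]
  hi <- higher[higher > i]
  lbase <- min(s[(if (length(lo)) max(lo) else 1):i])
  rbase <- min(s[i:(if (length(hi)) min(hi) else n)])
  h - max(lbase, rbase)
}

#' Detect, bound and integrate chromatographic peaks
#'
#' Peaks are local maxima of the smoothed, baseline-subtracted signal with
#' prominence and height at least `min_snr` times the noise sd. Bounds are
#' placed at the valley minimum towards each retained neighbour (perpendicular
#' drop for fused peaks) or at the near-baseline crossing, whichever is
#' closer to the apex; areas are trapezoidal integrals of the raw
#' baseline-subtracted signal between the bounds.
#'
#' @param chrom a [chromatogram()].
#' @param min_snr detection threshold in noise-sd units (default 5).
#' @param window,order Savitzky-Golay smoothing parameters.
#' @param baseline_half_width structuring half window in samples for
#'   [estimate_baseline()]; NULL picks 1 min worth of samples.
#' @param noise_sd noise sd in counts; NULL estimates it from the median
#'   absolute first difference of the baseline-subtracted signal.
#' @param min_rel_height relative height floor: candidates below
#'   `min_rel_height * max(signal)` are discarded even when the noise sd is
#'   negligible (suppresses smoothing/baseline ripple on noiseless traces).
#' @return data.frame of class `peak_list`, sorted by apex time, with
#'   columns `peak_id`, `apex_time`, `left`, `right`, `height`, `area`,
#'   `snr`. A flat input yields zero rows.
#' @export
detect_peaks <- function(chrom, min_snr = 5, window = 11, order = 3,
                         baseline_half_width = NULL, noise_sd = NULL,
                         min_rel_height = 1e-3) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (min_snr <= 0) stop("min_snr must be > 0")
  tt <- chrom$time
  dt <- grid_dt(chrom)
  if (is.null(baseline_half_width))
    baseline_half_width <- max(10L, as.integer(round(1 / dt)))
  ysm <- savgol_smooth(chrom$intensity, window, order)
  bl <- estimate_baseline(ysm, baseline_half_width)
  s <- ysm - bl
  raw <- chrom$intensity - bl
  if (is.null(noise_sd))
    noise_sd <- stats::mad(diff(raw)) / sqrt(2)
  n <- length(s)
  empty <- data.frame(peak_id = integer(), apex_time = numeric(),
                      left = numeric(), right = numeric(),
                      height = numeric(), area = numeric(),
                      snr = numeric())
  class(empty) <- c("peak_list", "data.frame")
  smax <- max(s)
  if (smax <= 0) return(empty)
  thr <- max(min_snr * noise_sd, min_rel_height * smax)
  maxima <- which(s[2:(n - 1)] > s[1:(n - 2)] &
                    s[2:(n - 1)] >= s[3:n]) + 1L
  if (!length(maxima)) return(empty)
  prom <- vapply(maxima, function(i) peak_prominence(s, i, maxima),
                 numeric(1))
  keep <- maxima[prom >= thr & s[maxima] >= thr]
  if (!length(keep)) return(empty)
  keep <- sort(keep)
  m <- length(keep)
  left <- right <- integer(m)
  for (j in seq_len(m)) {
    i <- keep[j]
    cross <- max(0.001 * s[i], noise_sd)
    # left: valley towards previous retained peak, or near-baseline crossing
    lo <- if (j > 1) keep[j - 1] else 1L
    seg <- s[lo:i]
    vall <- lo + which.min(seg) - 1L
    below <- which(s[lo:i] <= cross)
    crossidx <- if (length(below)) lo + max(below) - 1L else lo
    left[j] <- max(vall, crossidx)
    hi <- if (j < m) keep[j + 1] else n
    seg <- s[i:hi]
    valr <- i + which.min(seg) - 1L
    below <- which(s[i:hi] <= cross)
    crossidx <- if (length(below)) i + min(below) - 1L else hi
    right[j] <- min(valr, crossidx)
  }
  area <- vapply(seq_len(m), function(j) {
    idx <- left[j]:right[j]
    max(sum(diff(tt[idx]) * (raw[idx][-1] + raw[idx][-length(idx)]) / 2), 0)
  }, numeric(1))
  out <- data.frame(peak_id = seq_len(m), apex_time = tt[keep],
                    left = tt[left], right = tt[right],
                    height = s[keep], area = area,
                    snr = if (noise_sd > 0) s[keep] / noise_sd else Inf)
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Limits of detection and quantification from noise and sensitivity
#'
#' LOD and LOQ are the concentrations whose peak height reaches 3 and 10
#' times the noise sd: `lod = 3 * sd / sensitivity`,
#' `loq = 10 * sd / sensitivity`, so `loq = (10/3) * lod` exactly.
#'
#' @param noise a `noise_estimate` or a numeric noise sd (counts).
#' @param sensitivity peak height per unit concentration
#'   (counts per ug/mL, > 0).
#' @return list with elements `lod`, `loq` (ug/mL).
#' @export
lod_loq <- function(noise, sensitivity) {
  sd <- if (inherits(noise, "noise_estimate")) noise$sd else as.numeric(noise)
  if (!is.finite(sensitivity) || sensitivity <= 0)
    stop("sensitivity must be > 0")
  if (sd < 0) stop("noise sd must be >= 0")
  list(lod = 3 * sd / sensitivity, loq = 10 * sd / sensitivity)
}

#' Write a peak list as CSV
#' @param peaks a `peak_list`.
#' @param path output file.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(peak_id = peaks$peak_id,
                   apex_time_min = peaks$apex_time,
                   left_min = peaks$left, right_min = peaks$right,
                   height = peaks$height, area = peaks$area,
                   snr = peaks$snr)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
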