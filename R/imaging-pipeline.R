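#' Rigid motion correction
#'
#' Aligns the movie by integer-pixel translation using the
#' cross-correlation between successive frames (computed in the Fourier
#' domain): consecutive frames share nearly identical content, so the
#' incremental displacement is unambiguous even while different cells
#' blink on and off; the per-frame trajectory is the cumulative sum of
#' the increments, referenced to the first frame.
#'
#' @param movie A `calcium_movie` or a numeric array `ny x nx x n_frames`.
#' @param max_step Largest frame-to-frame displacement searched, pixels.
#' @return List with `frames` (aligned array) and `shifts` (integer
#'   matrix `n_frames x 2` of applied (dy, dx) corrections; the recovered
#'   drift relative to frame 1 is `-shifts`).
#' @export
rigid_align <- function(movie, max_step = 5L) {
  frames <- if (inherits(movie, "calcium_movie")) movie$frames else movie
  if (!is.array(frames) || length(dim(frames)) != 3L || dim(frames)[3] < 2L)
    stop("need a movie with at least 2 frames")
  n <- dim(frames)[3]
  steps <- matrix(0L, n, 2L)
  Fprev <- stats::fft(frames[, , 1])
  for (t in 2:n) {
    Fcur <- stats::fft(frames[, , t])
    steps[t, ] <- .xcorr_peak(Fcur, Fprev, max_step)
    Fprev <- Fcur
  }
  traj <- apply(steps, 2, cumsum)
  shifts <- -traj
  out <- frames
  for (t in seq_len(n))
    if (any(shifts[t, ] != 0L))
      out[, , t] <- .shift_frame(frames[, , t], shifts[t, 1], shifts[t, 2],
                                 fill = stats::median(frames[, , t]))
  list(frames = out, shifts = shifts)
}

# Displacement (dy, dx) of `frame` relative to `ref` from the circular
# cross-correlation peak, restricted to |shift| <= max_shift.
.xcorr_peak <- function(Ff, Fr, max_shift) {
  cc <- Re(stats::fft(Ff * Conj(Fr), inverse = TRUE))
  ny <- nrow(cc); nx <- ncol(cc)
  wrap <- function(idx, n) ifelse(idx - 1 <= n / 2, idx - 1, idx - 1 - n)
  dy <- wrap(seq_len(ny), ny); dx <- wrap(seq_len(nx), nx)
  ok <- outer(abs(dy) <= max_shift, abs(dx) <= max_shift)
  cc[!ok] <- -Inf
  p <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  c(dy[p[1]], dx[p[2]])
}

#' Local cross-correlation image
#'
#' Computes, per pixel, the sum over time of the pixel's fluorescence
#' multiplied by the difference-of-Gaussians (DoG) weighted average of its
#' neighborhood: `LocalX(x, y) = sum_t F(x,y,t) * [F(.,.,t) (*) DoG](x,y)`.
#' The center Gaussian (sigma 3 um by default) rewards correlation with
#' the immediate, cell-body-sized neighborhood; the surround Gaussian
#' (sigma 20 um) penalizes correlation with the neuropil. Both Gaussians
#' are integral-normalized before subtraction, so the DoG kernel sums to
#' zero and uniform background cancels. Convolution is circular.
#'
#' @param movie A `calcium_movie` or numeric array `ny x nx x n_frames`
#'   (already motion-corrected).
#' @param pixel_um Pixel size, um (taken from the movie if available).
#' @param center_sigma_um,surround_sigma_um DoG widths, um.
#' @return Object of class `localx_image`: list with `values` (matrix),
#'   `pixel_um` and the DoG parameters.
#' @export
local_crosscorr_image <- function(movie, pixel_um = NULL,
                                  center_sigma_um = 3,
                                  surround_sigma_um = 20) {
  frames <- if (inherits(movie, "calcium_movie")) movie$frames else movie
  if (is.null(pixel_um))
    pixel_um <- if (inherits(movie, "calcium_movie")) movie$pixel_um else
      stop("'pixel_um' must be given for a bare array")
  if (!is.array(frames) || length(dim(frames)) != 3L || dim(frames)[3] < 2L)
    stop("need a movie with at least 2 frames")
  ny <- dim(frames)[1]; nx <- dim(frames)[2]
  dog <- .dog_kernel(ny, nx, center_sigma_um / pixel_um,
                     surround_sigma_um / pixel_um)
  Fd <- stats::fft(dog)
  acc <- matrix(0, ny, nx)
  for (t in seq_len(dim(frames)[3])) {
    fr <- frames[, , t]
    sm <- Re(stats::fft(stats::fft(fr) * Fd, inverse = TRUE)) / (ny * nx)
    acc <- acc + fr * sm
  }
  structure(list(values = acc, pixel_um = pixel_um,
                 center_sigma_um = center_sigma_um,
                 surround_sigma_um = surround_sigma_um),
            class = "localx_image")
}

# DoG kernel laid out for FFT convolution (origin at element [1,1]),
# each Gaussian normalized to unit integral.
.dog_kernel <- function(ny, nx, s1_px, s2_px) {
  wrap <- function(n) {
    d <- seq_len(n) - 1
    pmin(d, n - d)
  }
  dy2 <- wrap(ny)^2; dx2 <- wrap(nx)^2
  r2 <- outer(dy2, dx2, `+`)
  g1 <- exp(-r2 / (2 * s1_px^2)); g1 <- g1 / sum(g1)
  g2 <- exp(-r2 / (2 * s2_px^2)); g2 <- g2 / sum(g2)
  g1 - g2
}

#' Automated cell detection on a local cross-correlation image
#'
#' Deterministic stand-in for manual point-and-click selection: local
#' maxima of the standardized LocalX image above a global threshold seed
#' region growing, and each ROI is the connected set of unclaimed pixels
#' exceeding a fixed fraction of its seed value (the local-threshold
#' rule). ROIs are non-overlapping; seeds are visited in decreasing
#' brightness.
#'
#' @param localx A [local_crosscorr_image()] result.
#' @param threshold_z Global seed threshold in robust z units.
#' @param local_frac Local threshold as a fraction of the seed value.
#' @param min_px,max_px Area bounds (pixels) for an accepted ROI.
#' @return List of ROIs, each a list with `pixels` (linear indices into
#'   the image), `centroid_um` (x, y) and `size`.
#' @export
segment_cells <- function(localx, threshold_z = 3, local_frac = 0.5,
                          min_px = 4L, max_px = 400L) {
  stopifnot(inherits(localx, "localx_image"))
  v <- localx$values
  if (any(!is.finite(v))) stop("LocalX image must be finite")
  scale <- stats::mad(v)
  if (scale == 0) scale <- stats::sd(v)
  if (is.na(scale) || scale == 0) return(list())
  z <- (v - stats::median(v)) / scale
  ny <- nrow(v); nx <- ncol(v)

  # 3x3 local maxima above the global threshold.
  is_max <- z >= threshold_z
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    shifted <- .shift_frame(z, dy, dx, fill = -Inf)
    is_max <- is_max & (z >= shifted)
  }
  seeds <- which(is_max)
  seeds <- seeds[order(v[seeds], decreasing = TRUE)]

  claimed <- matrix(FALSE, ny, nx)
  rois <- list()
  for (s in seeds) {
    if (claimed[s]) next
    thr <- local_frac * v[s]
    region <- .grow_region(v, s, thr, claimed, max_px)
    if (length(region) < min_px || length(region) > max_px) next
    claimed[region] <- TRUE
    rc <- arrayInd(region, c(ny, nx))
    w <- pmax(v[region], 0)
    if (sum(w) == 0) w <- rep(1, length(region))
    rois[[length(rois) + 1L]] <- list(
      pixels = region,
      centroid_um = c(x = sum((rc[, 2] - 1) * w) / sum(w) * localx$pixel_um,
                      y = sum((rc[, 1] - 1) * w) / sum(w) * localx$pixel_um),
      size = length(region))
  }
  rois
}

# 4-connected flood fill from `seed` over pixels with v >= thr that are
# not yet claimed, capped at max_px + 1 pixels.
.grow_region <- function(v, seed, thr, claimed, max_px) {
  ny <- nrow(v); nx <- ncol(v)
  visited <- claimed
  queue <- seed
  visited[seed] <- TRUE
  region <- integer(0)
  while (length(queue) && length(region) <= max_px) {
    p <- queue[1]; queue <- queue[-1]
    if (v[p] < thr) next
    region <- c(region, p)
    r <- ((p - 1) %% ny) + 1; cc <- ((p - 1) %/% ny) + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; c2 <- cc + d[2]
      if (rr < 1 || rr > ny || c2 < 1 || c2 > nx) next
      q <- (c2 - 1) * ny + rr
      if (!visited[q]) {
        visited[q] <- TRUE
        queue <- c(queue, q)
      }
    }
  }
  region
}

#' Extract ROI-averaged traces
#'
#' @param movie A `calcium_movie` or numeric array.
#' @param rois List of ROIs from [segment_cells()], or a labeled mask
#'   matrix (0 = background) such as `movie$masks`.
#' @return Matrix `n_frames x n_rois`.
#' @export
extract_traces <- function(movie, rois) {
  frames <- if (inherits(movie, "calcium_movie")) movie$frames else movie
  if (is.matrix(rois)) {
    labels <- sort(unique(rois[rois > 0]))
    rois <- lapply(labels, function(l) list(pixels = which(rois == l)))
  }
  n <- dim(frames)[3]
  npx <- prod(dim(frames)[1:2])
  flat <- matrix(frames, npx, n)
  vapply(rois, function(r) colMeans(flat[r$pixels, , drop = FALSE]),
         numeric(n))
}

#' Double notch filter for physiological artifacts
#'
#' Searches for up to two resonant spectral peaks, within a configurable
#' frequency band, that stand more than 3 robust SDs above the noise at
#' nearby frequencies, and suppresses them by zero-phase spectral
#' interpolation: the magnitude at the peak bins (and their conjugate
#' mirrors) is pulled down to the local noise floor while the phase is
#' retained. Peak detection runs on a segment-averaged (Welch) power
#' spectrum, whose reduced estimator variance makes the 3-SD criterion
#' selective: a plain noise trace passes unchanged, which also makes the
#' filter idempotent.
#'
#' @param trace Numeric vector, at least 64 samples.
#' @param fs Sampling rate, Hz.
#' @param band Search band `c(lo, hi)` in Hz; must lie below Nyquist.
#' @param z_thresh Peak threshold in robust SDs above the local median.
#' @param n_notch Maximum number of peaks removed.
#' @param halfwidth_bins Notch half-width in full-resolution bins.
#' @return Filtered trace, with attribute `notch_freqs` listing the
#'   removed frequencies (Hz), possibly empty.
#' @export
notch_filter_trace <- function(trace, fs = 15, band = c(0.2, 3),
                               z_thresh = 3, n_notch = 2L,
                               halfwidth_bins = 1L) {
  n <- length(trace)
  if (n < 64L) stop("trace must have at least 64 samples")
  if (band[2] >= fs / 2 || band[1] <= 0 || band[1] >= band[2])
    stop("search band must lie strictly inside (0, Nyquist)")
  mu <- mean(trace)
  x <- trace - mu

  # Welch-averaged power spectrum for detection.
  nseg <- min(64L, 2^floor(log2(n / 4)))
  hop <- nseg %/% 2L
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  starts <- seq(1L, n - nseg + 1L, by = hop)
  P <- rep(0, nseg %/% 2L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * win
    P <- P + Mod(stats::fft(seg))[2:(nseg %/% 2L + 1L)]^2
  }
  P <- P / length(starts)
  wfreq <- (1:(nseg %/% 2L)) * fs / nseg

  in_band <- which(wfreq >= band[1] & wfreq <= band[2])
  if (!length(in_band)) return(structure(trace, notch_freqs = numeric(0)))
  w <- 8L
  local_med <- vapply(in_band, function(k) {
    nb <- setdiff(max(1L, k - w):min(length(P), k + w), k)
    stats::median(P[nb])
  }, numeric(1))
  local_sd <- vapply(in_band, function(k) {
    nb <- setdiff(max(1L, k - w):min(length(P), k + w), k)
    stats::mad(P[nb])
  }, numeric(1))
  local_sd[local_sd == 0] <- Inf
  z <- (P[in_band] - local_med) / local_sd
  # A resonant peak must both stand z_thresh robust SDs above the nearby
  # noise and rise at least 4 dB above the local floor; the prominence
  # gate keeps chi-squared fluctuations of a featureless spectrum from
  # triggering spurious notches.
  prominent <- P[in_band] > 2.5 * local_med

  ord <- order(z, decreasing = TRUE)
  picked <- integer(0)
  for (j in ord) {
    if (length(picked) >= n_notch) break
    if (z[j] <= z_thresh) break
    if (!prominent[j]) next
    if (length(picked) && any(abs(in_band[j] - in_band[picked]) <= 2L))
      next
    picked <- c(picked, j)
  }
  if (!length(picked)) return(structure(trace, notch_freqs = numeric(0)))

  # Notch at full resolution: locate the exact peak bin near each
  # detected frequency and pull its magnitude down to the local floor.
  X <- stats::fft(x)
  half <- floor(n / 2)
  freqs <- (1:half) * fs / n
  removed <- numeric(0)
  for (j in picked) {
    f0 <- wfreq[in_band[j]]
    cand <- which(abs(freqs - f0) <= fs / nseg)
    if (!length(cand)) next
    k <- cand[which.max(Mod(X[cand + 1L]))]
    nb <- setdiff(max(1L, k - 8L):min(half, k + 8L),
                  (k - halfwidth_bins):(k + halfwidth_bins))
    floor_amp <- stats::median(Mod(X[nb + 1L]))
    for (b in max(1L, k - halfwidth_bins):min(half, k + halfwidth_bins)) {
      a <- Mod(X[b + 1L])
      if (a > floor_amp) {
        X[b + 1L] <- X[b + 1L] * (floor_amp / a)
        X[n - b + 1L] <- Conj(X[b + 1L])
      }
    }
    removed <- c(removed, freqs[k])
  }
  out <- Re(stats::fft(X, inverse = TRUE)) / n + mu
  structure(out, notch_freqs = removed)
}

#' Z-score a trace within a trial
#'
#' Standardizes a single-trial trace to mean 0, SD 1, which absorbs slow
#' changes in depth or overall fluorescence between trials. A
#' zero-variance trace cannot be standardized and raises a condition of
#' class `poolsi_zero_variance`, which callers use to exclude the cell.
#'
#' @param trace Numeric vector.
#' @return Standardized trace.
#' @export
zscore_trial <- function(trace) {
  s <- stats::sd(trace)
  if (!is.finite(s) || s == 0)
    stop(structure(class = c("poolsi_zero_variance", "error", "condition"),
                   list(message = "zero-variance trace: cell excluded",
                        call = sys.call(-1))))
  (trace - mean(trace)) / s
}

#' Stimulus-triggered average
#'
#' Averages trace segments following every presentation of each stimulus
#' condition, for `window_s` seconds after onset, producing the response
#' kernel `R[condition axes..., t]`.
#'
#' @param traces Numeric vector (one cell) or matrix `n_frames x n_cells`.
#' @param log A [make_stimulus_sequence()] log (needs `onset_frame`,
#'   `cond` and the condition axes).
#' @param ensemble The stimulus ensemble that generated the log.
#' @param window_s Averaging window, seconds.
#' @param fs Frame rate, Hz.
#' @return A [response_kernel()] (or list of them for matrix input) whose
#'   `counts` records presentations per condition; conditions never shown
#'   are `NA` and listed in attribute `missing_conds`.
#' @export
stimulus_triggered_average <- function(traces, log, ensemble,
                                       window_s = 1, fs = 15) {
  if (is.vector(traces)) traces <- matrix(traces, ncol = 1L)
  n_frames <- nrow(traces)
  L <- round(window_s * fs)
  kind <- attr(ensemble, "kind")
  axes <- switch(kind, grating = c("ori", "sf", "phase"),
                 bar = c("ori", "pos", "lum"),
                 stop("unknown ensemble kind"))
  coords <- lapply(axes, function(a) sort(unique(ensemble[[a]])))
  names(coords) <- axes
  dims <- vapply(coords, length, integer(1))

  usable <- log$onset_frame + L - 1L <= n_frames
  onsets_by_cond <- split(log$onset_frame[usable], log$cond[usable])

  # Map ensemble condition ids onto array positions.
  pos_of_cond <- vapply(seq_len(nrow(ensemble)), function(r) {
    sub <- vapply(seq_along(axes), function(i)
      match(ensemble[[axes[i]]][r], coords[[i]]), integer(1))
    as.integer(sum((sub - 1L) * cumprod(c(1L, dims[-length(dims)]))) + 1L)
  }, integer(1))

  counts <- array(0L, dims)
  kernels <- vector("list", ncol(traces))
  flat <- vector("list", ncol(traces))
  for (c_i in seq_len(ncol(traces)))
    flat[[c_i]] <- matrix(NA_real_, prod(dims), L)

  for (cond_chr in names(onsets_by_cond)) {
    cond <- as.integer(cond_chr)
    on <- onsets_by_cond[[cond_chr]]
    p <- pos_of_cond[cond]
    counts[p] <- length(on)
    seg_idx <- outer(on, 0:(L - 1L), `+`)
    for (c_i in seq_len(ncol(traces))) {
      seg <- matrix(traces[seg_idx, c_i], nrow = length(on))
      flat[[c_i]][p, ] <- colMeans(seg)
    }
  }
  missing <- which(counts == 0L)
  for (c_i in seq_len(ncol(traces))) {
    arr <- array(flat[[c_i]], c(dims, L))
    k <- response_kernel(arr, coords, kind, fs, counts = counts)
    attr(k, "missing_conds") <- missing
    attr(k, "center_deg") <- attr(ensemble, "center_deg")
    kernels[[c_i]] <- k
  }
  if (length(kernels) == 1L) kernels[[1L]] else kernels
}
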