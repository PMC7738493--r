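#' Response-kernel container
#'
#' Stimulus-triggered average response arrays. For gratings the kernel is
#' `R[ori, sf, phase, t]`; for bars it is `R[ori, pos, lum, t]`. The
#' condition coordinates, stimulus kind and frame rate travel with the
#' array.
#'
#' @param data Numeric array of responses.
#' @param coords Named list of coordinate vectors matching `dim(data)`
#'   minus the trailing time axis.
#' @param kind `"grating"` or `"bar"`.
#' @param fs Frame rate, Hz.
#' @param counts Optional array of per-condition presentation counts.
#' @return An object of class `response_kernel`.
#' @export
response_kernel <- function(data, coords, kind, fs = 15, counts = NULL) {
  stopifnot(is.array(data), length(dim(data)) == length(coords) + 1L)
  for (i in seq_along(coords))
    stopifnot(dim(data)[i] == length(coords[[i]]))
  structure(list(data = data, coords = coords, kind = kind, fs = fs,
                 counts = counts),
            class = "response_kernel")
}

#' @export
print.response_kernel <- function(x, ...) {
  cat(sprintf("<response_kernel: %s, %s, %g Hz>\n", x$kind,
              paste(dim(x$data), collapse = " x "), x$fs))
  invisible(x)
}

# Phase tuning curve with a prescribed F1/F0 as measured by the
# fixed-period sine fit on the given phase grid. The curve is a half-wave
# rectified cosine at offset phi0 plus a baseline chosen so that the
# sine-fit F1/F0 equals `ratio` (exact whenever the required baseline is
# nonnegative; near the rectifier ceiling the baseline clips at zero and
# the measured ratio saturates at the grid's rectifier value).
.phase_curve <- function(phases_deg, phi0_deg, ratio) {
  if (ratio <= 1e-8) return(rep(1, length(phases_deg)))
  rect <- pmax(0, cos((phases_deg - phi0_deg) * pi / 180))
  sf <- .sine_fit(phases_deg, rect)
  baseline <- max(0, sf$F1 / ratio - mean(rect))
  y <- rect + baseline
  y / mean(y)
}

# Grating response amplitude for every ensemble condition.
.grating_amp <- function(neuron, ensemble, amp = 1) {
  ori_g <- .gauss(.wrap_ori_diff(ensemble$ori, neuron$ori), 0,
                  neuron$sigma_theta)
  sf_g <- .gauss(ensemble$sf, neuron$fo, neuron$sigma_f)
  phases <- sort(unique(ensemble$phase))
  pc <- .phase_curve(phases, neuron$phase, neuron$f1f0)
  phase_g <- pc[match(ensemble$phase, phases)]
  amp * ori_g * sf_g * phase_g
}

#' Simulate a grating response kernel
#'
#' Generates the stimulus-triggered average kernel `R[ori, sf, phase, t]`
#' a noiseless pipeline would recover for a neuron of the given tuning:
#' a separable orientation (wrapped Gaussian) x SF (Gaussian) x phase
#' (rectified sinusoid with matched F1/F0) amplitude profile, multiplied
#' by the calcium impulse response, plus additive Gaussian noise.
#'
#' @param neuron One row of a [sample_population()] table (or any list
#'   with fields `fo`, `sigma_f`, `sigma_theta`, `f1f0`, `ori`, `phase`).
#' @param ensemble A [grating_ensemble()].
#' @param noise_sd Additive Gaussian noise SD (response units; the
#'   noiseless peak response is 1).
#' @param fs Frame rate, Hz; `window_s` kernel duration, seconds.
#' @param rise_s,decay_s Calcium impulse-response time constants, seconds.
#' @param seed Integer seed for the noise draw.
#' @return A [response_kernel()] of kind `"grating"`.
#' @export
simulate_grating_kernel <- function(neuron, ensemble = grating_ensemble(),
                                    noise_sd = 0.05, fs = 15, window_s = 1,
                                    rise_s = 0.05, decay_s = 0.4,
                                    seed = 1L) {
  stopifnot(attr(ensemble, "kind") == "grating")
  amp <- .grating_amp(neuron, ensemble)
  h <- .ca_impulse(fs, window_s, rise_s, decay_s)
  oris <- sort(unique(ensemble$ori)); sfs <- sort(unique(ensemble$sf))
  phases <- sort(unique(ensemble$phase))
  arr <- array(0, c(length(oris), length(sfs), length(phases), length(h)))
  io <- match(ensemble$ori, oris); is <- match(ensemble$sf, sfs)
  ip <- match(ensemble$phase, phases)
  for (r in seq_len(nrow(ensemble)))
    arr[io[r], is[r], ip[r], ] <- amp[r] * h
  if (noise_sd > 0) {
    rng <- .local_rng(seed)
    arr <- arr + noise_sd * array(rng$rnorm(length(arr)), dim(arr))
  }
  response_kernel(arr, list(ori = oris, sf = sfs, phase = phases),
                  "grating", fs)
}

# ON/OFF line-weighting profiles of the pooled RF along the probe axis at
# stimulus orientation `ori_s`, evaluated at positions `pos` (deg),
# including smearing by the finite bar width. Returns a 2-column matrix.
.bar_profile <- function(neuron, ori_s, pos, width_deg, aspect_ratio = 2,
                         fine_step = 0.02, center = c(0, 0)) {
  d <- .wrap_ori_diff(ori_s, neuron$ori) * pi / 180
  sx <- neuron$sigma_x
  sy <- aspect_ratio * sx
  s_proj <- sqrt(sx^2 * cos(d)^2 + sy^2 * sin(d)^2)
  # Orientation gain: bar responses are orientation tuned (energy-model
  # gain at the neuron's orientation bandwidth), unlike the bare line
  # integral of the envelope, whose total mass is orientation-invariant.
  ori_gain <- .gauss(d * 180 / pi, 0, neuron$sigma_theta)
  # RF center (relative to the stimulus center) projected onto the
  # bar-position axis (normal to the bar).
  u <- c(cos((ori_s + 90) * pi / 180), sin((ori_s + 90) * pi / 180))
  mu <- (neuron$rf_x - center[1]) * u[1] + (neuron$rf_y - center[2]) * u[2]
  # Carrier along the probe axis: frequency fo*cos(d), damped with
  # misalignment by the envelope length.
  damp <- exp(-(2 * pi * neuron$fo * sin(d))^2 * sy^2 / 2)
  w_s <- min(1, neuron$f1f0 / pi)  # linear (simple) weight
  xf <- seq(min(pos) - 3 * width_deg, max(pos) + 3 * width_deg,
            by = fine_step)
  env <- ori_gain * .gauss(xf, mu, s_proj) / s_proj
  carrier <- cos(2 * pi * neuron$fo * cos(d) * (xf - mu) +
                   neuron$phase * pi / 180)
  on <- env * (1 + w_s * damp * carrier) / 2
  off <- env * (1 - w_s * damp * carrier) / 2
  if (width_deg > 0) {
    nbox <- max(1L, round(width_deg / fine_step))
    box <- rep(1 / nbox, nbox)
    on <- stats::filter(on, box, sides = 2)
    off <- stats::filter(off, box, sides = 2)
  }
  cbind(on = stats::approx(xf, as.numeric(on), pos, rule = 2)$y,
        off = stats::approx(xf, as.numeric(off), pos, rule = 2)$y)
}

#' Simulate a bar response kernel
#'
#' Generates the stimulus-triggered average kernel `R[ori, pos, lum, t]`
#' for the flashed-bar ensemble. ON and OFF responses come from the
#' positive and negative lobes of the neuron's pooled RF: the envelope is
#' a 2D Gaussian (width `sigma_x`, length `aspect_ratio * sigma_x`) whose
#' projection onto the probe axis carries a phase-locked modulation
#' weighted by the neuron's phase selectivity (`f1f0/pi`), so complex
#' cells have overlapping ON/OFF envelopes and simple cells segregated
#' lobes. Profiles are smeared by the finite bar width (boxcar
#' convolution) before sampling at the stimulus positions.
#'
#' @inheritParams simulate_grating_kernel
#' @param ensemble A [bar_ensemble()].
#' @param aspect_ratio RF length/width used for the envelope.
#' @return A [response_kernel()] of kind `"bar"`.
#' @export
simulate_bar_kernel <- function(neuron, ensemble = bar_ensemble(),
                                noise_sd = 0.05, fs = 15, window_s = 1,
                                rise_s = 0.05, decay_s = 0.4,
                                aspect_ratio = 2, seed = 1L) {
  stopifnot(attr(ensemble, "kind") == "bar")
  oris <- sort(unique(ensemble$ori))
  pos <- sort(unique(ensemble$pos))
  width <- attr(ensemble, "width_deg")
  h <- .ca_impulse(fs, window_s, rise_s, decay_s)
  center <- attr(ensemble, "center_deg")
  if (is.null(center)) center <- c(0, 0)
  arr <- array(0, c(length(oris), length(pos), 2L, length(h)))
  for (i in seq_along(oris)) {
    prof <- .bar_profile(neuron, oris[i], pos, width, aspect_ratio,
                         center = center)
    for (j in seq_along(pos)) {
      arr[i, j, 1L, ] <- prof[j, "on"] * h
      arr[i, j, 2L, ] <- prof[j, "off"] * h
    }
  }
  # Scale so the peak noiseless response is 1.
  pk <- max(arr)
  if (pk > 0) arr <- arr / pk
  if (noise_sd > 0) {
    rng <- .local_rng(seed)
    arr <- arr + noise_sd * array(rng$rnorm(length(arr)), dim(arr))
  }
  k <- response_kernel(arr, list(ori = oris, pos = pos,
                                 lum = c("on", "off")), "bar", fs)
  attr(k, "center_deg") <- center
  k
}

#' Simulate a fluorescence time course from a stimulus sequence
#'
#' Builds the noiseless fluorescence trace of a neuron responding to a
#' presentation sequence: each presentation contributes its condition's
#' response amplitude convolved with the calcium impulse response.
#'
#' @param neuron One row of a [sample_population()] table.
#' @param log A [make_stimulus_sequence()] log over a grating ensemble.
#' @param ensemble The [grating_ensemble()] used for the log.
#' @param n_frames Trace length in frames.
#' @param fs Frame rate, Hz.
#' @param rise_s,decay_s Calcium impulse-response time constants.
#' @return Numeric vector of length `n_frames`.
#' @export
simulate_response_trace <- function(neuron, log, ensemble, n_frames,
                                    fs = 15, rise_s = 0.05, decay_s = 0.4) {
  amp <- .grating_amp(neuron, ensemble)
  h <- .ca_impulse(fs, 1, rise_s, decay_s)
  trace <- rep(0, n_frames + length(h))
  for (r in seq_len(nrow(log))) {
    f0 <- log$onset_frame[r]
    if (f0 > n_frames) next
    idx <- f0:(f0 + length(h) - 1L)
    trace[idx] <- trace[idx] + amp[log$cond[r]] * h
  }
  trace[seq_len(n_frames)]
}

#' Apply an accelerating fluorescence nonlinearity
#'
#' Pointwise power law on a nonnegative trace, modelling the accelerating
#' relation between calcium concentration and indicator fluorescence.
#' Exponent 1 is the identity.
#'
#' @param trace Numeric vector; must be nonnegative unless `exponent` is a
#'   whole number.
#' @param exponent Power-law exponent, >= 1.
#' @return The transformed trace.
#' @export
apply_fluorescence_nonlinearity <- function(trace, exponent = 1) {
  stopifnot(is.numeric(trace), is.numeric(exponent), length(exponent) == 1L)
  if (exponent < 1) stop("'exponent' must be >= 1")
  if (any(trace < 0) && exponent != round(exponent))
    stop("negative trace values require an integer 'exponent'")
  trace^exponent
}
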