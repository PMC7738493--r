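#' Generative pooling simulations
#'
#' Direct numerical simulations of the pooling construction: shifted,
#' Gaussian-weighted copies of a scale-invariant input are superposed and
#' the tuning of the superposition is measured from the resulting curve.
#' These simulations are independent of the closed-form predictions in
#' [tuning-models] and serve as their numerical oracles: as the center
#' grid is refined they converge to the variance-addition formulas.
#'
#' @name pooling-simulations
NULL

# Gaussian-weighted grid of pooling offsets spanning +/- span_sd SDs.
.pool_grid <- function(sigma, n_inputs, span_sd = 4) {
  if (!is.numeric(n_inputs) || n_inputs < 1)
    stop("'n_inputs' must be >= 1")
  n_inputs <- as.integer(n_inputs)
  if (sigma == 0 || n_inputs == 1L)
    return(list(centers = 0, weights = 1))
  centers <- seq(-span_sd * sigma, span_sd * sigma, length.out = n_inputs)
  w <- exp(-centers^2 / (2 * sigma^2))
  list(centers = centers, weights = w / sum(w))
}

# 1-sigma width of a sampled nonnegative profile, by second moment.
.moment_width <- function(x, y) {
  y <- pmax(y, 0)
  s <- sum(y)
  if (s <= 0) stop("degenerate profile: all mass zero")
  mu <- sum(x * y) / s
  sqrt(sum((x - mu)^2 * y) / s)
}

#' @describeIn pooling-simulations Superpose shifted scale-invariant RF
#'   envelopes (Gaussians of width `si_rf_width(fo)`, or `input_width` if
#'   given) under a Gaussian pooling window of width `pool$sigma_hx`, and
#'   return the 1-sigma width of the pooled envelope measured by its second
#'   moment. Converges to [pooled_rf_width()] as `n_inputs` grows and
#'   `step` shrinks.
#'
#' @param fo Preferred spatial frequency, cyc/deg (> 0).
#' @param pool [pooling_params()] object.
#' @param si [si_params()] object.
#' @param n_inputs Number of pooled inputs on the center grid (>= 1).
#' @param step Spatial sampling step, degrees (> 0).
#' @param input_width Optional input envelope width (degrees) overriding
#'   the scale-invariant width; used e.g. to check plain Gaussian
#'   convolution identities.
#' @return `simulate_spatial_pooling`: pooled envelope width, degrees.
#' @export
simulate_spatial_pooling <- function(fo, pool, si = si_params(),
                                     n_inputs = 201L, step = 0.01,
                                     input_width = NULL) {
  if (!is.numeric(step) || step <= 0) stop("degenerate grid: 'step' must be > 0")
  sx <- if (is.null(input_width)) si_rf_width(fo, si) else input_width
  if (sx <= 0) stop("input width must be > 0")
  g <- .pool_grid(pool$sigma_hx, n_inputs)
  half <- 5 * (sx + pool$sigma_hx)
  x <- seq(-half, half, by = step)
  prof <- rep(0, length(x))
  for (k in seq_along(g$centers))
    prof <- prof + g$weights[k] * exp(-(x - g$centers[k])^2 / (2 * sx^2))
  .moment_width(x, prof)
}

#' @describeIn pooling-simulations Sum half-wave-rectified, phase-shifted,
#'   Gaussian-weighted scale-invariant inputs and measure F1/F0 of the
#'   summed phase tuning curve (F1 = peak-to-peak of the fundamental, F0 =
#'   mean). `phase_mode = "relative"` advances absolute phase at the full
#'   retinotopic rate (D = 1), `"absolute"` keeps absolute phase constant
#'   (D = 0), `"D"` uses `pool$D`. Matches [pooled_f1f0()] with the
#'   corresponding D in the dense-grid limit.
#'
#' @param phase_mode One of `"D"`, `"relative"`, `"absolute"`.
#' @param n_phases Number of stimulus phase samples over 360 degrees.
#' @return `simulate_phase_pooling`: F1/F0, dimensionless in (0, pi].
#' @export
simulate_phase_pooling <- function(fo, pool,
                                   phase_mode = c("D", "relative", "absolute"),
                                   n_inputs = 201L, n_phases = 720L) {
  .check_fo(fo)
  phase_mode <- match.arg(phase_mode)
  D <- switch(phase_mode, D = pool$D, relative = 1, absolute = 0)
  g <- .pool_grid(pool$sigma_hx, n_inputs)
  phi <- seq(0, 2 * pi, length.out = n_phases + 1L)[-(n_phases + 1L)]
  theta <- D * 2 * pi * fo * g$centers  # carrier phase offset per input
  r <- rep(0, n_phases)
  for (k in seq_along(theta))
    r <- r + g$weights[k] * pmax(0, cos(phi - theta[k]))
  f0 <- mean(r)
  c1 <- mean(r * exp(-1i * phi))
  f1 <- 4 * Mod(c1)  # peak-to-peak of the fundamental
  f1 / f0
}

# 1D superposition of shifted Gaussians of width sigma_in under Gaussian
# weighting of width sigma_pool, measured by second moment.
.superpose_1d <- function(sigma_in, sigma_pool, n_inputs, n_grid = 1001L) {
  g <- .pool_grid(sigma_pool, n_inputs)
  half <- 5 * (sigma_in + sigma_pool)
  x <- seq(-half, half, length.out = n_grid)
  prof <- rep(0, length(x))
  for (k in seq_along(g$centers))
    prof <- prof + g$weights[k] * exp(-(x - g$centers[k])^2 / (2 * sigma_in^2))
  .moment_width(x, prof)
}

#' @describeIn pooling-simulations Superpose shifted copies of the 2D
#'   scale-invariant spectral Gaussian at `fo` (radial width
#'   `si_sf_bandwidth(fo)`, tangential width `si_sf_bandwidth(fo)/A`)
#'   under an isotropic 2D Gaussian pooling window of width
#'   `pool$sigma_hf`, and measure the radial width (SF bandwidth, cyc/deg)
#'   and the orientation bandwidth `atan(tangential width / fo)` (degrees)
#'   of the superposition. Converges to [pooled_sf_bandwidth()] and
#'   [pooled_ori_bandwidth()].
#'
#' @return `simulate_spectral_pooling`: list with elements `sf_bw`
#'   (cyc/deg) and `ori_bw` (degrees).
#' @export
simulate_spectral_pooling <- function(fo, pool, si = si_params(),
                                      n_inputs = 201L, n_grid = 2001L) {
  .check_fo(fo)
  s_rad <- si_sf_bandwidth(fo, si)
  s_tan <- s_rad / si$aspect_ratio
  if (s_rad <= 0) stop("input spectral width must be > 0")
  # The offset grid and weights factorize (isotropic Gaussian window on a
  # product grid), so the superposed 2D energy is separable and the radial
  # and tangential widths can each be measured from a 1D superposition.
  sf_sigma <- .superpose_1d(s_rad, pool$sigma_hf, n_inputs, n_grid)
  tan_sigma <- .superpose_1d(s_tan, pool$sigma_hf, n_inputs, n_grid)
  list(sf_bw = sf_sigma, ori_bw = atan(tan_sigma / fo) * 180 / pi)
}
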