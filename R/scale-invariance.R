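#' Scale-invariant and pooled tuning predictions
#'
#' Closed-form predictions of classical V1 tuning parameters from the
#' preferred spatial frequency `fo` (cyc/deg), under two nested models.
#'
#' Under *scale invariance* the Gabor RF keeps its shape as it scales:
#' \describe{
#'   \item{`si_rf_width()`}{RF envelope width (1 sigma, degrees),
#'     `1 / (alpha * fo)`.}
#'   \item{`si_sf_bandwidth()`}{linear SF bandwidth (1 sigma, cyc/deg),
#'     `alpha * fo / (2*pi)`; with `alpha = pi` this is `fo / 2`.}
#'   \item{`si_log_bandwidth()`}{log SF bandwidth (octaves),
#'     `log2(1 + alpha/(2*pi))`, constant in `fo`.}
#'   \item{`si_ori_bandwidth()`}{orientation bandwidth (degrees),
#'     `atan(alpha / (2*pi*A))`, constant in `fo` (about 14 deg at the
#'     defaults).}
#' }
#'
#' Under *pooled scale invariance* the measured RF is the superposition of
#' scale-invariant inputs drawn through a Gaussian pooling window, so the
#' pooling variance adds to the scale-invariant variance:
#' \describe{
#'   \item{`pooled_rf_width()`}{`sqrt(si_rf_width(fo)^2 + sigma_hx^2)`.}
#'   \item{`pooled_sf_bandwidth()`}{`sqrt(si_sf_bandwidth(fo)^2 + sigma_hf^2)`.}
#'   \item{`pooled_log_bandwidth()`}{`log2((fo + pooled_sf_bandwidth(fo))/fo)`.}
#'   \item{`pooled_ori_bandwidth()`}{`atan(sqrt(si_sf_bandwidth(fo)^2/A^2 +
#'     sigma_hf^2) / fo)` in degrees; it reuses the spectral pooling width
#'     fitted from SF bandwidth with no extra free parameter.}
#'   \item{`pooled_f1f0()`}{phase selectivity,
#'     `pi * exp(-(sigma_hx * 2*pi * fo * D)^2 / 2)`, a Gaussian in `fo`
#'     with SD `1/(sigma_hx * 2*pi * D)` (see [f1f0_gaussian_sd()]).}
#' }
#'
#' All functions are vectorized over `fo`. Angles are returned in degrees.
#'
#' @param fo Preferred spatial frequency, cyc/deg. Must be > 0 (except
#'   `pooled_f1f0()`, which accepts 0).
#' @param si [si_params()] object.
#' @param pool [pooling_params()] object.
#' @return Numeric vector, same length as `fo`.
#' @name tuning-models
NULL

.check_fo <- function(fo, allow_zero = FALSE) {
  if (!is.numeric(fo) || any(!is.finite(fo)))
    stop("'fo' must be finite numeric")
  if (allow_zero) {
    if (any(fo < 0)) stop("'fo' must be >= 0")
  } else if (any(fo <= 0)) stop("'fo' must be > 0")
  invisible(fo)
}

#' @rdname tuning-models
#' @export
si_rf_width <- function(fo, si = si_params()) {
  .check_fo(fo)
  1 / (si$alpha * fo)
}

#' @rdname tuning-models
#' @export
si_sf_bandwidth <- function(fo, si = si_params()) {
  .check_fo(fo, allow_zero = TRUE)
  si$alpha * fo / (2 * pi)
}

#' @rdname tuning-models
#' @export
si_log_bandwidth <- function(fo, si = si_params()) {
  .check_fo(fo)
  rep(log2(1 + si$alpha / (2 * pi)), length(fo))
}

#' @rdname tuning-models
#' @export
si_ori_bandwidth <- function(si = si_params()) {
  atan(si$alpha / (2 * pi * si$aspect_ratio)) * 180 / pi
}

#' @rdname tuning-models
#' @export
pooled_rf_width <- function(fo, si = si_params(), pool = pooling_params()) {
  .check_fo(fo)
  sqrt(si_rf_width(fo, si)^2 + pool$sigma_hx^2)
}

#' @rdname tuning-models
#' @export
pooled_f1f0 <- function(fo, pool = pooling_params()) {
  .check_fo(fo, allow_zero = TRUE)
  pi * exp(-(pool$sigma_hx * 2 * pi * fo * pool$D)^2 / 2)
}

#' @rdname tuning-models
#' @export
pooled_sf_bandwidth <- function(fo, si = si_params(), pool = pooling_params()) {
  .check_fo(fo)
  sqrt(si_sf_bandwidth(fo, si)^2 + pool$sigma_hf^2)
}

#' @rdname tuning-models
#' @export
pooled_log_bandwidth <- function(fo, si = si_params(), pool = pooling_params()) {
  .check_fo(fo)
  log2((fo + pooled_sf_bandwidth(fo, si, pool)) / fo)
}

#' @rdname tuning-models
#' @export
pooled_ori_bandwidth <- function(fo, si = si_params(), pool = pooling_params()) {
  .check_fo(fo)
  atan(sqrt(si_sf_bandwidth(fo, si)^2 / si$aspect_ratio^2 + pool$sigma_hf^2) /
         fo) * 180 / pi
}

#' Width of the F1/F0 vs preferred-SF Gaussian
#'
#' The pooled model predicts phase selectivity F1/F0 as a Gaussian in
#' preferred SF; its standard deviation is `1 / (sigma_hx * 2*pi * D)`
#' cyc/deg. At `sigma_hx = 0.24` deg and `D = 1` this is about 0.66
#' cyc/deg.
#'
#' @param pool [pooling_params()] object with `sigma_hx > 0`.
#' @param D Optional override of the phase-progression rate (default the
#'   value stored in `pool`); the relative-phase case is `D = 1`.
#' @return SD in cyc/deg (`Inf` when `sigma_hx * D == 0`).
#' @export
f1f0_gaussian_sd <- function(pool, D = pool$D) {
  stopifnot(inherits(pool, "pooling_params"))
  if (pool$sigma_hx * D == 0) return(Inf)
  1 / (pool$sigma_hx * 2 * pi * D)
}
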