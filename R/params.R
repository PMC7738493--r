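#' Scale-invariance parameters
#'
#' Container for the two constants of the scale-invariant Gabor family:
#' the scaling coefficient `alpha` relating RF width to preferred spatial
#' frequency (sigma_x = 1/(alpha * f_o)), and the RF aspect ratio
#' (length/width) `aspect_ratio`. The defaults alpha = pi and
#' aspect_ratio = 2 correspond to the classical Gabor model with 2-3
#' ON/OFF subfields.
#'
#' @param alpha Dimensionless scaling coefficient, > 0. Default `pi`.
#' @param aspect_ratio Dimensionless RF length/width, > 0. Default 2.
#' @return An object of class `si_params`.
#' @examples
#' si_params()           # the defaults
#' si_params(alpha = 2)  # a looser scaling coefficient
#' @export
si_params <- function(alpha = pi, aspect_ratio = 2) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(aspect_ratio), length(aspect_ratio) == 1L,
            is.finite(aspect_ratio))
  if (alpha <= 0) stop("'alpha' must be > 0")
  if (aspect_ratio <= 0) stop("'aspect_ratio' must be > 0")
  structure(list(alpha = alpha, aspect_ratio = aspect_ratio),
            class = "si_params")
}

#' Pooling parameters
#'
#' Container for the three free parameters of the pooled-scale-invariance
#' model: the spatial pooling width `sigma_hx` (degrees of visual angle),
#' the spectral pooling width `sigma_hf` (cyc/deg), and the absolute
#' phase-progression rate `D` in \[0, 1\]. `D = 1` corresponds to constant
#' relative phase (absolute phase fully coupled to retinotopy), `D = 0` to
#' constant absolute phase.
#'
#' @param sigma_hx Spatial pooling width, degrees, >= 0.
#' @param sigma_hf Spectral pooling width, cyc/deg, >= 0.
#' @param D Phase-progression rate, dimensionless in \[0, 1\].
#' @return An object of class `pooling_params`.
#' @examples
#' pooling_params(sigma_hx = 0.24, sigma_hf = 0.85, D = 0.54)
#' @export
pooling_params <- function(sigma_hx = 0.24, sigma_hf = 0.85, D = 0.54) {
  stopifnot(is.numeric(sigma_hx), length(sigma_hx) == 1L, is.finite(sigma_hx),
            is.numeric(sigma_hf), length(sigma_hf) == 1L, is.finite(sigma_hf),
            is.numeric(D), length(D) == 1L, is.finite(D))
  if (sigma_hx < 0) stop("'sigma_hx' must be >= 0")
  if (sigma_hf < 0) stop("'sigma_hf' must be >= 0")
  if (D < 0 || D > 1) stop("'D' must lie in [0, 1]")
  structure(list(sigma_hx = sigma_hx, sigma_hf = sigma_hf, D = D),
            class = "pooling_params")
}

#' @export
print.si_params <- function(x, ...) {
  cat(sprintf("Scale-invariance parameters: alpha = %.4g, aspect ratio = %.4g\n",
              x$alpha, x$aspect_ratio))
  invisible(x)
}

#' @export
print.pooling_params <- function(x, ...) {
  cat(sprintf(
    "Pooling parameters: sigma_h(x) = %.4g deg, sigma_h(f) = %.4g cyc/deg, D = %.4g\n",
    x$sigma_hx, x$sigma_hf, x$D))
  invisible(x)
}

#' Serialize model parameters to JSON
#'
#' Writes (or returns) the combined scale-invariance and pooling parameters
#' as a flat JSON document with keys `alpha`, `aspect_ratio_A`,
#' `sigma_hx_deg`, `sigma_hf_cpd` and `D`.
#'
#' @param si `si_params` object.
#' @param pool `pooling_params` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
write_model_params <- function(si, pool, path = NULL) {
  stopifnot(inherits(si, "si_params"), inherits(pool, "pooling_params"))
  doc <- list(alpha = si$alpha, aspect_ratio_A = si$aspect_ratio,
              sigma_hx_deg = pool$sigma_hx, sigma_hf_cpd = pool$sigma_hf,
              D = pool$D)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Read model parameters from JSON
#'
#' Inverse of [write_model_params()].
#'
#' @param path Path to a JSON file written by [write_model_params()].
#' @return A list with elements `si` (`si_params`) and `pool`
#'   (`pooling_params`).
#' @export
read_model_params <- function(path) {
  doc <- jsonlite::fromJSON(path)
  list(si = si_params(alpha = doc$alpha, aspect_ratio = doc$aspect_ratio_A),
       pool = pooling_params(sigma_hx = doc$sigma_hx_deg,
                             sigma_hf = doc$sigma_hf_cpd, D = doc$D))
}
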