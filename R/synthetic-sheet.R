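#' Synthesize ground-truth cortical functional maps
#'
#' Builds a square-pixel cortical sheet carrying the four functional maps
#' the generator needs: preferred spatial frequency (periodic, log-normal
#' marginal), preferred orientation (pinwheel structure), retinotopy
#' (linear gradient set by the magnification factor) and absolute spatial
#' phase (advancing at `D` times the carrier rate along the retinotopic
#' gradient).
#'
#' The preferred-SF map is band-pass-filtered Gaussian noise, exponentiated
#' so that log2(fo) has the configured mean and SD; the dominant spatial
#' period of the map equals `fo_period_um`. The orientation map is the
#' half-angle of band-pass-filtered complex noise, which produces
#' pinwheels at the same spatial scale.
#'
#' @param nx,ny Grid size in pixels (each >= 64).
#' @param pixel_um Pixel size, micrometers.
#' @param fo_period_um Dominant spatial period of the preferred-SF map,
#'   micrometers (default 750).
#' @param fo_mean_log2,fo_sd_log2 Marginal mean and SD of log2(fo)
#'   (defaults 0.95 and 0.64, the calibration used throughout).
#' @param magnification Cortical magnification factor, mm/deg (default 2).
#' @param D Absolute phase-progression rate in \[0, 1\] (default 0.54).
#' @param band_rel_sd Relative width of the annular frequency band used
#'   for map synthesis (fraction of the pass frequency).
#' @param seed Integer seed; the sheet is bit-identical given the seed.
#' @return An object of class `cortical_sheet`: a list with matrices
#'   `fo_map` (cyc/deg), `ori_map` (deg, in \[0, 180)), `retinotopy_x`,
#'   `retinotopy_y` (deg), `phase_map` (deg, in \[0, 360)), plus
#'   `pixel_um`, `magnification` and the generating config.
#' @export
make_cortical_sheet <- function(nx = 160L, ny = 160L, pixel_um = 10,
                                fo_period_um = 750, fo_mean_log2 = 0.95,
                                fo_sd_log2 = 0.64, magnification = 2,
                                D = 0.54, band_rel_sd = 0.25, seed = 1L) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 64L || ny < 64L) stop("grid must be at least 64 x 64")
  stopifnot(pixel_um > 0, fo_period_um > 0, magnification > 0,
            fo_sd_log2 >= 0, D >= 0, D <= 1)
  if (fo_period_um <= 2 * pixel_um || fo_period_um >= max(nx, ny) * pixel_um)
    stop("'fo_period_um' is inconsistent with the grid: it must exceed two ",
         "pixels and fit inside the sheet")
  rng <- .local_rng(seed)

  # Annular Gaussian band in the 2D frequency plane, centered on the
  # configured map period.
  f_pass <- 1 / fo_period_um  # cycles per um
  fxv <- .fft_freq(nx, pixel_um)
  fyv <- .fft_freq(ny, pixel_um)
  rho <- sqrt(outer(fyv^2, fxv^2, `+`))
  band <- exp(-(rho - f_pass)^2 / (2 * (band_rel_sd * f_pass)^2))

  bp_real <- function() {
    noise <- matrix(rng$rnorm(nx * ny), ny, nx)
    Re(stats::fft(stats::fft(noise) * band, inverse = TRUE)) / (nx * ny)
  }

  z <- bp_real()
  z <- (z - mean(z)) / stats::sd(z)
  fo_map <- 2^(fo_mean_log2 + fo_sd_log2 * z)

  wre <- bp_real(); wim <- bp_real()
  ori_map <- (atan2(wim, wre) / 2) * 180 / pi  # in (-90, 90]
  ori_map <- (ori_map + 180) %% 180

  x_mm <- matrix(rep((seq_len(nx) - 1) * pixel_um / 1000, each = ny), ny, nx)
  y_mm <- matrix(rep((seq_len(ny) - 1) * pixel_um / 1000, nx), ny, nx)
  retinotopy_x <- x_mm / magnification
  retinotopy_y <- y_mm / magnification

  # Absolute phase advances at D * (2*pi*fo) per degree of retinotopic
  # shift, expressed here in degrees of phase.
  phase_map <- (D * 360 * fo_map * retinotopy_x) %% 360

  structure(list(fo_map = fo_map, ori_map = ori_map,
                 retinotopy_x = retinotopy_x, retinotopy_y = retinotopy_y,
                 phase_map = phase_map, pixel_um = pixel_um,
                 magnification = magnification,
                 config = list(nx = nx, ny = ny, fo_period_um = fo_period_um,
                               fo_mean_log2 = fo_mean_log2,
                               fo_sd_log2 = fo_sd_log2, D = D,
                               band_rel_sd = band_rel_sd, seed = seed)),
            class = "cortical_sheet")
}

.fft_freq <- function(n, step) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k / (n * step)
}

#' @export
print.cortical_sheet <- function(x, ...) {
  cat(sprintf(
    "Cortical sheet: %d x %d px @ %.3g um/px (%.2f x %.2f mm), %.3g mm/deg\n",
    x$config$nx, x$config$ny, x$pixel_um,
    x$config$nx * x$pixel_um / 1000, x$config$ny * x$pixel_um / 1000,
    x$magnification))
  cat(sprintf("  fo: median %.2f cyc/deg, SD-log2 %.2f; map period %.0f um\n",
              stats::median(x$fo_map), stats::sd(log2(x$fo_map)),
              x$config$fo_period_um))
  invisible(x)
}

#' Sample a neuron population from a cortical sheet
#'
#' Draws `n_cells` pixels from a [make_cortical_sheet()] sheet and assigns
#' each neuron its ground-truth tuning under pooled scale invariance: the
#' noiseless parameters are computed from the local preferred SF with the
#' closed-form model ([tuning-models]), and measured-parameter targets are
#' obtained by applying multiplicative log-normal scatter (SD
#' `scatter_sd` in natural log units) to the widths and additive truncated
#' Gaussian noise (SD `f1f0_noise_sd`, clipped to \[0, pi\]) to F1/F0.
#'
#' @param sheet A `cortical_sheet`.
#' @param pool [pooling_params()] ground truth for the population.
#' @param si [si_params()] object.
#' @param n_cells Number of neurons (>= 1).
#' @param scatter_sd Log-normal scatter SD on widths (0 = noiseless).
#' @param f1f0_noise_sd Truncated-Gaussian noise SD on F1/F0.
#' @param rf_jitter_deg Isotropic Gaussian jitter SD applied to RF centers
#'   (deg); 0 keeps centers exactly on the retinotopic gradient.
#' @param seed Integer seed.
#' @return A data.frame of class `neuron_population`, one row per neuron:
#'   cortical position (`x_um`, `y_um`), RF center (`rf_x`, `rf_y`, deg),
#'   `fo` (cyc/deg), preferred orientation `ori` and absolute phase
#'   `phase` (deg), scattered targets `sigma_x`, `sigma_f`, `sigma_logf`,
#'   `sigma_theta`, `f1f0`, their noiseless `*_true` counterparts, and a
#'   `lowpass` flag (all `FALSE`: the generator is band-pass by
#'   construction). Ground-truth parameters are attached as attributes.
#' @export
sample_population <- function(sheet, pool = pooling_params(),
                              si = si_params(), n_cells = 200L,
                              scatter_sd = 0.2, f1f0_noise_sd = 0.15,
                              rf_jitter_deg = 0, seed = 1L) {
  stopifnot(inherits(sheet, "cortical_sheet"), n_cells >= 1)
  rng <- .local_rng(seed)
  npx <- length(sheet$fo_map)
  idx <- rng$sample(npx, size = min(n_cells, npx), replace = n_cells > npx)
  rc <- arrayInd(idx, dim(sheet$fo_map))

  fo <- sheet$fo_map[idx]
  df <- data.frame(
    cell = seq_along(idx),
    x_um = (rc[, 2] - 1) * sheet$pixel_um,
    y_um = (rc[, 1] - 1) * sheet$pixel_um,
    rf_x = sheet$retinotopy_x[idx] + rf_jitter_deg * rng$rnorm(length(idx)),
    rf_y = sheet$retinotopy_y[idx] + rf_jitter_deg * rng$rnorm(length(idx)),
    fo = fo,
    ori = sheet$ori_map[idx],
    phase = sheet$phase_map[idx]
  )
  df$sigma_x_true <- pooled_rf_width(fo, si, pool)
  df$sigma_f_true <- pooled_sf_bandwidth(fo, si, pool)
  df$sigma_logf_true <- pooled_log_bandwidth(fo, si, pool)
  df$sigma_theta_true <- pooled_ori_bandwidth(fo, si, pool)
  df$f1f0_true <- pooled_f1f0(fo, pool)

  n <- nrow(df)
  lnorm <- function(mu) mu * exp(scatter_sd * rng$rnorm(n))
  df$sigma_x <- lnorm(df$sigma_x_true)
  df$sigma_f <- lnorm(df$sigma_f_true)
  df$sigma_theta <- lnorm(df$sigma_theta_true)
  df$sigma_logf <- log2((fo + df$sigma_f) / fo)
  df$f1f0 <- pmin(pi, pmax(0, df$f1f0_true + f1f0_noise_sd * rng$rnorm(n)))
  df$lowpass <- FALSE

  structure(df, pool = pool, si = si, scatter_sd = scatter_sd,
            f1f0_noise_sd = f1f0_noise_sd, seed = seed,
            class = c("neuron_population", "data.frame"))
}
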