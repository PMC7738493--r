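#' Stimulus ensembles
#'
#' Condition tables for the two reverse-correlation stimulus ensembles
#' used throughout the package.
#'
#' `grating_ensemble()` enumerates the flashed sine-grating ensemble:
#' 8 orientations (22.5 deg apart), 7 log-spaced spatial frequencies from
#' 0.25 to 8 cyc/deg, and 4 spatial phases (90 deg apart) -- 224
#' conditions, updated every 133 ms inside a 3 deg aperture.
#'
#' `bar_ensemble()` enumerates the flashed-bar ensemble: 0.2 deg wide bars
#' (3 deg long by default), positions 0.1 deg apart, orientations 10 deg
#' apart, at two luminances (bright/dark relative to the gray background).
#'
#' @param n_ori,n_phase Numbers of orientations and phases (gratings).
#' @param sf_range,n_sf Log-spaced SF range (cyc/deg) and count.
#' @param update_s Stimulus update interval, seconds.
#' @param aperture_deg Square aperture side, degrees.
#' @return A data.frame with one row per condition (`cond` id plus the
#'   condition axes), carrying the ensemble geometry as attributes; class
#'   `stimulus_ensemble`.
#' @examples
#' nrow(grating_ensemble())  # 224
#' @export
grating_ensemble <- function(n_ori = 8L, sf_range = c(0.25, 8), n_sf = 7L,
                             n_phase = 4L, update_s = 0.133,
                             aperture_deg = 3) {
  oris <- seq(0, 180, length.out = n_ori + 1L)[seq_len(n_ori)]
  sfs <- 2^seq(log2(sf_range[1]), log2(sf_range[2]), length.out = n_sf)
  phases <- seq(0, 360, length.out = n_phase + 1L)[seq_len(n_phase)]
  df <- expand.grid(ori = oris, sf = sfs, phase = phases,
                    KEEP.OUT.ATTRS = FALSE)
  df <- cbind(cond = seq_len(nrow(df)), df)
  structure(df, kind = "grating", update_s = update_s,
            aperture_deg = aperture_deg,
            class = c("stimulus_ensemble", "data.frame"))
}

#' @rdname grating_ensemble
#' @param length_deg,width_deg Bar length and width, degrees.
#' @param pos_range Range of bar positions along the probe axis, degrees
#'   (relative to `center`).
#' @param pos_step Position step, degrees.
#' @param ori_step Orientation step, degrees.
#' @param center Visual-field point `c(x, y)` (deg) bar positions are
#'   measured from; in practice the stimulus is centered on the
#'   population's aggregate RF location.
#' @export
bar_ensemble <- function(length_deg = 3, width_deg = 0.2,
                         pos_range = c(-1.5, 1.5), pos_step = 0.1,
                         ori_step = 10, update_s = 0.133,
                         center = c(0, 0)) {
  oris <- seq(0, 180 - ori_step, by = ori_step)
  pos <- seq(pos_range[1], pos_range[2], by = pos_step)
  df <- expand.grid(ori = oris, pos = pos, lum = c("on", "off"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- cbind(cond = seq_len(nrow(df)), df)
  structure(df, kind = "bar", update_s = update_s, width_deg = width_deg,
            length_deg = length_deg, pos_step = pos_step,
            center_deg = as.numeric(center),
            class = c("stimulus_ensemble", "data.frame"))
}

#' Random stimulus sequence
#'
#' Draws a balanced random presentation order of an ensemble: conditions
#' are presented in repeated shuffled sweeps so every condition appears
#' `n_sweeps` times. Onsets are spaced by the ensemble update interval and
#' also reported as frame indices at the imaging frame rate.
#'
#' @param ensemble A [grating_ensemble()] or [bar_ensemble()].
#' @param n_sweeps Number of complete sweeps through the ensemble.
#' @param fs Imaging frame rate, Hz.
#' @param seed Integer seed; the sequence is deterministic given the seed.
#' @return A data.frame (class `stimulus_log`) with columns `onset_s`,
#'   `onset_frame`, `cond` and the condition axes of the ensemble.
#' @export
make_stimulus_sequence <- function(ensemble, n_sweeps = 1L, fs = 15,
                                   seed = 1L) {
  stopifnot(inherits(ensemble, "stimulus_ensemble"), n_sweeps >= 1)
  update_s <- attr(ensemble, "update_s")
  rng <- .local_rng(seed)
  order <- unlist(lapply(seq_len(n_sweeps),
                         function(i) rng$sample(nrow(ensemble))))
  log <- ensemble[order, , drop = FALSE]
  log$onset_s <- (seq_along(order) - 1L) * update_s
  log$onset_frame <- floor(log$onset_s * fs) + 1L
  rownames(log) <- NULL
  structure(log, kind = attr(ensemble, "kind"), fs = fs,
            update_s = update_s,
            class = c("stimulus_log", "data.frame"))
}

# Seed-local RNG helper: runs `expr`-style draws under a private RNG state
# so generators are deterministic without clobbering the caller's stream.
.local_rng <- function(seed) {
  seed <- as.integer(seed)
  env <- new.env()
  run <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (!is.null(env$state)) assign(".Random.seed", env$state, envir = globalenv())
    else set.seed(seed)
    out <- f()
    env$state <- get(".Random.seed", globalenv())
    out
  }
  list(
    run = run,
    sample = function(n, ...) run(function() sample.int(n, ...)),
    rnorm = function(n, mean = 0, sd = 1) run(function() rnorm(n, mean, sd)),
    runif = function(n, min = 0, max = 1) run(function() runif(n, min, max))
  )
}
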