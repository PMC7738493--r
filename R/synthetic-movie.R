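#' Render a synthetic calcium imaging movie
#'
#' Turns a neuron population plus per-cell fluorescence traces into a raw
#' movie: Gaussian puncta (cell bodies) at the cortical positions, a
#' diffuse background, shared sinusoidal breathing/heartbeat artifacts,
#' white noise, and optional frame-wise lateral drift. Ground-truth ROI
#' masks and the drift trajectory are returned alongside so downstream
#' stages can be validated.
#'
#' @param population A [sample_population()] table (positions in um).
#' @param traces Matrix `n_frames x n_cells` of noiseless fluorescence.
#' @param pixel_um Movie pixel size, um.
#' @param fs Frame rate, Hz (15 by default).
#' @param punctum_sigma_um Gaussian radius of a cell body, um.
#' @param background Constant background level.
#' @param artifact_freqs Frequencies (Hz) of the shared sinusoidal
#'   artifacts; use `numeric(0)` to disable.
#' @param artifact_amp Amplitude of each artifact sinusoid.
#' @param noise_sd White-noise SD per pixel and frame.
#' @param drift Either `NULL` (no drift) or an integer matrix
#'   `n_frames x 2` of (dy, dx) pixel shifts applied to each frame.
#' @param seed Integer seed.
#' @return An object of class `calcium_movie`: list with `frames`
#'   (array `ny x nx x n_frames`), `masks` (labeled integer matrix, 0 =
#'   background), `traces`, `drift`, `fs`, `pixel_um`, `artifact_freqs`.
#' @export
render_movie <- function(population, traces, pixel_um = 2, fs = 15,
                         punctum_sigma_um = 3, background = 0.1,
                         artifact_freqs = c(0.3, 1.2), artifact_amp = 0.05,
                         noise_sd = 0.02, drift = NULL, seed = 1L) {
  stopifnot(is.matrix(traces), nrow(population) == ncol(traces))
  n_frames <- nrow(traces)
  rng <- .local_rng(seed)

  margin_px <- ceiling(4 * punctum_sigma_um / pixel_um) + 4L
  nx <- ceiling(max(population$x_um) / pixel_um) + 2L * margin_px
  ny <- ceiling(max(population$y_um) / pixel_um) + 2L * margin_px
  cx <- population$x_um / pixel_um + margin_px
  cy <- population$y_um / pixel_um + margin_px

  sig_px <- punctum_sigma_um / pixel_um
  xs <- seq_len(nx); ys <- seq_len(ny)
  # Static neuropil texture (smoothed noise) on top of the flat
  # background; it moves with the drift, giving the aligner something to
  # lock onto even between cellular transients.
  tex <- matrix(rng$rnorm(ny * nx), ny, nx)
  kb <- stats::fft(.dog_kernel(ny, nx, 2 * sig_px, 1e6)) # low-pass part only
  tex <- Re(stats::fft(stats::fft(tex) * kb, inverse = TRUE)) / (ny * nx)
  tex <- tex / max(abs(tex))
  base <- matrix(background, ny, nx) * (1 + 0.5 * tex)
  cell_imgs <- vector("list", nrow(population))
  masks <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(population))) {
    img <- outer(.gauss(ys, cy[i], sig_px), .gauss(xs, cx[i], sig_px))
    cell_imgs[[i]] <- img
    sel <- img > exp(-2) & masks == 0L   # within ~2 sigma, first claim wins
    masks[sel] <- i
  }

  if (length(artifact_freqs)) {
    ph <- rng$runif(length(artifact_freqs), 0, 2 * pi)
    t <- (seq_len(n_frames) - 1) / fs
    art <- rowSums(vapply(seq_along(artifact_freqs), function(j)
      artifact_amp * sin(2 * pi * artifact_freqs[j] * t + ph[j]),
      numeric(n_frames)))
  } else art <- rep(0, n_frames)

  frames <- array(0, c(ny, nx, n_frames))
  for (t in seq_len(n_frames)) {
    fr <- base
    for (i in seq_along(cell_imgs))
      fr <- fr + cell_imgs[[i]] * traces[t, i]
    fr <- fr + art[t]
    if (noise_sd > 0)
      fr <- fr + matrix(rng$rnorm(ny * nx, sd = noise_sd), ny, nx)
    if (!is.null(drift))
      fr <- .shift_frame(fr, drift[t, 1], drift[t, 2], fill = background)
    frames[, , t] <- fr
  }

  structure(list(frames = frames, masks = masks, traces = traces,
                 drift = drift, fs = fs, pixel_um = pixel_um,
                 artifact_freqs = artifact_freqs,
                 centers_px = cbind(y = cy, x = cx)),
            class = "calcium_movie")
}

# Integer-pixel shift of a matrix, padding exposed edges with `fill`.
.shift_frame <- function(m, dy, dx, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

#' @export
print.calcium_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<calcium_movie: %d x %d px, %d frames @ %g Hz, %d cells>\n",
              d[1], d[2], d[3], x$fs, max(x$masks)))
  invisible(x)
}

#' Write / read a movie as a TIFF stack
#'
#' Convenience export of the frame stack to a multi-page TIFF (values
#' rescaled to \[0, 1\]; the scale is returned so traces stay
#' quantitative). Requires the `tiff` package.
#'
#' @param movie A `calcium_movie`.
#' @param path Output file path.
#' @return `write_movie_tiff`: the rescale factor, invisibly.
#'   `read_movie_tiff`: array `ny x nx x n_frames`.
#' @export
write_movie_tiff <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  fr <- movie$frames
  lo <- min(fr); hi <- max(fr)
  sc <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(fr)[3]), function(t) (fr[, , t] - lo) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(sc)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF import")
  pages <- tiff::readTIFF(path, all = TRUE)
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}
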