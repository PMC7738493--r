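# Small structured movie used across the alignment/detection tests.
make_test_movie <- function(n_frames = 80, drift = NULL, noise_sd = 0.02,
                            seed = 1) {
  set.seed(seed)
  base <- matrix(0.1, 48, 48)
  centers <- cbind(x = c(12, 30, 38, 15), y = c(14, 12, 34, 38))
  for (i in seq_len(nrow(centers)))
    base <- base + outer(exp(-(1:48 - centers[i, "y"])^2 / 4.5),
                         exp(-(1:48 - centers[i, "x"])^2 / 4.5))
  frames <- array(0, c(48, 48, n_frames))
  for (t in seq_len(n_frames)) {
    fr <- base * (0.6 + 0.4 * abs(sin(t / 7 + 1:4))[1])
    if (!is.null(drift))
      fr <- poolsi:::.shift_frame(fr, drift[t, 1], drift[t, 2], 0.1)
    frames[, , t] <- fr + matrix(rnorm(48 * 48, 0, noise_sd), 48, 48)
  }
  list(frames = frames, centers = centers)
}

test_that("rigid alignment recovers known drift and is idempotent", {
  # zero drift: all shifts 0
  m0 <- make_test_movie(40)
  al0 <- rigid_align(m0$frames)
  expect_true(all(al0$shifts == 0))

  # known drift within +/- 3 px recovered within 1 px
  set.seed(3)
  drift <- cbind(pmin(pmax(round(cumsum(rnorm(60, 0, 0.8))), -3), 3),
                 pmin(pmax(round(cumsum(rnorm(60, 0, 0.8))), -3), 3))
  m1 <- make_test_movie(60, drift = drift)
  al1 <- rigid_align(m1$frames)
  expect_lte(max(abs(-al1$shifts - drift)), 1)

  # aligning an aligned movie changes nothing
  al2 <- rigid_align(al1$frames)
  expect_true(all(al2$shifts == 0))

  expect_error(rigid_align(array(0, c(4, 4, 1))), "2 frames")
})

test_that("local cross-correlation image matches its brute-force definition", {
  set.seed(7)
  mov <- array(rnorm(24 * 24 * 12, 0.5, 0.1), c(24, 24, 12))
  lx <- local_crosscorr_image(mov, pixel_um = 2)
  # brute force: explicit circular shift-and-add over every kernel
  # element, sm[y, x] = sum_{dy,dx} dog[dy, dx] * fr[y - dy, x - dx]
  dog <- poolsi:::.dog_kernel(24, 24, 3 / 2, 20 / 2)
  circ <- function(m, dy, dx) {
    m[((seq_len(24) - 1 - dy) %% 24) + 1, ((seq_len(24) - 1 - dx) %% 24) + 1]
  }
  acc <- matrix(0, 24, 24)
  for (t in 1:12) {
    fr <- mov[, , t]
    sm <- matrix(0, 24, 24)
    for (dy in 0:23) for (dx in 0:23)
      sm <- sm + dog[dy + 1, dx + 1] * circ(fr, dy, dx)
    acc <- acc + fr * sm
  }
  expect_equal(lx$values, acc, tolerance = 1e-10)
})

test_that("local cross-correlation is near zero for white noise and bright for puncta", {
  set.seed(11)
  noise_mov <- array(rnorm(40 * 40 * 60), c(40, 40, 60))
  lxn <- local_crosscorr_image(noise_mov, pixel_um = 2)
  z <- (lxn$values - median(lxn$values)) / mad(lxn$values)
  expect_lt(mean(abs(z) > 4), 0.005)

  # one coherent punctum lights up
  img <- outer(exp(-(1:40 - 20)^2 / 4), exp(-(1:40 - 20)^2 / 4))
  tr <- abs(sin(1:60 / 3))
  mov <- array(0, c(40, 40, 60))
  for (t in 1:60) mov[, , t] <- img * tr[t] +
    matrix(rnorm(1600, 0, 0.05), 40, 40)
  lx <- local_crosscorr_image(mov, pixel_um = 2)
  pk <- which(lx$values == max(lx$values), arr.ind = TRUE)
  expect_lt(max(abs(pk - c(20, 20))), 2)
})

test_that("cell segmentation finds synthetic puncta and rejects flat images", {
  flat <- structure(list(values = matrix(1, 30, 30), pixel_um = 2,
                         center_sigma_um = 3, surround_sigma_um = 20),
                    class = "localx_image")
  expect_length(segment_cells(flat), 0)

  pop <- make_pop(20, seed = 15)
  set.seed(15)
  pop$x_um <- runif(20, 10, 150); pop$y_um <- runif(20, 10, 150)
  tr <- matrix(abs(rnorm(250 * 20, 0.4, 0.3)), 250, 20)
  mov <- render_movie(pop, tr, noise_sd = 0.02, seed = 16)
  lx <- local_crosscorr_image(mov, pixel_um = mov$pixel_um)
  rois <- segment_cells(lx)
  true_xy <- (mov$centers_px - 1) * mov$pixel_um
  matched <- sum(sapply(seq_len(nrow(true_xy)), function(i) {
    any(sapply(rois, function(r)
      sqrt((r$centroid_um["x"] - true_xy[i, "x"])^2 +
             (r$centroid_um["y"] - true_xy[i, "y"])^2) < 3))
  }))
  expect_gte(matched, 18)
  # ROI count cannot exceed the number of detected local maxima and
  # ROIs never overlap
  all_px <- unlist(lapply(rois, `[[`, "pixels"))
  expect_equal(length(all_px), length(unique(all_px)))
})

test_that("notch filter removes resonant peaks and only them", {
  set.seed(21)
  n <- 900; fs <- 15
  t <- (0:(n - 1)) / fs
  signal <- as.numeric(arima.sim(list(ar = 0.6), n)) * 0.3
  artifact <- 0.8 * sin(2 * pi * 0.4 * t) + 0.8 * sin(2 * pi * 1.5 * t)
  trace <- signal + artifact
  out <- notch_filter_trace(trace, fs)
  expect_setequal(round(attr(out, "notch_freqs"), 1), c(0.4, 1.5))

  amp_at <- function(x, f0) {
    a <- Mod(fft(x - mean(x)))[2:(n / 2)]
    fr <- (1:(n / 2 - 1)) * fs / n
    a[which.min(abs(fr - f0))]
  }
  # >= 20 dB attenuation at the artifact frequencies
  for (f0 in c(0.4, 1.5))
    expect_gt(20 * log10(amp_at(trace, f0) / amp_at(out, f0)), 20)
  # < 1 dB change in broadband power away from the notches
  spec_keep <- function(x) {
    a <- Mod(fft(x - mean(x)))[2:(n / 2)]
    fr <- (1:(n / 2 - 1)) * fs / n
    sum(a[abs(fr - 0.4) > 0.1 & abs(fr - 1.5) > 0.1]^2)
  }
  expect_lt(abs(10 * log10(spec_keep(out) / spec_keep(trace))), 1)

  # white noise passes unchanged; filtering is idempotent
  wn <- rnorm(300)
  expect_equal(as.numeric(notch_filter_trace(wn, fs)), wn)
  out2 <- notch_filter_trace(as.numeric(out), fs)
  expect_equal(as.numeric(out2), as.numeric(out), tolerance = 1e-8)

  expect_error(notch_filter_trace(rnorm(30), fs), "64")
  expect_error(notch_filter_trace(wn, fs, band = c(1, 10)), "Nyquist")
})

test_that("per-trial Z-scoring standardizes and flags degenerate traces", {
  set.seed(5)
  x <- rnorm(100, 3, 2)
  z <- zscore_trial(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore_trial(5 * x + 2), z)  # affine invariance
  expect_error(zscore_trial(rep(1, 50)), class = "poolsi_zero_variance")
})

test_that("stimulus-triggered average equals the brute-force event loop", {
  ens <- grating_ensemble()
  lg <- make_stimulus_sequence(ens, n_sweeps = 2, seed = 31)
  nf <- max(lg$onset_frame) + 20
  set.seed(31)
  tr <- rnorm(nf)
  k <- stimulus_triggered_average(tr, lg, ens)
  # delta-stimulus sanity: a trace that spikes only after condition 17
  tr2 <- rep(0, nf)
  on17 <- lg$onset_frame[lg$cond == 17]
  tr2[on17] <- 1
  k2 <- stimulus_triggered_average(tr2, lg, ens)
  co <- ens[ens$cond == 17, ]
  io <- match(co$ori, k2$coords$ori); is <- match(co$sf, k2$coords$sf)
  ip <- match(co$phase, k2$coords$phase)
  expect_equal(k2$data[io, is, ip, 1], 1)

  # brute force: loop over presentations and conditions
  L <- 15
  for (cond in c(1, 17, 224)) {
    on <- lg$onset_frame[lg$cond == cond & lg$onset_frame + L - 1 <= nf]
    manual <- colMeans(do.call(rbind,
                               lapply(on, function(f) tr[f:(f + L - 1)])))
    co <- ens[ens$cond == cond, ]
    io <- match(co$ori, k$coords$ori); is <- match(co$sf, k$coords$sf)
    ip <- match(co$phase, k$coords$phase)
    expect_equal(k$data[io, is, ip, ], manual)
  }
  expect_equal(sum(k$counts), sum(lg$onset_frame + L - 1 <= nf))
})

test_that("kernel standard error shrinks like one over sqrt of trial count", {
  ens <- grating_ensemble()
  se_of <- function(n_sweeps, seed) {
    lg <- make_stimulus_sequence(ens, n_sweeps = n_sweeps, seed = seed)
    nf <- max(lg$onset_frame) + 20
    set.seed(seed)
    tr <- rnorm(nf)
    k <- stimulus_triggered_average(tr, lg, ens)
    sd(k$data[, , , 1])
  }
  ratios <- sapply(1:12, function(s) se_of(2, s) / se_of(8, s + 100))
  expect_rel(mean(ratios), 2, 0.2)
})

test_that("the movie-to-kernel pipeline recovers the generative kernels", {
  pop <- make_pop(8, seed = 7)
  set.seed(2)
  pop$x_um <- runif(8, 10, 90); pop$y_um <- runif(8, 10, 90)
  ens <- grating_ensemble()
  n_blocks <- 10
  all_tr <- list(); all_log <- list(); frame_off <- 0; rois <- NULL
  for (b in seq_len(n_blocks)) {
    lg <- make_stimulus_sequence(ens, n_sweeps = 4, seed = 100 + b)
    nf <- max(lg$onset_frame) + 20
    traces <- sapply(seq_len(nrow(pop)), function(i)
      simulate_response_trace(pop[i, ], lg, ens, nf))
    mov <- render_movie(pop, traces, pixel_um = 2, noise_sd = 0.02,
                        artifact_amp = 0.05, seed = 200 + b)
    if (b == 1) {
      lx <- local_crosscorr_image(mov$frames, 2)
      rois <- segment_cells(lx)
    }
    tr <- extract_traces(mov$frames, rois)
    all_tr[[b]] <- apply(tr, 2, function(x)
      zscore_trial(notch_filter_trace(x)))
    lg$onset_frame <- lg$onset_frame + frame_off
    all_log[[b]] <- lg
    frame_off <- frame_off + nf
  }
  kl <- stimulus_triggered_average(do.call(rbind, all_tr),
                                   do.call(rbind, all_log), ens)
  k0 <- lapply(seq_len(nrow(pop)), function(i)
    simulate_grating_kernel(pop[i, ], ens, noise_sd = 0))
  # compare condition-differential structure (the stimulus-independent
  # pedestal from overlapping responses carries no tuning information)
  demean <- function(a) sweep(a, 4, apply(a, 4, mean))
  cors <- sapply(seq_along(rois), function(j)
    max(sapply(seq_len(nrow(pop)), function(i)
      cor(as.vector(demean(kl[[j]]$data)), as.vector(demean(k0[[i]]$data))))))
  expect_gte(length(rois), 6)
  expect_gt(median(cors), 0.9)
})
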