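make_grating_kernel <- function(amp_fun, fs = 15, nt = 15) {
  ens <- grating_ensemble()
  oris <- sort(unique(ens$ori)); sfs <- sort(unique(ens$sf))
  phases <- sort(unique(ens$phase))
  h <- poolsi:::.ca_impulse(fs, nt / fs)
  arr <- array(0, c(8, 7, 4, nt))
  for (i in 1:8) for (j in 1:7) for (k in 1:4)
    arr[i, j, k, ] <- amp_fun(oris[i], sfs[j], phases[k]) * h
  response_kernel(arr, list(ori = oris, sf = sfs, phase = phases),
                  "grating", fs)
}

test_that("temporal collapse slices at the smoothed peak with earliest-tie rule", {
  # delta in time: slice at that frame
  arr <- array(0, c(4, 3, 15)); arr[2, 2, 7] <- 1
  k <- response_kernel(arr, list(a = 1:4, b = 1:3), "grating", 15)
  col <- temporal_collapse(k, sigma_s = 1e-6)
  expect_equal(col$t_index, 7)
  expect_equal(which.max(col$resp), 4 + 2)
  # time-constant kernel: earliest frame chosen
  arr2 <- array(rep(c(1, 2, 1), each = 1, times = 15), c(3, 1, 15))
  k2 <- response_kernel(arr2, list(a = 1:3, b = 1), "grating", 15)
  expect_equal(temporal_collapse(k2)$t_index, 1)
  # smoothing attenuates white-noise peaks
  set.seed(8)
  peaks <- replicate(40, {
    arr <- array(rnorm(4 * 3 * 15), c(4, 3, 15))
    k <- response_kernel(arr, list(a = 1:4, b = 1:3), "grating", 15)
    max(temporal_collapse(k)$resp) < max(arr)
  })
  expect_gt(mean(peaks), 0.9)
  expect_error(temporal_collapse(response_kernel(
    array(0, c(2, 2, 15)), list(a = 1:2, b = 1:2), "grating", 15)),
    "all-zero")
})

test_that("orientation fit recovers a noiseless Gaussian to within 1%", {
  k <- make_grating_kernel(function(o, s, p)
    exp(-poolsi:::.wrap_ori_diff(o, 70)^2 / (2 * 20^2)) *
      exp(-(s - 2)^2 / (2 * 1^2)))
  o <- fit_orientation(k)
  expect_rel(o$sigma_theta, 20, 0.01)
  expect_lt(abs(poolsi:::.wrap_ori_diff(o$ori_opt, 70)), 2)
  expect_gt(o$ve, 0.999)
  # the 61% half-width of a Gaussian equals ~0.994 sigma (closed form),
  # within 1% of sigma itself
  expect_equal(sqrt(2 * log(1 / 0.61)), 0.9943, tolerance = 1e-3)
  expect_lt(abs(sqrt(2 * log(1 / 0.61)) - 1), 0.01)
})

test_that("SF fit recovers parameters, flags low-pass, applies the f_low fallback", {
  k <- make_grating_kernel(function(o, s, p)
    exp(-poolsi:::.wrap_ori_diff(o, 40)^2 / (2 * 25^2)) *
      exp(-(s - 2)^2 / (2 * 0.8^2)))
  s <- fit_sf(k)
  expect_rel(s$fo, 2, 0.02)
  expect_rel(s$sigma_f, 0.8, 0.02)
  expect_false(s$lowpass)
  expect_equal(s$sigma_logf, log2((s$fo + s$sigma_f) / s$fo))

  # monotone-decreasing SF tuning is low pass
  klow <- make_grating_kernel(function(o, s, p)
    exp(-poolsi:::.wrap_ori_diff(o, 40)^2 / (2 * 25^2)) * exp(-s / 1.5))
  expect_true(fit_sf(klow)$lowpass)

  # very broad tuning never crosses 61% below the peak: f_low falls back
  # to the lowest stimulus SF (0.25 cyc/deg)
  kb <- make_grating_kernel(function(o, s, p)
    exp(-poolsi:::.wrap_ori_diff(o, 40)^2 / (2 * 25^2)) *
      exp(-(s - 3)^2 / (2 * 6^2)))
  sb <- fit_sf(kb)
  # premise: the generating curve stays above 61% of its peak below fo
  fgrid <- seq(0.25, sb$fo, length.out = 400)
  expect_gt(min(exp(-(fgrid - 3)^2 / (2 * 6^2))) /
              exp(-(sb$fo - 3)^2 / (2 * 6^2)), 0.61)
  expect_equal(sb$f_low, 0.25)
  expect_equal(sb$sigma_f, (sb$f_hi - 0.25) / 2)
})

test_that("phase fit matches the discrete Fourier oracle", {
  ens <- grating_ensemble()
  k <- make_grating_kernel(function(o, s, p)
    exp(-poolsi:::.wrap_ori_diff(o, 40)^2 / (2 * 25^2)) *
      exp(-(s - 2)^2 / (2 * 0.8^2)) * c(`0` = 2, `90` = 1, `180` = 0,
                                        `270` = 1)[as.character(p)])
  s <- fit_sf(k); o <- fit_orientation(k)
  p <- fit_phase(k, s$fo, o$ori_opt)
  expect_equal(p$f1f0, 2, tolerance = 1e-6)
  # the discrete Fourier oracle on the raw tuning values
  orc <- poolsi:::.sine_fit(c(0, 90, 180, 270), c(2, 1, 0, 1))
  expect_equal(orc$F1, 2, tolerance = 1e-12)
  expect_equal(orc$F0, 1, tolerance = 1e-12)

  # constant responses: complex-cell limit
  kc <- make_grating_kernel(function(o, s, p)
    exp(-poolsi:::.wrap_ori_diff(o, 40)^2 / (2 * 25^2)) *
      exp(-(s - 2)^2 / (2 * 0.8^2)))
  pc <- fit_phase(kc, 2, 40)
  expect_equal(pc$f1f0, 0, tolerance = 1e-9)

  # half-wave rectified sinusoid at 4 phases: the sine-fit estimate of
  # F1/F0 lands at 4 when sampled on-peak (the dense-phase value is pi)
  rect <- pmax(0, cos((c(0, 90, 180, 270)) * pi / 180))
  sf <- poolsi:::.sine_fit(c(0, 90, 180, 270), rect)
  expect_equal(sf$F1 / sf$F0, 4, tolerance = 1e-9)
  expect_lt(abs(sf$F1 / sf$F0 - pi) / pi, 0.3)
})

test_that("F1/F0 is invariant to response amplitude scaling", {
  k1 <- make_grating_kernel(function(o, s, p)
    exp(-poolsi:::.wrap_ori_diff(o, 40)^2 / (2 * 25^2)) *
      exp(-(s - 2)^2 / (2 * 0.8^2)) * (1 + 0.8 * cos(p * pi / 180)))
  p1 <- fit_phase(k1, 2, 40)
  k2 <- make_grating_kernel(function(o, s, p)
    7.3 * exp(-poolsi:::.wrap_ori_diff(o, 40)^2 / (2 * 25^2)) *
      exp(-(s - 2)^2 / (2 * 0.8^2)) * (1 + 0.8 * cos(p * pi / 180)))
  p2 <- fit_phase(k2, 2, 40)
  expect_equal(p1$f1f0, p2$f1f0, tolerance = 1e-9)
})

test_that("bar RF fit recovers width, center and ON/OFF separation", {
  pop <- make_pop(3, scatter = 0, f1f0_noise = 0, seed = 41)
  n <- pop[1, ]
  n$ori <- 65  # align the envelope with the binned orientation grid
  ens <- bar_ensemble(center = c(n$rf_x, n$rf_y))
  b <- fit_bar_rf(simulate_bar_kernel(n, ens, noise_sd = 0))
  # residual error decomposes into the 2x position binning (~2%) and the
  # +/-5 deg slice misalignment left by the binned orientation grid (~1%)
  expect_rel(correct_bar_width(b$sigma_x, 0.2), n$sigma_x, 0.035)
  expect_lt(sqrt((b$rf_center[1] - n$rf_x)^2 + (b$rf_center[2] - n$rf_y)^2),
            0.1)
  expect_true(b$ok)
  expect_gte(b$ve_env, 0.70)

  # separation formula: mu +/- 0.2, sigma 0.2 gives exactly 1
  expect_equal(abs(0.2 - (-0.2)) / (0.2 + 0.2), 1)
  # identical ON/OFF profiles give separation 0
  nc <- n; nc$f1f0 <- 0
  bc <- fit_bar_rf(simulate_bar_kernel(nc, ens, noise_sd = 0))
  expect_lt(bc$onoff_separation, 0.05)
})

test_that("bar-width deconvolution subtracts the boxcar variance", {
  expect_equal(correct_bar_width(0.3, 0), 0.3)
  expect_equal(correct_bar_width(0.3, 0.2), sqrt(0.09 - 0.04 / 12))
  expect_rel(correct_bar_width(0.3, 0.2), 0.294, 0.01)  # ~2% shrink
  expect_warning(out <- correct_bar_width(0.01, 0.2), "0")
  expect_equal(out, 0)

  # round trip: simulate with the 0.2 deg bar, correct, recover the
  # point-bar width within 1%
  pop <- make_pop(2, scatter = 0, f1f0_noise = 0, seed = 43)
  n <- pop[1, ]
  n$ori <- 45
  ens0 <- bar_ensemble(width_deg = 0, center = c(n$rf_x, n$rf_y))
  ens2 <- bar_ensemble(width_deg = 0.2, center = c(n$rf_x, n$rf_y))
  s0 <- fit_bar_rf(simulate_bar_kernel(n, ens0, noise_sd = 0))$sigma_x
  s2 <- fit_bar_rf(simulate_bar_kernel(n, ens2, noise_sd = 0))$sigma_x
  expect_rel(correct_bar_width(s2, 0.2), s0, 0.01)
})

test_that("exclusion rules intersect criteria and audit the counts", {
  fits <- data.frame(
    ve_ori = c(0.9, 0.5, 0.9, 0.9, 0.9),
    ve_sf = c(0.9, 0.9, 0.6, 0.9, 0.9),
    ve_env = c(0.9, 0.9, 0.9, 0.3, 0.9),
    ori_fit_ok = TRUE, sf_fit_ok = TRUE, rf_fit_ok = TRUE,
    lowpass = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  ex <- apply_exclusions(fits)
  expect_equal(ex$grating_ok, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(ex$bar_ok, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(ex$joint_ok, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_lte(sum(ex$joint_ok), min(sum(ex$grating_ok), sum(ex$bar_ok)))
  expect_equal(unname(ex$audit["lowpass_excluded"]), 1)
  expect_equal(unname(ex$audit["grating_fit_excluded"]), 2)

  # all perfect: nothing excluded
  perfect <- data.frame(ve_ori = 1, ve_sf = 1, ve_env = 1,
                        ori_fit_ok = TRUE, sf_fit_ok = TRUE,
                        rf_fit_ok = TRUE, lowpass = FALSE)[rep(1, 8), ]
  expect_true(all(apply_exclusions(perfect)$joint_ok))
})

test_that("tuning recovery stays within 10% median error at default noise", {
  pop <- make_pop(40, seed = 51)
  ens_b <- bar_ensemble(center = c(mean(pop$rf_x), mean(pop$rf_y)))
  fits <- do.call(rbind, lapply(seq_len(nrow(pop)), function(i) {
    n <- pop[i, ]
    kg <- simulate_grating_kernel(n, noise_sd = 0.03, seed = i)
    kb <- simulate_bar_kernel(n, ens_b, noise_sd = 0.03, seed = i + 500)
    fit_neuron(kg, kb)
  }))
  med_rel <- function(a, b) median(abs(a - b) / b, na.rm = TRUE)
  expect_lt(med_rel(fits$fo, pop$fo), 0.1)
  expect_lt(med_rel(fits$sigma_x, pop$sigma_x), 0.1)
  expect_lt(med_rel(fits$sigma_f, pop$sigma_f), 0.1)
  expect_lt(med_rel(fits$sigma_theta, pop$sigma_theta), 0.1)
})
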