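test_that("pooling-width estimators invert noiseless generative data exactly", {
  pop0 <- make_pop(100, scatter = 0, f1f0_noise = 0, seed = 2,
                   pool = pooling_params(0.3, 0.6, 0.54))
  expect_equal(estimate_sigma_hx(pop0, ref_si), 0.3, tolerance = 1e-12)
  expect_equal(estimate_sigma_hf(pop0, ref_si), 0.6, tolerance = 1e-12)
  expect_equal(estimate_D(pop0, 0.3), 0.54, tolerance = 1e-5)

  # a scale-invariant population triggers the failure signal
  si_pop <- sample_population(ref_sheet, pooling_params(0, 0, 0), ref_si,
                              50, scatter_sd = 0, f1f0_noise_sd = 0,
                              seed = 2)
  expect_error(estimate_sigma_hx(si_pop, ref_si),
               class = "poolsi_estimation_failure")
  expect_error(estimate_sigma_hf(si_pop, ref_si),
               class = "poolsi_estimation_failure")
  # all cells at the rectifier ceiling: D = 0
  flat <- data.frame(fo = c(1, 2, 4, 6), f1f0 = pi)
  expect_equal(estimate_D(flat, 0.24), 0, tolerance = 1e-6)
  expect_error(estimate_sigma_hx(si_pop[1:2, ], ref_si),
               class = "poolsi_estimation_failure")
})

test_that("root-median estimator is robust to reordering and contamination", {
  pop <- make_pop(200, seed = 6)
  est <- estimate_sigma_hx(pop, ref_si)
  shuffled <- pop[sample(nrow(pop)), ]
  expect_equal(estimate_sigma_hx(shuffled, ref_si), est)
  # 10% gross outlier contamination shifts the estimate by < 5%
  dirty <- pop
  dirty$sigma_x[1:10] <- dirty$sigma_x[1:10] * 10
  dirty$sigma_x[11:20] <- dirty$sigma_x[11:20] / 10
  expect_rel(estimate_sigma_hx(dirty, ref_si), est, 0.05)
})

test_that("estimators recover the generating parameters under default scatter", {
  ests <- sapply(1:20, function(s) {
    pop <- make_pop(200, seed = 600 + s)
    c(hx = estimate_sigma_hx(pop, ref_si),
      hf = estimate_sigma_hf(pop, ref_si),
      D = estimate_D(pop, 0.24))
  })
  expect_rel(median(ests["hx", ]), 0.24, 0.1)
  expect_rel(median(ests["hf", ]), 0.85, 0.1)
  expect_lt(abs(median(ests["D", ]) - 0.54), 0.05)
})

test_that("flexible scaling coefficient inverts and never loses to fixed alpha in-sample", {
  fo <- draw_fo(150, seed = 13)
  tab <- data.frame(fo = fo, sigma_x = 1 / (4 * fo), sigma_f = 4 * fo / (2 * pi))
  expect_equal(fit_flexible_alpha(tab, "rf_width"), 4, tolerance = 1e-9)
  expect_equal(fit_flexible_alpha(tab, "sf_bandwidth"), 4, tolerance = 1e-9)

  # nested models: the fitted coefficient's log-space training MSE is
  # never above the fixed-alpha model's
  pop <- make_pop(120, seed = 14)
  a <- fit_flexible_alpha(pop, "rf_width")
  mse_fit <- mean((log2(pop$sigma_x) - log2(1 / (a * pop$fo)))^2)
  mse_fix <- mean((log2(pop$sigma_x) - log2(1 / (pi * pop$fo)))^2)
  expect_lte(mse_fit, mse_fix + 1e-12)
})

test_that("leave-one-out comparison equals a naive per-cell refit and favors the true model", {
  pop <- make_pop(30, seed = 17)
  cv <- loocv_compare(pop, "rf_width", si = ref_si)
  # independent brute-force reimplementation
  y <- log2(pop$sigma_x)
  for (i in c(1, 7, 30)) {
    train <- pop[-i, ]
    sh <- sqrt(median(train$sigma_x^2 - (1 / (pi * train$fo))^2))
    pred_pooled <- log2(sqrt((1 / (pi * pop$fo[i]))^2 + sh^2))
    expect_equal(unname(cv$errors[i, "pooled"]), (y[i] - pred_pooled)^2,
                 tolerance = 1e-12)
    a <- 2^mean(-log2(train$sigma_x) - log2(train$fo))
    pred_flex <- log2(1 / (a * pop$fo[i]))
    expect_equal(unname(cv$errors[i, "si_flex"]), (y[i] - pred_flex)^2,
                 tolerance = 1e-12)
    expect_equal(unname(cv$errors[i, "si"]),
                 (y[i] - log2(1 / (pi * pop$fo[i])))^2, tolerance = 1e-12)
  }

  # the comparison is antisymmetric in the model order
  cv_sw <- loocv_compare(pop, "rf_width", models = c("si", "pooled"),
                         si = ref_si)
  d1 <- cv$comparisons[cv$comparisons$model == "si", ]
  d2 <- cv_sw$comparisons[cv_sw$comparisons$model == "pooled", ]
  expect_equal(d2$mean_diff, -d1$mean_diff, tolerance = 1e-12)
  expect_equal(d2$p, d1$p, tolerance = 1e-12)

  # pooled model beats both SI variants on its own generative data
  pop150 <- make_pop(150, seed = 18)
  cvx <- loocv_compare(pop150, "rf_width", si = ref_si)
  cmp <- cvx$comparisons
  expect_true(all(cmp$mean_diff > 0))
  expect_true(all(cmp$p < 0.05))
  expect_true(all(cmp$ci_lo <= cmp$mean_diff & cmp$mean_diff <= cmp$ci_hi))
})

test_that("magnification estimate is exact on a perfect retinotopic gradient", {
  n <- 25
  xy <- expand.grid(x_um = seq(0, 1000, length.out = 5),
                    y_um = seq(0, 700, length.out = 5))
  tab <- data.frame(xy, rf_x = xy$x_um / 1000 / 2, rf_y = xy$y_um / 1000 / 2)
  m <- estimate_magnification(tab)
  expect_equal(m$magnification, 2, tolerance = 1e-12)
  expect_equal(m$n_pairs, n * (n - 1) / 2)
  expect_error(estimate_magnification(tab[1, ]), "2 cells")

  # isotropic jitter on RF centers biases the slope downward modestly
  slopes <- sapply(1:20, function(s) {
    set.seed(s)
    tj <- tab
    tj$rf_x <- tj$rf_x + rnorm(n, 0, 0.02)
    tj$rf_y <- tj$rf_y + rnorm(n, 0, 0.02)
    estimate_magnification(tj)$magnification
  })
  expect_lt(median(slopes), 2)
  expect_gt(median(slopes), 2 * 0.95)
})

test_that("cortical pooling extent multiplies width by magnification", {
  ext <- cortical_pooling_extent(0.24, 2.0)
  expect_equal(ext$extent_1sigma_mm, 0.48)
  expect_equal(ext$extent_2sigma_mm, 0.96)
  expect_equal(cortical_pooling_extent(0, 2)$extent_1sigma_mm, 0)
})

test_that("marginal statistics compute the five row statistics and F-tests", {
  tab <- data.frame(fo = c(1, 2, 4), sigma_x = c(0.2, 0.3, 0.4))
  ms <- marginal_statistics(tab, params = c("fo", "sigma_x"))
  fo_col <- ms$stats$fo
  names(fo_col) <- ms$stats$statistic
  expect_equal(unname(fo_col["mean_log2"]), 1)
  expect_equal(unname(fo_col["sd_log2"]), 1)
  expect_equal(unname(fo_col["median"]), 2)

  # constant column: SD 0 and the F-test is flagged degenerate
  tabc <- data.frame(fo = c(1, 2, 4, 8), sigma_x = 0.3)
  msc <- marginal_statistics(tabc, params = c("fo", "sigma_x"))
  expect_equal(msc$stats$sigma_x[msc$stats$statistic == "sd"], 0)
  expect_true(msc$f_tests$degenerate[msc$f_tests$param == "sigma_x"])

  # on generated pooled data the variance ratio exceeds 1 (width
  # compression relative to fo) and the F-test is significant
  pop <- make_pop(200, seed = 23)
  msp <- marginal_statistics(pop, params = c("fo", "sigma_x"))
  ratio <- msp$f_tests$var_ratio[msp$f_tests$param == "sigma_x"]
  expect_gt(ratio, 1)
  expect_lt(msp$f_tests$p[msp$f_tests$param == "sigma_x"], 0.01)
})

test_that("the full fit report assembles all components", {
  pop <- make_pop(120, seed = 29)
  rep <- fit_pooling_model(pop, ref_si)
  expect_s3_class(rep, "pooling_fit_report")
  expect_rel(rep$sigma_hx, 0.24, 0.2)
  expect_rel(rep$sigma_hf, 0.85, 0.2)
  expect_true(rep$D >= 0 && rep$D <= 1)
  expect_true(all(is.finite(rep$alpha_flexible)))
  expect_false(is.null(rep$magnification))
  expect_equal(rep$cortical_extent$extent_2sigma_mm,
               2 * rep$sigma_hx * rep$magnification$magnification)
  expect_output(print(rep), "Pooled scale invariance")
})
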