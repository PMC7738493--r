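.estimation_failure <- function(msg) {
  stop(structure(class = c("poolsi_estimation_failure", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Estimate the spatial pooling width
#'
#' Root-median estimator: the median over cells of the signed difference
#' `sigma_x^2 - si_rf_width(fo)^2`, square-rooted. On noiseless data
#' generated under pooled scale invariance this inverts the model exactly;
#' a non-positive median (a population at or below scale invariance)
#' raises an estimation-failure condition of class
#' `poolsi_estimation_failure`.
#'
#' @param tuning Tuning table with columns `fo` and `sigma_x` (degrees).
#' @param si [si_params()] object.
#' @param include Optional logical vector of rows to use (e.g.
#'   `apply_exclusions()$joint_ok`).
#' @return Estimated `sigma_h(x)`, degrees.
#' @export
estimate_sigma_hx <- function(tuning, si = si_params(), include = NULL) {
  d <- if (is.null(include)) tuning else tuning[include, , drop = FALSE]
  d <- d[is.finite(d$fo) & is.finite(d$sigma_x), , drop = FALSE]
  if (nrow(d) < 3L) .estimation_failure("need at least 3 usable cells")
  med <- stats::median(d$sigma_x^2 - si_rf_width(d$fo, si)^2)
  if (med <= 0)
    .estimation_failure("non-positive median width excess: population is at or below scale invariance")
  sqrt(med)
}

#' Estimate the spectral pooling width
#'
#' Same root-median estimator in the SF domain, on
#' `sigma_f^2 - si_sf_bandwidth(fo)^2`.
#'
#' @param tuning Tuning table with columns `fo` and `sigma_f` (cyc/deg).
#' @inheritParams estimate_sigma_hx
#' @return Estimated `sigma_h(f)`, cyc/deg.
#' @export
estimate_sigma_hf <- function(tuning, si = si_params(), include = NULL) {
  d <- if (is.null(include)) tuning else tuning[include, , drop = FALSE]
  d <- d[is.finite(d$fo) & is.finite(d$sigma_f), , drop = FALSE]
  if (nrow(d) < 3L) .estimation_failure("need at least 3 usable cells")
  med <- stats::median(d$sigma_f^2 - si_sf_bandwidth(d$fo, si)^2)
  if (med <= 0)
    .estimation_failure("non-positive median bandwidth excess")
  sqrt(med)
}

#' Estimate the absolute phase-progression rate D
#'
#' One-dimensional least squares of the phase-selectivity model
#' `F1/F0 = pi * exp(-(sigma_hx * 2*pi * fo * D)^2 / 2)` over D in
#' \[0, 1\], against measured (fo, F1/F0) pairs. The spatial pooling
#' width is supplied externally (it is constrained by the RF-width fit
#' first, without D).
#'
#' @param tuning Tuning table with columns `fo` and `f1f0`.
#' @param sigma_hx Spatial pooling width, degrees.
#' @param include Optional logical row filter.
#' @return Estimated D in \[0, 1\].
#' @export
estimate_D <- function(tuning, sigma_hx, include = NULL) {
  d <- if (is.null(include)) tuning else tuning[include, , drop = FALSE]
  d <- d[is.finite(d$fo) & is.finite(d$f1f0), , drop = FALSE]
  if (nrow(d) < 3L) .estimation_failure("need at least 3 usable (fo, F1/F0) pairs")
  sse <- function(D) {
    pred <- pi * exp(-(sigma_hx * 2 * pi * d$fo * D)^2 / 2)
    sum((d$f1f0 - pred)^2)
  }
  opt <- stats::optimize(sse, interval = c(0, 1), tol = 1e-8)
  # optimize() never evaluates exactly at the boundary; accept 0 or 1 when
  # they do at least as well.
  cand <- c(opt$minimum, 0, 1)
  cand[which.min(vapply(cand, sse, numeric(1)))]
}

#' Fit a flexible scale-invariance scaling coefficient
#'
#' Least-squares fit, in log2 space, of the single scaling coefficient of
#' the pure scale-invariance prediction: `sigma_x = 1/(alpha * fo)` for RF
#' width, or `sigma_f = alpha * fo / (2*pi)` for SF bandwidth. This is the
#' "flexible scale invariance" comparison model: it relaxes the fixed
#' alpha = pi while remaining a one-parameter proportional model.
#'
#' @param tuning Tuning table.
#' @param target `"rf_width"` (uses `sigma_x`) or `"sf_bandwidth"`
#'   (uses `sigma_f`).
#' @param include Optional logical row filter.
#' @return Fitted alpha (dimensionless).
#' @export
fit_flexible_alpha <- function(tuning, target = c("rf_width", "sf_bandwidth"),
                               include = NULL) {
  target <- match.arg(target)
  d <- if (is.null(include)) tuning else tuning[include, , drop = FALSE]
  col <- if (target == "rf_width") "sigma_x" else "sigma_f"
  d <- d[is.finite(d$fo) & is.finite(d[[col]]) & d[[col]] > 0, , drop = FALSE]
  if (nrow(d) < 1L) .estimation_failure("no usable cells")
  if (target == "rf_width") {
    # log2(sigma_x) = -log2(alpha) - log2(fo)
    2^mean(-log2(d$sigma_x) - log2(d$fo))
  } else {
    # log2(sigma_f) = log2(alpha/(2*pi)) + log2(fo)
    2 * pi * 2^mean(log2(d$sigma_f) - log2(d$fo))
  }
}

# Model predictions of log2(width) used by the cross-validation.
.predict_log2_width <- function(model, target, fo, si, train) {
  switch(model,
    si = if (target == "rf_width") log2(si_rf_width(fo, si))
         else log2(si_sf_bandwidth(fo, si)),
    si_flex = {
      a <- fit_flexible_alpha(train, target)
      sif <- si_params(alpha = a, aspect_ratio = si$aspect_ratio)
      if (target == "rf_width") log2(si_rf_width(fo, sif))
      else log2(si_sf_bandwidth(fo, sif))
    },
    pooled = {
      sh <- tryCatch(
        if (target == "rf_width") estimate_sigma_hx(train, si)
        else estimate_sigma_hf(train, si),
        poolsi_estimation_failure = function(e) 0)
      pool <- pooling_params(sigma_hx = sh, sigma_hf = sh, D = 0)
      if (target == "rf_width") log2(pooled_rf_width(fo, si, pool))
      else log2(pooled_sf_bandwidth(fo, si, pool))
    },
    stop("unknown model: ", model))
}

#' Leave-one-out cross-validated model comparison
#'
#' For every cell, each competing model is refit on all remaining cells
#' and used to predict the left-out cell's RF width or SF bandwidth; the
#' per-cell prediction error is `[log2(data) - log2(prediction)]^2`.
#' Models are compared by a paired t-test on the per-cell squared-error
#' differences, with the 95% CI of the mean difference (a Wilcoxon
#' signed-rank alternative is also reported).
#'
#' @param tuning Tuning table (columns `fo` plus `sigma_x` or `sigma_f`).
#' @param target `"rf_width"` or `"sf_bandwidth"`.
#' @param models Character vector among `"pooled"`, `"si"`, `"si_flex"`.
#' @param si [si_params()] object.
#' @param include Optional logical row filter.
#' @return List with `errors` (matrix cells x models of squared log2
#'   errors), `mse` (named vector), and `comparisons` (data.frame of
#'   pairwise paired tests of the first model vs the rest: mean
#'   difference, t, p, CI bounds, Wilcoxon p).
#' @export
loocv_compare <- function(tuning, target = c("rf_width", "sf_bandwidth"),
                          models = c("pooled", "si", "si_flex"),
                          si = si_params(), include = NULL) {
  target <- match.arg(target)
  d <- if (is.null(include)) tuning else tuning[include, , drop = FALSE]
  col <- if (target == "rf_width") "sigma_x" else "sigma_f"
  d <- d[is.finite(d$fo) & is.finite(d[[col]]) & d[[col]] > 0, , drop = FALSE]
  n <- nrow(d)
  if (n < 10L) warning("fewer than 10 cells: cross-validation is fragile")
  y <- log2(d[[col]])
  errs <- matrix(NA_real_, n, length(models),
                 dimnames = list(NULL, models))
  for (i in seq_len(n)) {
    train <- d[-i, , drop = FALSE]
    for (m in models)
      errs[i, m] <- (y[i] -
        .predict_log2_width(m, target, d$fo[i], si, train))^2
  }
  ref <- models[1]
  comp <- do.call(rbind, lapply(setdiff(models, ref), function(m) {
    dif <- errs[, m] - errs[, ref]  # positive: ref (pooled) better
    tt <- stats::t.test(dif)
    wt <- stats::wilcox.test(dif, exact = FALSE)
    data.frame(model = m, vs = ref, mean_diff = mean(dif),
               t = unname(tt$statistic), p = tt$p.value,
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               p_wilcoxon = wt$p.value)
  }))
  list(errors = errs, mse = colMeans(errs), comparisons = comp, n = n)
}

#' Estimate the cortical magnification factor
#'
#' Computes the cortical separation (mm) and RF separation (deg) between
#' all unordered cell pairs and fits a line through the origin of the
#' (deg, mm) scatter; the slope is the magnification factor in mm/deg.
#'
#' @param tuning Table with cortical positions `x_um`, `y_um` and RF
#'   centers `rf_x`, `rf_y` (deg).
#' @param include Optional logical row filter.
#' @return List: `magnification` (mm/deg), `n_pairs`, `n_cells`.
#' @export
estimate_magnification <- function(tuning, include = NULL) {
  d <- if (is.null(include)) tuning else tuning[include, , drop = FALSE]
  d <- d[stats::complete.cases(d[, c("x_um", "y_um", "rf_x", "rf_y")]), ,
         drop = FALSE]
  if (nrow(d) < 2L) stop("need at least 2 cells with positions")
  d_mm <- as.vector(stats::dist(cbind(d$x_um, d$y_um))) / 1000
  d_deg <- as.vector(stats::dist(cbind(d$rf_x, d$rf_y)))
  if (sum(d_deg^2) == 0) stop("all RF centers coincide")
  list(magnification = sum(d_deg * d_mm) / sum(d_deg^2),
       n_pairs = length(d_mm), n_cells = nrow(d))
}

#' Cortical extent of the spatial pooling window
#'
#' Multiplies the spatial pooling width (deg) by the magnification factor
#' (mm/deg), reporting both the 1-sigma and 2-sigma extents.
#'
#' @param sigma_hx Spatial pooling width, degrees.
#' @param magnification Magnification factor, mm/deg.
#' @return List: `extent_1sigma_mm`, `extent_2sigma_mm`.
#' @export
cortical_pooling_extent <- function(sigma_hx, magnification) {
  stopifnot(sigma_hx >= 0, magnification > 0)
  list(extent_1sigma_mm = sigma_hx * magnification,
       extent_2sigma_mm = 2 * sigma_hx * magnification)
}

#' Marginal statistics of a tuning table
#'
#' For each tuning parameter: mean, median, SD, mean of log2 and SD of
#' log2 (log statistics only where all values are positive). Also runs
#' variance-ratio F-tests comparing the SD-log2 of the reference
#' parameter (`fo` by default) with every other parameter -- the key
#' scale-invariance diagnostics (under scale invariance SD-log2 of RF
#' width equals SD-log2 of fo).
#'
#' @param tuning Tuning table.
#' @param params Columns to summarize (defaults to those present among
#'   the standard tuning parameters).
#' @param ref Reference column for the F-tests.
#' @param include Optional logical row filter.
#' @return List: `stats` (data.frame, one row per statistic), `f_tests`
#'   (data.frame with variance ratio of log2 values and p; `NA` and
#'   flagged when a column is constant).
#' @export
marginal_statistics <- function(tuning,
                                params = intersect(
                                  c("fo", "sigma_x", "sigma_f", "sigma_logf",
                                    "sigma_theta", "f1f0",
                                    "onoff_separation"), names(tuning)),
                                ref = "fo", include = NULL) {
  d <- if (is.null(include)) tuning else tuning[include, , drop = FALSE]
  one <- function(v) {
    v <- v[is.finite(v)]
    logable <- length(v) > 0 && all(v > 0)
    c(mean = mean(v), median = stats::median(v), sd = stats::sd(v),
      mean_log2 = if (logable) mean(log2(v)) else NA_real_,
      sd_log2 = if (logable) stats::sd(log2(v)) else NA_real_)
  }
  stats_mat <- vapply(params, function(p) one(d[[p]]), numeric(5))
  stats_df <- data.frame(statistic = rownames(stats_mat), stats_mat,
                         row.names = NULL, check.names = FALSE)

  vref <- d[[ref]]; vref <- vref[is.finite(vref) & vref > 0]
  ftests <- do.call(rbind, lapply(setdiff(params, ref), function(p) {
    v <- d[[p]]; v <- v[is.finite(v) & v > 0]
    if (length(v) < 3L || length(vref) < 3L ||
        stats::sd(log2(v)) == 0 || stats::sd(log2(vref)) == 0)
      return(data.frame(param = p, var_ratio = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    vt <- stats::var.test(log2(vref), log2(v))
    data.frame(param = p, var_ratio = unname(vt$estimate), p = vt$p.value,
               degenerate = FALSE)
  }))
  list(stats = stats_df, f_tests = ftests)
}

#' Fit the full pooled-scale-invariance report
#'
#' Convenience wrapper producing the package's model report for a tuning
#' table: overall and per-group pooling parameter estimates, flexible
#' scale-invariance coefficients, leave-one-out model comparisons,
#' magnification and cortical pooling extent (when positions are
#' available), and marginal statistics.
#'
#' @param tuning Tuning table.
#' @param si [si_params()] object.
#' @param group_col Optional grouping column (e.g. imaging region) for
#'   per-group estimates.
#' @param include Optional logical row filter (defaults to all rows, with
#'   low-pass cells removed if a `lowpass` column exists).
#' @param loocv Run the cross-validated comparisons (default TRUE).
#' @return Object of class `pooling_fit_report`.
#' @export
fit_pooling_model <- function(tuning, si = si_params(), group_col = NULL,
                              include = NULL, loocv = TRUE) {
  if (is.null(include)) {
    include <- rep(TRUE, nrow(tuning))
    if ("lowpass" %in% names(tuning)) include <- include & !.is_true(tuning$lowpass)
  }
  d <- tuning[include, , drop = FALSE]
  sigma_hx <- tryCatch(estimate_sigma_hx(d, si),
                       poolsi_estimation_failure = function(e) NA_real_)
  sigma_hf <- tryCatch(estimate_sigma_hf(d, si),
                       poolsi_estimation_failure = function(e) NA_real_)
  D <- if (is.finite(sigma_hx))
    tryCatch(estimate_D(d, sigma_hx),
             poolsi_estimation_failure = function(e) NA_real_) else NA_real_
  alpha_x <- tryCatch(fit_flexible_alpha(d, "rf_width"),
                      poolsi_estimation_failure = function(e) NA_real_)
  alpha_f <- tryCatch(fit_flexible_alpha(d, "sf_bandwidth"),
                      poolsi_estimation_failure = function(e) NA_real_)

  per_group <- NULL
  if (!is.null(group_col) && group_col %in% names(d)) {
    per_group <- do.call(rbind, lapply(split(d, d[[group_col]]), function(g) {
      data.frame(
        group = g[[group_col]][1], n = nrow(g),
        sigma_hx = tryCatch(estimate_sigma_hx(g, si),
                            poolsi_estimation_failure = function(e) NA_real_),
        sigma_hf = tryCatch(estimate_sigma_hf(g, si),
                            poolsi_estimation_failure = function(e) NA_real_))
    }))
  }

  cv_rf <- cv_sf <- NULL
  if (loocv && sum(is.finite(d$sigma_x)) >= 10)
    cv_rf <- loocv_compare(d, "rf_width", si = si)
  if (loocv && sum(is.finite(d$sigma_f)) >= 10)
    cv_sf <- loocv_compare(d, "sf_bandwidth", si = si)

  mag <- NULL
  if (all(c("x_um", "y_um", "rf_x", "rf_y") %in% names(d)))
    mag <- tryCatch(estimate_magnification(d), error = function(e) NULL)
  extent <- if (!is.null(mag) && is.finite(sigma_hx))
    cortical_pooling_extent(sigma_hx, mag$magnification) else NULL

  structure(list(
    pool = if (is.finite(sigma_hx) && is.finite(sigma_hf) && is.finite(D))
      pooling_params(sigma_hx, sigma_hf, D) else NULL,
    sigma_hx = sigma_hx, sigma_hf = sigma_hf, D = D,
    alpha_flexible = c(rf_width = alpha_x, sf_bandwidth = alpha_f),
    per_group = per_group, loocv_rf_width = cv_rf,
    loocv_sf_bandwidth = cv_sf, magnification = mag,
    cortical_extent = extent, n_cells = nrow(d),
    marginals = marginal_statistics(d), si = si),
    class = "pooling_fit_report")
}

#' @export
print.pooling_fit_report <- function(x, ...) {
  cat("Pooled scale invariance fit\n")
  cat(sprintf("  cells: %d\n", x$n_cells))
  cat(sprintf("  sigma_h(x) = %.3g deg, sigma_h(f) = %.3g cyc/deg, D = %.3g\n",
              x$sigma_hx, x$sigma_hf, x$D))
  cat(sprintf("  flexible alpha: rf %.3g, sf %.3g\n",
              x$alpha_flexible["rf_width"], x$alpha_flexible["sf_bandwidth"]))
  if (!is.null(x$magnification))
    cat(sprintf("  magnification = %.3g mm/deg (%d pairs)\n",
                x$magnification$magnification, x$magnification$n_pairs))
  if (!is.null(x$cortical_extent))
    cat(sprintf("  cortical pooling extent = %.3g mm (1 sigma), %.3g mm (2 sigma)\n",
                x$cortical_extent$extent_1sigma_mm,
                x$cortical_extent$extent_2sigma_mm))
  invisible(x)
}
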