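#' Pipeline configuration
#'
#' Builds the single nested configuration object driving
#' [run_pipeline()]: one section per stage, every value serializable to
#' YAML, so a run is reproducible from the config plus its seed alone.
#' Defaults mirror the package's standard analysis settings (alpha = pi,
#' aspect ratio 2, 75-um clustering bins, 70% variance-explained and 61%
#' half-width criteria, pooling ground truth sigma_h(x) = 0.24 deg,
#' sigma_h(f) = 0.85 cyc/deg, D = 0.54).
#'
#' @param seed Master seed for the run.
#' @param mode `"kernels"`: simulate response kernels per cell and fit
#'   them (the full measurement path); `"direct"`: analyse the
#'   generator's measured-parameter targets directly (fast path).
#' @param ... Named overrides of nested sections (partial lists are
#'   merged over the defaults).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, mode = c("kernels", "direct"), ...) {
  mode <- match.arg(mode)
  cfg <- list(
    seed = as.integer(seed),
    mode = mode,
    si = list(alpha = pi, aspect_ratio = 2),
    pool = list(sigma_hx = 0.24, sigma_hf = 0.85, D = 0.54),
    sheet = list(nx = 100L, ny = 70L, pixel_um = 10, fo_period_um = 750,
                 fo_mean_log2 = 0.95, fo_sd_log2 = 0.64, magnification = 2),
    population = list(n_cells = 40L, scatter_sd = 0.2, f1f0_noise_sd = 0.15),
    kernels = list(noise_sd = 0.03, fs = 15, window_s = 1),
    fitting = list(min_ve = 0.70),
    clustering = list(bin_um = 75, n_shuffles = 200L,
                      params = c("fo", "sigma_x", "sigma_f", "sigma_theta",
                                 "f1f0"))
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` (for writing).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, c(list(seed = cfg$seed, mode = cfg$mode),
                             cfg[setdiff(names(cfg), c("seed", "mode"))]))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes generate (cortical sheet + population) -> measure (simulated
#' response kernels fitted per cell, or the generator's targets directly)
#' -> model (pooling-parameter estimation, cross-validated comparison,
#' magnification) -> cluster (distance-binned profiles), writing every
#' stage's tabular output plus a manifest (config, seed, file checksums)
#' into `outdir`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return The output directory, invisibly; artifacts: `tuning.csv`,
#'   `fit_report.json`, `clustering_<param>.csv`, `ground_truth.csv`,
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("poolsi_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  si <- si_params(config$si$alpha, config$si$aspect_ratio)
  pool <- pooling_params(config$pool$sigma_hx, config$pool$sigma_hf,
                         config$pool$D)

  sheet <- .stage("generate", make_cortical_sheet(
    nx = config$sheet$nx, ny = config$sheet$ny,
    pixel_um = config$sheet$pixel_um,
    fo_period_um = config$sheet$fo_period_um,
    fo_mean_log2 = config$sheet$fo_mean_log2,
    fo_sd_log2 = config$sheet$fo_sd_log2,
    magnification = config$sheet$magnification,
    D = config$pool$D, seed = config$seed))
  pop <- .stage("generate", sample_population(
    sheet, pool, si, n_cells = config$population$n_cells,
    scatter_sd = config$population$scatter_sd,
    f1f0_noise_sd = config$population$f1f0_noise_sd,
    seed = config$seed + 1L))
  utils::write.csv(as.data.frame(pop), file.path(outdir, "ground_truth.csv"),
                   row.names = FALSE)

  tuning <- .stage("measure", {
    if (config$mode == "direct") {
      cbind(as.data.frame(pop)[, c("cell", "x_um", "y_um", "rf_x", "rf_y",
                                   "fo", "ori", "sigma_x", "sigma_f",
                                   "sigma_logf", "sigma_theta", "f1f0",
                                   "lowpass")],
            ve_ori = 1, ve_sf = 1, ve_env = 1,
            ori_fit_ok = TRUE, sf_fit_ok = TRUE, rf_fit_ok = TRUE)
    } else {
      genb <- bar_ensemble(center = c(mean(pop$rf_x), mean(pop$rf_y)))
      rows <- lapply(seq_len(nrow(pop)), function(i) {
        neuron <- pop[i, ]
        kg <- simulate_grating_kernel(neuron,
                                      noise_sd = config$kernels$noise_sd,
                                      fs = config$kernels$fs,
                                      window_s = config$kernels$window_s,
                                      seed = config$seed + 100L + i)
        kb <- simulate_bar_kernel(neuron, genb,
                                  noise_sd = config$kernels$noise_sd,
                                  fs = config$kernels$fs,
                                  window_s = config$kernels$window_s,
                                  seed = config$seed + 5000L + i)
        cbind(cell = neuron$cell, x_um = neuron$x_um, y_um = neuron$y_um,
              fit_neuron(kg, kb))
      })
      do.call(rbind, rows)
    }
  })
  utils::write.csv(tuning, file.path(outdir, "tuning.csv"),
                   row.names = FALSE)

  report <- .stage("model", {
    keep <- apply_exclusions(tuning, min_ve = config$fitting$min_ve)
    rep <- fit_pooling_model(tuning, si,
                             include = keep$grating_ok | keep$bar_ok,
                             loocv = sum(keep$grating_ok) >= 10)
    attr(rep, "audit") <- keep$audit
    rep
  })
  .write_fit_report_json(report, file.path(outdir, "fit_report.json"))

  .stage("cluster", {
    for (p in config$clustering$params) {
      if (!p %in% names(tuning)) next
      v <- tuning[[p]]
      ok <- is.finite(v)
      if (sum(ok) < 5) next
      prof <- pairwise_profile(v[ok], tuning$x_um[ok], tuning$y_um[ok],
                               bin_um = config$clustering$bin_um)
      utils::write.csv(prof, file.path(outdir,
                                       sprintf("clustering_%s.csv", p)),
                       row.names = FALSE)
    }
    if ("ori" %in% names(tuning)) {
      ok <- is.finite(tuning$ori)
      if (sum(ok) >= 5) {
        prof <- circular_ori_profile(
          tuning$ori[ok] %% 180, tuning$x_um[ok], tuning$y_um[ok],
          bin_um = config$clustering$bin_um,
          n_shuffles = config$clustering$n_shuffles,
          seed = config$seed + 7L)
        utils::write.csv(prof, file.path(outdir, "clustering_ori.csv"),
                         row.names = FALSE)
      }
    }
  })

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("poolsi")),
    seed = config$seed, config = unclass(config),
    checksums = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

.write_fit_report_json <- function(report, path) {
  out <- list(
    sigma_hx_deg = report$sigma_hx, sigma_hf_cpd = report$sigma_hf,
    D = report$D, alpha_flexible = as.list(report$alpha_flexible),
    n_cells = report$n_cells,
    magnification_mm_per_deg =
      if (!is.null(report$magnification)) report$magnification$magnification,
    cortical_extent_mm = report$cortical_extent,
    loocv = lapply(list(rf_width = report$loocv_rf_width,
                        sf_bandwidth = report$loocv_sf_bandwidth),
                   function(cv) if (is.null(cv)) NULL else
                     list(mse = as.list(cv$mse),
                          comparisons = cv$comparisons)),
    audit = as.list(attr(report, "audit")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Render figures and tables from a pipeline run
#'
#' Reads the artifacts of a [run_pipeline()] directory and produces the
#' standard report: scatter plots of each tuning parameter against
#' preferred SF with the scale-invariance (blue) and pooled (green) model
#' curves, clustering profiles, and the marginal-statistics table.
#'
#' @param outdir A [run_pipeline()] output directory.
#' @param file PDF file to create (default `report.pdf` inside `outdir`).
#' @return Invisibly, the paths written. Missing inputs are reported in
#'   the error message.
#' @export
render_report <- function(outdir, file = file.path(outdir, "report.pdf")) {
  need <- c("tuning.csv", "fit_report.json")
  missing <- need[!file.exists(file.path(outdir, need))]
  if (length(missing))
    stop("missing pipeline artifacts: ", paste(missing, collapse = ", "))
  tuning <- utils::read.csv(file.path(outdir, "tuning.csv"))
  rep <- jsonlite::fromJSON(file.path(outdir, "fit_report.json"))
  si <- si_params()
  pool <- pooling_params(
    sigma_hx = if (is.finite(rep$sigma_hx_deg)) rep$sigma_hx_deg else 0,
    sigma_hf = if (is.finite(rep$sigma_hf_cpd)) rep$sigma_hf_cpd else 0,
    D = if (!is.null(rep$D) && is.finite(rep$D)) min(1, max(0, rep$D)) else 0)

  fo_grid <- 2^seq(-2.2, 3.2, length.out = 200)
  panel <- function(ycol, ylab, si_fun, pooled_fun, logy = TRUE) {
    ok <- is.finite(tuning$fo) & is.finite(tuning[[ycol]]) &
      tuning[[ycol]] > 0
    if (!sum(ok)) return(invisible())
    graphics::plot(tuning$fo[ok], tuning[[ycol]][ok], log = if (logy) "xy" else "x",
                   pch = 16, col = "grey30", xlab = "preferred SF (cyc/deg)",
                   ylab = ylab)
    graphics::lines(fo_grid, si_fun(fo_grid), col = "blue", lwd = 2)
    graphics::lines(fo_grid, pooled_fun(fo_grid), col = "darkgreen", lwd = 2)
    graphics::legend("topright", c("scale invariance", "pooled"),
                     col = c("blue", "darkgreen"), lwd = 2, bty = "n",
                     cex = 0.8)
  }

  grDevices::pdf(file, width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  panel("sigma_x", "RF width (deg)",
        function(f) si_rf_width(f, si), function(f) pooled_rf_width(f, si, pool))
  panel("sigma_f", "SF bandwidth (cyc/deg)",
        function(f) si_sf_bandwidth(f, si),
        function(f) pooled_sf_bandwidth(f, si, pool))
  panel("sigma_theta", "orientation bandwidth (deg)",
        function(f) rep(si_ori_bandwidth(si), length(f)),
        function(f) pooled_ori_bandwidth(f, si, pool))
  if ("f1f0" %in% names(tuning)) {
    ok <- is.finite(tuning$fo) & is.finite(tuning$f1f0)
    if (sum(ok)) {
      graphics::plot(tuning$fo[ok], tuning$f1f0[ok], log = "x", pch = 16,
                     col = "grey30", xlab = "preferred SF (cyc/deg)",
                     ylab = "F1/F0", ylim = c(0, pi))
      graphics::lines(fo_grid, pooled_f1f0(fo_grid, pool),
                      col = "darkgreen", lwd = 2)
    }
  }
  profs <- list.files(outdir, pattern = "^clustering_.*\\.csv$",
                      full.names = TRUE)
  for (f in profs) {
    prof <- utils::read.csv(f)
    graphics::plot((prof$bin_lo + prof$bin_hi) / 2, prof$r, type = "b",
                   pch = ifelse(prof$tier %in% c("p<0.01", "p<0.001"), 8, 16),
                   xlab = "cortical distance (um)", ylab = "pairwise r",
                   main = sub("clustering_(.*)\\.csv", "\\1", basename(f)))
    graphics::abline(h = 0, lty = 3)
  }

  # Marginal statistics table to CSV (lossless round trip).
  marg <- marginal_statistics(tuning)
  tab_path <- file.path(outdir, "marginal_statistics.csv")
  utils::write.csv(marg$stats, tab_path, row.names = FALSE)
  invisible(c(file, tab_path))
}
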