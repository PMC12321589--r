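#' Experiment configuration for the phantom image-quality study
#'
#' Describes one full phantom evaluation: phantom and forward-model
#' parameters, the dose levels to emulate by count thinning, the
#' reconstruction variants to compare, and the iteration/subset settings.
#' The defaults reproduce the standard evaluation grid: dose fractions
#' `{1, 0.5, 0.25, 0.125}`; OSEM (unfiltered), OSEM with a 3 mm Gaussian
#' post-filter, and guided reconstruction with `beta` in `{0.5, 1, 2}`;
#' 20 subsets and 8 iterations with every iteration saved.
#'
#' @param size phantom grid shape.
#' @param spacing_mm voxel size in mm.
#' @param n_angles projection angles of the forward model.
#' @param psf_fwhm_mm image-space PSF width of the forward model, mm.
#' @param total_counts expected full-dose total counts.
#' @param dose_fractions dose levels emulated by binomial thinning.
#' @param betas penalization strengths of the guided variants.
#' @param include_osem,include_osem_gf include the OSEM variants.
#' @param osem_gf_fwhm_mm post-filter width of the OSEM+GF variant.
#' @param n_subsets,n_iterations reconstruction settings.
#' @param seed master seed; all per-dose seeds are derived from it.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(size = c(128, 128), spacing_mm = 1.2,
                              n_angles = 120, psf_fwhm_mm = 0,
                              total_counts = 2e6,
                              dose_fractions = c(1, 0.5, 0.25, 0.125),
                              betas = c(0.5, 1, 2),
                              include_osem = TRUE, include_osem_gf = TRUE,
                              osem_gf_fwhm_mm = 3,
                              n_subsets = 20L, n_iterations = 8L,
                              seed = 1L) {
  if (any(dose_fractions <= 0 | dose_fractions > 1)) {
    stop("dose fractions must lie in (0, 1]", call. = FALSE)
  }
  structure(list(size = size, spacing_mm = spacing_mm, n_angles = n_angles,
                 psf_fwhm_mm = psf_fwhm_mm, total_counts = total_counts,
                 dose_fractions = sort(dose_fractions, decreasing = TRUE),
                 betas = betas, include_osem = include_osem,
                 include_osem_gf = include_osem_gf,
                 osem_gf_fwhm_mm = osem_gf_fwhm_mm,
                 n_subsets = as.integer(n_subsets),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(s), tf)
  unname(tools::md5sum(tf))
}

experiment_variants <- function(config) {
  v <- list()
  if (config$include_osem) {
    v <- c(v, list(list(name = "OSEM", beta = NA_real_, postfilter = 0)))
  }
  if (config$include_osem_gf) {
    v <- c(v, list(list(name = "OSEM_GF", beta = NA_real_,
                        postfilter = config$osem_gf_fwhm_mm)))
  }
  for (b in config$betas) {
    v <- c(v, list(list(name = sprintf("MRg_beta%g", b), beta = b, postfilter = 0)))
  }
  v
}

#' Run the phantom dose / algorithm / iteration sweep
#'
#' Generates the phantom, simulates full-dose counts, thins them to each
#' configured dose level, reconstructs every variant saving each iteration,
#' and tabulates the phantom metric panel per snapshot. The OSEM+GF variant
#' reuses the OSEM trajectory with a Gaussian post-filter applied to each
#' snapshot. Fully deterministic given the configuration's seed. One row is
#' emitted per (dose, variant, iteration).
#'
#' @param config an [experiment_config].
#' @param out_dir optional directory; when given, per-iteration images
#'   (NIfTI), the metric table (CSV) and a JSON manifest with the config
#'   hash are written there.
#' @param keep_images return the reconstructed snapshots alongside the
#'   metric table (memory permitting).
#' @return list with `report` (data.frame of metrics), `phantom`,
#'   `meas_rois`, `hash`, and (optionally) `images`.
#' @export
run_experiment <- function(config, out_dir = NULL, keep_images = FALSE) {
  if (!inherits(config, "experiment_config")) {
    stop("`config` must be an experiment_config", call. = FALSE)
  }
  hash <- config_hash(config)
  ph <- generate_brain_phantom(config$size, config$spacing_mm, seed = config$seed)
  model <- system_model(dim(ph$activity$values), config$spacing_mm,
                        n_angles = config$n_angles,
                        psf_fwhm_mm = config$psf_fwhm_mm)
  meas <- place_tissue_rois(ph$rois, mode = "eroded", margin_vox = 2L)
  sim <- simulate_counts(ph$activity, model, total_counts = config$total_counts,
                         seed = config$seed)
  variants <- experiment_variants(config)
  cfg <- recon_config(n_subsets = config$n_subsets,
                      n_iterations = config$n_iterations,
                      save_every_iteration = TRUE)

  rows <- list()
  images <- list()
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), hash = hash, artifacts = list())

  for (di in seq_along(config$dose_fractions)) {
    f <- config$dose_fractions[di]
    y <- if (f < 1) thin_counts(sim$y, f, seed = config$seed + di) else sim$y
    osem_traj <- NULL
    for (v in variants) {
      if (v$name == "OSEM" || v$name == "OSEM_GF") {
        if (is.null(osem_traj)) osem_traj <- osem(y, model, cfg)
        traj <- if (v$postfilter > 0) {
          lapply(osem_traj, gaussian_postfilter, fwhm_mm = v$postfilter)
        } else {
          osem_traj
        }
      } else {
        traj <- mrg_reconstruct(y, model, ph$prior, penalty_params(beta = v$beta), cfg)
      }
      for (it in seq_along(traj)) {
        m <- phantom_metrics(traj[[it]], meas)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(dose = f, algorithm = v$name, beta = v$beta, iteration = it,
                     stringsAsFactors = FALSE),
          m)
        if (!is.null(out_dir)) {
          fn <- sprintf("recon_dose%g_%s_it%02d.nii.gz", f, v$name, it)
          write_image_nifti(traj[[it]], file.path(out_dir, fn))
          manifest$artifacts[[length(manifest$artifacts) + 1L]] <-
            list(file = fn, dose = f, algorithm = v$name, iteration = it,
                 seed = config$seed, hash = hash)
        }
      }
      if (keep_images) images[[paste(f, v$name, sep = "_")]] <- traj
    }
  }
  report <- do.call(rbind, rows)
  report$config_hash <- hash
  if (!is.null(out_dir)) {
    write.csv(report, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write_image_nifti(ph$activity, file.path(out_dir, "phantom_activity.nii.gz"))
    write_image_nifti(ph$prior, file.path(out_dir, "phantom_prior.nii.gz"))
    write_rois_nifti(ph$rois, file.path(out_dir, "phantom_labels.nii.gz"))
  }
  out <- list(report = report, phantom = ph, meas_rois = meas, hash = hash)
  if (keep_images) out$images <- images
  out
}

#' Plot the phantom metric sweep
#'
#' Figure-style panels of CRC, COV and tissue contrasts against iteration
#' number, one line per reconstruction variant, facetted by dose. Requires
#' ggplot2.
#'
#' @param report the metric table from [run_experiment()].
#' @param metrics which metric columns to show.
#' @return a ggplot object.
#' @export
plot_metric_report <- function(report, metrics = c("crc", "cov", "gm_wm", "gm_csf")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(dose = report$dose, algorithm = report$algorithm,
               iteration = report$iteration, metric = m, value = report[[m]],
               stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(metric ~ dose, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "iteration (full passes)", y = NULL)
}
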