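#' Region-of-interest statistics
#'
#' Mean, sample standard deviation (denominator `n - 1`), maximum and voxel
#' count of an image over the voxels carrying a given label.
#'
#' @param u an [image_grid].
#' @param rois a [roi_label_map] on the same grid.
#' @param label role name (e.g. `"GM"`) or integer label.
#' @return object of class `roi_stats` with fields `mean`, `sd`, `max`,
#'   `n_voxels`. `sd` is `NA` for a single-voxel region.
#' @export
roi_stats <- function(u, rois, label) {
  if (!is_image_grid(u)) stop("`u` must be an image_grid", call. = FALSE)
  if (!identical(dim(u$values), dim(rois$labels))) {
    stop("label map shape does not match the image", call. = FALSE)
  }
  mask <- roi_mask(rois, label)
  if (!any(mask)) stop("the requested label covers no voxels", call. = FALSE)
  vals <- u$values[mask]
  structure(list(mean = mean(vals),
                 sd = if (length(vals) >= 2L) sd(vals) else NA_real_,
                 max = max(vals), n_voxels = length(vals)),
            class = "roi_stats")
}

#' Build roi_stats from explicit summary values
#'
#' Mostly useful for worked examples and for metrics computed on regions
#' summarized elsewhere.
#'
#' @param mean,sd,max,n_voxels the summary values.
#' @return an object of class `roi_stats`.
#' @export
roi_stats_values <- function(mean, sd = NA_real_, max = NA_real_, n_voxels = NA_integer_) {
  structure(list(mean = mean, sd = sd, max = max, n_voxels = n_voxels),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> mean %.5g, sd %.5g, max %.5g, n %s\n",
              x$mean, x$sd, x$max, format(x$n_voxels)))
  invisible(x)
}

check_roi_stats <- function(x, arg) {
  if (!inherits(x, "roi_stats")) {
    stop(sprintf("`%s` must be a roi_stats object", arg), call. = FALSE)
  }
  invisible(TRUE)
}

#' Contrast recovery coefficient (CRC)
#'
#' `CRC = (GM_mean / WM_mean - 1) / (4 - 1)`: fraction of the true 4:1
#' gray-to-white activity ratio of the Hoffman-type phantom recovered in the
#' reconstruction. `1` is perfect recovery, `0` means no contrast.
#'
#' @param gm,wm [roi_stats] for the gray- and white-matter ROIs.
#' @return the CRC value.
#' @export
crc <- function(gm, wm) {
  check_roi_stats(gm, "gm"); check_roi_stats(wm, "wm")
  if (!is.finite(wm$mean) || wm$mean <= 0) stop("WM mean must be positive", call. = FALSE)
  (gm$mean / wm$mean - 1) / (4 - 1)
}

#' Coefficient of variation (COV)
#'
#' `COV = SD / mean` of a reference region (conventionally white matter) —
#' the relative-noise proxy. Invariant under global positive rescaling of
#' the image.
#'
#' @param region [roi_stats] of the reference region.
#' @return the COV value.
#' @export
roi_cov <- function(region) {
  check_roi_stats(region, "region")
  if (!is.finite(region$mean) || region$mean <= 0) {
    stop("region mean must be positive", call. = FALSE)
  }
  region$sd / region$mean
}

#' Tissue contrasts
#'
#' `GM-WM contrast = GM_mean / WM_mean` and
#' `GM-CSF contrast = (GM_mean - CSF_mean) / GM_mean`. On the noise-free
#' ground-truth phantom these are 4 and 1 exactly.
#'
#' @param gm,wm,csf [roi_stats] of the three tissue ROIs.
#' @return list with `gm_wm` and `gm_csf`.
#' @export
tissue_contrasts <- function(gm, wm, csf) {
  check_roi_stats(gm, "gm"); check_roi_stats(wm, "wm"); check_roi_stats(csf, "csf")
  if (wm$mean <= 0) stop("WM mean must be positive", call. = FALSE)
  if (gm$mean <= 0) stop("GM mean must be positive", call. = FALSE)
  list(gm_wm = gm$mean / wm$mean,
       gm_csf = (gm$mean - csf$mean) / gm$mean)
}

#' Contrast-to-noise ratio (CNR)
#'
#' `CNR = (GM_mean - WM_mean) / WM_SD`.
#'
#' @param gm,wm [roi_stats].
#' @return the CNR value.
#' @export
cnr <- function(gm, wm) {
  check_roi_stats(gm, "gm"); check_roi_stats(wm, "wm")
  if (!is.finite(wm$sd) || wm$sd <= 0) {
    stop("WM SD must be positive (CNR undefined for a noiseless region)", call. = FALSE)
  }
  (gm$mean - wm$mean) / wm$sd
}

#' Line profile through an image
#'
#' Samples the image by bilinear interpolation along the segment from `p0`
#' to `p1` (physical mm coordinates, `(x, y)`, origin at the centre of voxel
#' `[1, 1]`) at a uniform step. Used to extract count profiles perpendicular
#' to gray/white interfaces for edge-sharpness analysis.
#'
#' @param u an [image_grid].
#' @param p0,p1 segment endpoints in mm, inside the grid.
#' @param step_mm sampling step in mm.
#' @return object of class `line_profile` with `positions_mm` (distance along
#'   the segment) and `counts`.
#' @export
profile_extract <- function(u, p0, p1, step_mm) {
  if (!is_image_grid(u)) stop("`u` must be an image_grid", call. = FALSE)
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (length(p0) != 2L || length(p1) != 2L) stop("endpoints must be (x, y) mm", call. = FALSE)
  if (!is.finite(step_mm) || step_mm <= 0) stop("`step_mm` must be positive", call. = FALSE)
  L <- sqrt(sum((p1 - p0)^2))
  if (L <= 0) stop("degenerate segment: endpoints coincide", call. = FALSE)
  sp <- u$spacing_mm
  ny <- nrow(u$values); nx <- ncol(u$values)
  xmax <- (nx - 1) * sp[2]; ymax <- (ny - 1) * sp[1]
  for (p in list(p0, p1)) {
    if (p[1] < 0 || p[1] > xmax || p[2] < 0 || p[2] > ymax) {
      stop("profile endpoints must lie inside the grid", call. = FALSE)
    }
  }
  tvals <- seq(0, L, by = step_mm)
  if (length(tvals) < 3L) stop("profile must contain at least 3 samples", call. = FALSE)
  dir <- (p1 - p0) / L
  px <- p0[1] + tvals * dir[1]
  py <- p0[2] + tvals * dir[2]
  counts <- bilinear_sample(u$values, px / sp[2] + 1, py / sp[1] + 1)
  structure(list(positions_mm = tvals, counts = counts), class = "line_profile")
}

# bilinear interpolation at fractional (col, row) coordinates
bilinear_sample <- function(values, cx, cy) {
  ny <- nrow(values); nx <- ncol(values)
  j0 <- pmin(pmax(floor(cx), 1), nx - 1); i0 <- pmin(pmax(floor(cy), 1), ny - 1)
  fx <- cx - j0; fy <- cy - i0
  v00 <- values[cbind(i0, j0)]
  v01 <- values[cbind(i0, j0 + 1)]
  v10 <- values[cbind(i0 + 1, j0)]
  v11 <- values[cbind(i0 + 1, j0 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Edge sharpness index
#'
#' Maximum slope of a count profile, expressed as percent of the profile's
#' maximum count per millimetre: `100 * max|diff(counts)| / diff(positions)
#' / max(counts)`. Higher values indicate sharper tissue interfaces.
#'
#' @param profile a `line_profile` (from [profile_extract()]) or any list
#'   with `positions_mm` and `counts`.
#' @return the sharpness index in percent per mm.
#' @export
edge_sharpness <- function(profile) {
  pos <- profile$positions_mm; cts <- profile$counts
  if (length(pos) < 3L) stop("profile must contain at least 3 samples", call. = FALSE)
  if (any(diff(pos) <= 0)) stop("profile positions must be strictly increasing", call. = FALSE)
  mx <- max(cts)
  if (mx <= 0) stop("profile maximum must be positive", call. = FALSE)
  slopes <- abs(diff(cts)) / diff(pos)
  100 * max(slopes) / mx
}

#' Lesion-to-background ratios
#'
#' The four lesion conspicuity metrics used for hypermetabolic brain
#' lesions, computed from lesion and background region statistics (on SUV
#' images where calibration is available; every ratio is invariant to the
#' SUV scale factor, so activity values are exact surrogates):
#' `SBR = max_lesion / mean_bg`, `SNR = max_lesion / SD_bg`,
#' `CBR = (mean_lesion - mean_bg) / mean_bg`,
#' `CNR = (mean_lesion - mean_bg) / SD_bg`.
#'
#' @param lesion,background [roi_stats].
#' @return list with `sbr`, `snr`, `cbr`, `cnr`.
#' @export
lesion_ratios <- function(lesion, background) {
  check_roi_stats(lesion, "lesion"); check_roi_stats(background, "background")
  if (!is.finite(background$mean) || background$mean <= 0) {
    stop("background mean must be positive", call. = FALSE)
  }
  if (!is.finite(background$sd) || background$sd <= 0) {
    stop("background SD must be positive", call. = FALSE)
  }
  list(sbr = lesion$max / background$mean,
       snr = lesion$max / background$sd,
       cbr = (lesion$mean - background$mean) / background$mean,
       cnr = (lesion$mean - background$mean) / background$sd)
}

#' SUVR and target-region CNR
#'
#' Standardized uptake value ratio of a target region relative to a
#' reference region (`SUVR = target_mean / reference_mean`, e.g. putamen
#' over cerebellum), and the contrast-to-noise ratio of the target against a
#' noise region on the SUVR-scaled image:
#' `CNR = (SUVR_target - SUVR_noise) / SUVR_SD_noise`
#' (the reference scaling cancels in the CNR).
#'
#' @param target,reference,noise_region [roi_stats].
#' @return list with `suvr` and `cnr`.
#' @export
suvr_cnr <- function(target, reference, noise_region) {
  check_roi_stats(target, "target"); check_roi_stats(reference, "reference")
  check_roi_stats(noise_region, "noise_region")
  if (!is.finite(reference$mean) || reference$mean <= 0) {
    stop("reference mean must be positive", call. = FALSE)
  }
  if (!is.finite(noise_region$sd) || noise_region$sd <= 0) {
    stop("noise region SD must be positive", call. = FALSE)
  }
  suvr <- target$mean / reference$mean
  list(suvr = suvr,
       cnr = (target$mean - noise_region$mean) / noise_region$sd)
}

#' Phantom image-quality metric panel
#'
#' Convenience wrapper computing the full phantom metric set (CRC, WM COV,
#' GM-WM and GM-CSF contrast, CNR) for one reconstruction against a
#' measurement ROI map.
#'
#' @param u reconstructed [image_grid].
#' @param meas_rois measurement ROI map with `GM`, `WM`, `CSF` roles (see
#'   [place_tissue_rois()]).
#' @return one-row `data.frame` with columns `crc`, `cov`, `gm_wm`,
#'   `gm_csf`, `cnr`.
#' @export
phantom_metrics <- function(u, meas_rois) {
  gm <- roi_stats(u, meas_rois, "GM")
  wm <- roi_stats(u, meas_rois, "WM")
  csf <- roi_stats(u, meas_rois, "CSF")
  tc <- tissue_contrasts(gm, wm, csf)
  data.frame(crc = crc(gm, wm), cov = roi_cov(wm),
             gm_wm = tc$gm_wm, gm_csf = tc$gm_csf,
             cnr = if (is.finite(wm$sd) && wm$sd > 0) cnr(gm, wm) else NA_real_)
}
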