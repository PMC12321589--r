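#' Integer-labelled region map
#'
#' A tissue / region-of-interest partition aligned with an [image_grid]: every
#' voxel carries exactly one integer label, and a legend maps label values to
#' roles (`background_air`, `CSF`, `WM`, `GM`, `lesion_k`, or user-defined ROI
#' roles such as `reference`).
#'
#' @param labels integer matrix of labels.
#' @param legend named integer vector: `names(legend)` are roles, values are
#'   the label integers appearing in `labels`.
#' @param spacing_mm voxel size in mm (as for [image_grid]).
#' @return an object of class `roi_label_map`.
#' @export
roi_label_map <- function(labels, legend, spacing_mm = c(1, 1)) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  legend <- vapply(legend, as.integer, integer(1))
  if (is.null(names(legend)) || any(!nzchar(names(legend)))) {
    stop("`legend` must be a named vector (role -> label)", call. = FALSE)
  }
  if (anyDuplicated(legend)) stop("legend labels must be unique", call. = FALSE)
  present <- sort(unique(as.vector(labels)))
  if (!all(present %in% legend)) {
    stop("every label in the map must appear in the legend", call. = FALSE)
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  structure(list(labels = labels, legend = legend, spacing_mm = spacing_mm),
            class = "roi_label_map")
}

#' @export
print.roi_label_map <- function(x, ...) {
  d <- dim(x$labels)
  counts <- vapply(x$legend, function(l) sum(x$labels == l), integer(1))
  cat(sprintf("<roi_label_map> %d x %d voxels\n", d[1], d[2]))
  for (r in names(x$legend)) {
    cat(sprintf("  %-16s label %2d  (%d voxels)\n", r, x$legend[[r]], counts[[r]]))
  }
  invisible(x)
}

roi_mask <- function(rois, role) {
  if (is.character(role)) {
    if (!role %in% names(rois$legend)) {
      stop(sprintf("role '%s' not present in the label legend", role), call. = FALSE)
    }
    lab <- rois$legend[[role]]
  } else {
    lab <- as.integer(role)
    if (!lab %in% rois$legend) {
      stop(sprintf("label %d not present in the label legend", lab), call. = FALSE)
    }
  }
  rois$labels == lab
}

# Default T1-like prior intensities: in T1-weighted brain MR, white matter is
# brightest, gray matter intermediate, CSF dark.
default_prior_intensities <- function() {
  c(background_air = 0, CSF = 0.1, WM = 1.0, GM = 0.6)
}

# Hoffman-type activity levels (relative units): GM:WM:CSF = 4:1:0.
default_activity_levels <- function() {
  c(background_air = 0, CSF = 0, WM = 1, GM = 4)
}

#' Generate a Hoffman-type digital brain phantom
#'
#' Builds a 2-D single-slice digital brain phantom emulating a Hoffman brain
#' insert: an elliptical brain with an outer CSF rim, a convoluted cortical
#' gray-matter ribbon, a white-matter core and two ventricles, with activity
#' levels GM:WM:CSF = 4:1:0 exactly. The matched anatomical prior is a
#' T1-like image (WM brightest, then GM, then CSF) sharing every tissue
#' boundary with the activity image. The gray/white interface carries a
#' sinusoidal "gyral" perturbation whose harmonic phases are drawn from
#' `seed`, so different seeds vary the interface geometry but never the
#' tissue activity levels, and the same seed reproduces the phantom
#' bit-for-bit.
#'
#' @param size grid shape `(ny, nx)` (a single number is square); at least
#'   32 voxels per axis.
#' @param spacing_mm voxel size in mm (default 1.2, a typical brain PET
#'   reconstruction voxel).
#' @param seed integer seed controlling the gyral phases.
#' @param activity_levels named vector of activity per role (defaults 4:1:0).
#' @param prior_intensities named vector of prior intensity per role.
#' @return list with `activity` and `prior` ([image_grid]s) and `rois`
#'   ([roi_label_map]).
#' @export
generate_brain_phantom <- function(size = c(128, 128), spacing_mm = 1.2, seed = 1,
                                   activity_levels = default_activity_levels(),
                                   prior_intensities = default_prior_intensities()) {
  size <- as.integer(size)
  if (length(size) == 1L) size <- rep(size, 2L)
  if (length(size) != 2L || any(size < 32L)) {
    stop("`size` must give at least 32 voxels per axis (too small to contain the brain geometry)",
         call. = FALSE)
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  ny <- size[1]; nx <- size[2]

  # gyral perturbation: fixed harmonics, seed-dependent phases
  ph <- with_seed(seed, runif(3, 0, 2 * pi))

  # physical coordinates centred on the grid centre
  xs <- (seq_len(nx) - (nx + 1) / 2) * spacing_mm[2]
  ys <- (seq_len(ny) - (ny + 1) / 2) * spacing_mm[1]
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)

  ax <- 0.42 * nx * spacing_mm[2]   # brain semi-axes
  ay <- 0.46 * ny * spacing_mm[1]
  rho <- sqrt((X / ax)^2 + (Y / ay)^2)
  theta <- atan2(Y / ay, X / ax)

  # normalized radii of the tissue interfaces
  r_csf_in <- 0.93                              # outer CSF rim: (r_csf_in, 1]
  gyr <- 0.055 * sin(7 * theta + ph[1]) +
         0.040 * sin(11 * theta + ph[2]) +
         0.025 * sin(17 * theta + ph[3])
  r_gw <- 0.66 + gyr                            # gray/white interface

  labels <- matrix(0L, ny, nx)                  # background air
  labels[rho <= 1] <- 1L                        # CSF rim
  labels[rho <= r_csf_in] <- 3L                 # GM ribbon
  labels[rho <= r_gw] <- 2L                     # WM core

  # two ventricles (CSF) inside the WM core
  for (sgn in c(-1, 1)) {
    vx <- sgn * 0.16 * ax; vy <- -0.05 * ay
    vr <- sqrt(((X - vx) / (0.10 * ax))^2 + ((Y - vy) / (0.22 * ay))^2)
    labels[vr <= 1] <- 1L
  }

  legend <- c(background_air = 0L, CSF = 1L, WM = 2L, GM = 3L)
  for (r in c("CSF", "WM", "GM")) {
    if (!any(labels == legend[[r]])) {
      stop(sprintf("grid too small: tissue '%s' is empty", r), call. = FALSE)
    }
  }

  lut <- function(tbl) {
    v <- matrix(0, ny, nx)
    for (r in names(legend)) v[labels == legend[[r]]] <- tbl[[r]]
    v
  }
  list(
    activity = image_grid(lut(activity_levels), spacing_mm, nonnegative = TRUE),
    prior    = image_grid(lut(prior_intensities), spacing_mm),
    rois     = roi_label_map(labels, legend, spacing_mm)
  )
}

#' Focal lesion specification
#'
#' Describes a disk-shaped lesion to insert into a phantom: its centre (grid
#' coordinates), radius in mm, and independent multipliers for the PET
#' activity and the MR prior intensity relative to the host tissue. Setting
#' the two multipliers independently creates PET/MR-mismatched fixtures, e.g.
#' a hypermetabolic lymphoma-like lesion (`pet_multiplier > 1`) or a PET-cold
#' but MR-bright angioma-like lesion (`pet_multiplier < 1`,
#' `mr_multiplier > 1`).
#'
#' @param center lesion centre as `(row, col)` voxel coordinates.
#' @param radius_mm lesion radius in mm.
#' @param pet_multiplier activity multiplier, `>= 0`.
#' @param mr_multiplier prior intensity multiplier, `>= 0`.
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radius_mm, pet_multiplier = 1, mr_multiplier = 1) {
  center <- as.numeric(center)
  if (length(center) != 2L || any(!is.finite(center))) {
    stop("`center` must be (row, col) grid coordinates", call. = FALSE)
  }
  if (!is.finite(radius_mm) || radius_mm <= 0) stop("`radius_mm` must be positive", call. = FALSE)
  if (pet_multiplier < 0 || mr_multiplier < 0) {
    stop("lesion multipliers must be nonnegative", call. = FALSE)
  }
  structure(list(center = center, radius_mm = radius_mm,
                 pet_multiplier = pet_multiplier, mr_multiplier = mr_multiplier),
            class = "lesion_spec")
}

#' Insert a focal lesion into a phantom
#'
#' Multiplies the activity and prior intensity inside a disk by the lesion's
#' PET and MR multipliers and adds a new lesion label to the label map. The
#' inputs are not modified. The lesion must lie entirely inside the brain
#' (no voxel of the disk may be background air).
#'
#' @param activity,prior [image_grid]s from [generate_brain_phantom()].
#' @param rois the matching [roi_label_map].
#' @param spec a [lesion_spec].
#' @return list with modified `activity`, `prior`, `rois`, and `role`, the
#'   legend role of the new lesion label.
#' @export
insert_lesion <- function(activity, prior, rois, spec) {
  if (!inherits(spec, "lesion_spec")) stop("`spec` must be a lesion_spec", call. = FALSE)
  stopifnot_same_grid(activity, prior)
  ny <- nrow(rois$labels); nx <- ncol(rois$labels)
  sp <- rois$spacing_mm
  X <- matrix((seq_len(nx) - spec$center[2]) * sp[2], ny, nx, byrow = TRUE)
  Y <- matrix((seq_len(ny) - spec$center[1]) * sp[1], ny, nx)
  mask <- (X^2 + Y^2) <= spec$radius_mm^2
  if (!any(mask)) stop("lesion disk contains no voxels at this grid resolution", call. = FALSE)
  if (any(rois$labels[mask] == rois$legend[["background_air"]])) {
    stop("lesion extends outside the brain mask", call. = FALSE)
  }

  av <- activity$values; pv <- prior$values
  av[mask] <- av[mask] * spec$pet_multiplier
  pv[mask] <- pv[mask] * spec$mr_multiplier

  k <- sum(startsWith(names(rois$legend), "lesion_")) + 1L
  new_label <- max(rois$legend) + 1L
  role <- sprintf("lesion_%d", k)
  legend <- c(rois$legend, stats::setNames(new_label, role))
  labels <- rois$labels
  labels[mask] <- new_label

  list(activity = image_grid(av, activity$spacing_mm, nonnegative = TRUE),
       prior = image_grid(pv, prior$spacing_mm),
       rois = roi_label_map(labels, legend, sp),
       role = role)
}

# 3x3 binary erosion with FALSE padding
erode3x3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  out <- m
  for (di in -1:1) for (dj in -1:1) {
    out <- out & pad[(2 + di):(ny + 1 + di), (2 + dj):(nx + 1 + dj)]
  }
  out
}

# Chessboard distance-to-boundary (in voxels) inside a binary mask, by
# iterated erosion: depth 1 at the mask boundary, increasing inwards.
mask_depth <- function(m) {
  depth <- matrix(0L, nrow(m), ncol(m))
  cur <- m
  while (any(cur)) {
    depth[cur] <- depth[cur] + 1L
    cur <- erode3x3(cur)
  }
  depth
}

#' Place measurement ROIs inside each tissue class
#'
#' Builds a measurement ROI map for quantitative analysis, emulating manually
#' drawn tissue ROIs placed well inside each compartment. Two modes:
#' `"eroded"` keeps every voxel of the tissue at least `margin_vox` voxels
#' away from its boundary (large, stable samples for noise statistics);
#' `"disk"` places one circular ROI per tissue at the deepest interior point
#' (the maximum of the distance-to-boundary transform), with the radius
#' shrunk if needed so the disk stays inside the tissue.
#'
#' @param rois a [roi_label_map] with GM/WM/CSF labels.
#' @param roles tissue roles to place ROIs for.
#' @param mode `"eroded"` or `"disk"`.
#' @param margin_vox erosion margin in voxels (eroded mode).
#' @param radius_mm requested disk radius in mm (disk mode).
#' @return a [roi_label_map] with one label per requested role (same role
#'   names); voxels outside every ROI carry the `outside` label 0.
#' @export
place_tissue_rois <- function(rois, roles = c("GM", "WM", "CSF"),
                              mode = c("eroded", "disk"),
                              margin_vox = 2L, radius_mm = 4) {
  mode <- match.arg(mode)
  ny <- nrow(rois$labels); nx <- ncol(rois$labels)
  sp <- rois$spacing_mm
  out <- matrix(0L, ny, nx)
  legend <- c(outside = 0L)
  for (k in seq_along(roles)) {
    m <- roi_mask(rois, roles[k])
    depth <- mask_depth(m)
    if (mode == "eroded") {
      sel <- depth > margin_vox
      if (!any(sel)) sel <- depth == max(depth)  # degenerate thin tissue
    } else {
      pk <- which(depth == max(depth))[1]
      ci <- (pk - 1L) %% ny + 1L
      cj <- (pk - 1L) %/% ny + 1L
      r_fit <- min(radius_mm, (depth[pk] - 1) * min(sp))
      r_fit <- max(r_fit, min(sp) / 2)          # at least the centre voxel
      X <- matrix((seq_len(nx) - cj) * sp[2], ny, nx, byrow = TRUE)
      Y <- matrix((seq_len(ny) - ci) * sp[1], ny, nx)
      sel <- (X^2 + Y^2) <= r_fit^2 & m
    }
    out[sel] <- k
    legend <- c(legend, stats::setNames(k, roles[k]))
  }
  roi_label_map(out, legend, sp)
}
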