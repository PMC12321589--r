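#' Parallel-beam PET system model
#'
#' Projection geometry and resolution model connecting an image to its
#' sinogram. The projector is a 2-D parallel-beam system matrix with exact
#' ray-pixel intersection lengths (in mm), with projection angles evenly
#' spaced over 180 degrees. Resolution is modelled as an isotropic image-space
#' Gaussian point spread function applied before projection (and, being
#' self-adjoint, after back-projection), so forward and back projection remain
#' exact adjoints. Optional per-LOR multiplicative normalization factors
#' (attenuation/sensitivity surrogates) and an additive background (scatter +
#' randoms surrogate) complete the affine count model
#' `ybar = n * (A blur(u)) + r`.
#'
#' @param image_shape image grid shape `(ny, nx)`.
#' @param spacing_mm image voxel size in mm.
#' @param n_angles number of projection angles over `[0, pi)`.
#' @param n_radial_bins number of radial bins; default covers the image
#'   diagonal (an odd count, centred on the scanner axis).
#' @param bin_spacing_mm radial bin spacing in mm; default the voxel size.
#' @param psf_fwhm_mm image-space PSF width, mm; `0` disables resolution
#'   modelling.
#' @param normalization per-LOR positive factors, as an `(angle, bin)` matrix
#'   or a scalar; default 1.
#' @param background per-LOR nonnegative additive expectations; default 0.
#' @return an object of class `system_model`. The sparse system matrix and
#'   per-subset structures are cached inside the object.
#' @export
system_model <- function(image_shape, spacing_mm = 1.2,
                         n_angles = 120, n_radial_bins = NULL,
                         bin_spacing_mm = NULL, psf_fwhm_mm = 0,
                         normalization = 1, background = 0) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) == 1L) image_shape <- rep(image_shape, 2L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  if (any(spacing_mm <= 0)) stop("`spacing_mm` must be positive", call. = FALSE)
  n_angles <- as.integer(n_angles)
  if (n_angles < 1L) stop("`n_angles` must be >= 1", call. = FALSE)
  ny <- image_shape[1]; nx <- image_shape[2]
  if (is.null(bin_spacing_mm)) bin_spacing_mm <- min(spacing_mm)
  if (is.null(n_radial_bins)) {
    diag_mm <- sqrt((nx * spacing_mm[2])^2 + (ny * spacing_mm[1])^2)
    n_radial_bins <- 2L * ceiling(diag_mm / bin_spacing_mm / 2) + 1L
  }
  n_radial_bins <- as.integer(n_radial_bins)
  if (psf_fwhm_mm < 0) stop("`psf_fwhm_mm` must be nonnegative", call. = FALSE)

  angles <- seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  offsets <- (seq_len(n_radial_bins) - (n_radial_bins + 1) / 2) * bin_spacing_mm

  trip <- .siddon_weights(nx, ny, spacing_mm[2], spacing_mm[1], angles, offsets)
  A <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(n_angles * n_radial_bins, ny * nx))

  n_lor <- n_angles * n_radial_bins
  norm_vec <- as.vector(if (is.matrix(normalization)) t(normalization) else rep(normalization, length.out = n_lor))
  if (length(norm_vec) != n_lor || any(norm_vec <= 0)) {
    stop("`normalization` must be positive, one value per LOR (or scalar)", call. = FALSE)
  }
  bg_vec <- as.vector(if (is.matrix(background)) t(background) else rep(background, length.out = n_lor))
  if (length(bg_vec) != n_lor || any(bg_vec < 0)) {
    stop("`background` must be nonnegative, one value per LOR (or scalar)", call. = FALSE)
  }

  m <- structure(list(
    image_shape = image_shape, spacing_mm = spacing_mm,
    n_angles = n_angles, n_radial_bins = n_radial_bins,
    bin_spacing_mm = bin_spacing_mm, psf_fwhm_mm = psf_fwhm_mm,
    angles = angles, offsets = offsets,
    A = A, normalization = norm_vec, background = bg_vec,
    cache = new.env(parent = emptyenv())
  ), class = "system_model")

  sens <- back_project_vec(rep(1, n_lor), m)  # B A^T n
  m$cache$sensitivity <- sens
  m$cache$fov <- sens > 1e-9 * max(sens)
  m
}

#' @export
print.system_model <- function(x, ...) {
  cat(sprintf("<system_model> %d x %d image @ %.3g mm | %d angles x %d bins @ %.3g mm | PSF %.3g mm FWHM\n",
              x$image_shape[1], x$image_shape[2], min(x$spacing_mm),
              x$n_angles, x$n_radial_bins, x$bin_spacing_mm, x$psf_fwhm_mm))
  invisible(x)
}

#' Sinogram container
#'
#' Counts (or expected counts) indexed by projection angle and radial bin,
#' plus the dose fraction the data represent (1 = full acquisition; binomial
#' thinning reduces it multiplicatively).
#'
#' @param values numeric `(n_angles, n_radial_bins)` matrix, nonnegative.
#' @param dose_fraction value in `(0, 1]`.
#' @return an object of class `sinogram`.
#' @export
sinogram <- function(values, dose_fraction = 1) {
  if (!is.matrix(values) || any(!is.finite(values)) || any(values < 0)) {
    stop("sinogram values must be a finite nonnegative matrix", call. = FALSE)
  }
  if (dose_fraction <= 0 || dose_fraction > 1) {
    stop("`dose_fraction` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(values = values, dose_fraction = dose_fraction), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d bins, total %.6g, dose fraction %.4g\n",
              nrow(x$values), ncol(x$values), sum(x$values), x$dose_fraction))
  invisible(x)
}

# sinogram matrix [angle, bin] <-> ray vector in angle-major order
sino_to_vec <- function(values) as.vector(t(values))
vec_to_sino <- function(v, model) {
  matrix(v, nrow = model$n_angles, ncol = model$n_radial_bins, byrow = TRUE)
}

check_model_grid <- function(u, model) {
  if (!identical(dim(u$values), as.integer(model$image_shape))) {
    stop("image shape does not match the system model", call. = FALSE)
  }
  if (max(abs(u$spacing_mm - model$spacing_mm)) > 1e-9) {
    stop("image spacing does not match the system model", call. = FALSE)
  }
  invisible(TRUE)
}

blur_model <- function(values, model) {
  gauss_blur_matrix(values, model$psf_fwhm_mm, model$spacing_mm)
}

# linear part of the forward model applied to an image matrix -> ray vector
forward_project_vec <- function(values, model) {
  as.vector(model$A %*% as.vector(blur_model(values, model)))
}

# adjoint of the linear part applied to a ray vector -> image matrix
back_project_vec <- function(rayvec, model) {
  img <- matrix(as.vector(Matrix::crossprod(model$A, rayvec)),
                model$image_shape[1], model$image_shape[2])
  blur_model(img, model)
}

#' Forward projection
#'
#' Computes the expected sinogram `ybar = n * (A blur(u)) + r`, where `A` is
#' the intersection-length system matrix, `blur` the image-space PSF, `n` the
#' per-LOR normalization and `r` the additive background. Linear in `u` when
#' `r = 0`.
#'
#' @param u nonnegative [image_grid] on the model's grid.
#' @param model a [system_model].
#' @return a [sinogram] of expected counts (dose fraction 1).
#' @export
forward_project <- function(u, model) {
  if (!is_image_grid(u)) stop("`u` must be an image_grid", call. = FALSE)
  check_model_grid(u, model)
  if (any(u$values < 0)) stop("activity image must be nonnegative", call. = FALSE)
  v <- model$normalization * forward_project_vec(u$values, model) + model$background
  sinogram(vec_to_sino(v, model), dose_fraction = 1)
}

#' Back projection (adjoint of the forward projection)
#'
#' Applies the exact adjoint of the linear part of the forward model:
#' `blur(A^T (n * s))`. Satisfies `<A u, s> = <u, A^T s>` for every image `u`
#' and sinogram `s`. Back-projecting a unit sinogram with unit normalization
#' yields the sensitivity image, strictly positive inside the field of view.
#'
#' @param s a [sinogram] (any nonnegative values).
#' @param model a [system_model].
#' @return an [image_grid].
#' @export
back_project <- function(s, model) {
  if (!inherits(s, "sinogram")) stop("`s` must be a sinogram", call. = FALSE)
  if (!identical(dim(s$values), c(model$n_angles, model$n_radial_bins))) {
    stop("sinogram shape does not match the system model", call. = FALSE)
  }
  img <- back_project_vec(model$normalization * sino_to_vec(s$values), model)
  image_grid(img, model$spacing_mm)
}

#' Sensitivity image
#'
#' `s_j = blur(A^T n)`: the expected number of detected events per unit
#' activity in voxel `j`. Used as the EM update denominator.
#'
#' @param model a [system_model].
#' @return an [image_grid].
#' @export
sensitivity_image <- function(model) {
  image_grid(model$cache$sensitivity, model$spacing_mm)
}

#' Simulate Poisson counts
#'
#' Draws independent Poisson counts with the given expected sinogram as mean.
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param ybar expected-count [sinogram] (nonnegative).
#' @param seed integer seed.
#' @return an integer-valued counts [sinogram].
#' @export
add_poisson_noise <- function(ybar, seed) {
  if (!inherits(ybar, "sinogram")) stop("`ybar` must be a sinogram", call. = FALSE)
  if (any(ybar$values < 0)) stop("expected counts must be nonnegative", call. = FALSE)
  v <- with_seed(seed, rpois(length(ybar$values), lambda = ybar$values))
  sinogram(matrix(as.numeric(v), nrow(ybar$values), ncol(ybar$values)),
           dose_fraction = ybar$dose_fraction)
}

#' Binomial count thinning (dose reduction)
#'
#' Randomly keeps each recorded event with probability `fraction`
#' (element-wise `Binomial(y_i, fraction)`), which is statistically equivalent
#' to having acquired that fraction of the listmode events. Thinning a
#' Poisson sinogram with mean `ybar` yields Poisson counts with mean
#' `fraction * ybar`. The sinogram's dose fraction is updated
#' multiplicatively.
#'
#' @param y integer-count [sinogram].
#' @param fraction retention probability in `(0, 1]`.
#' @param seed integer seed.
#' @return the thinned counts [sinogram].
#' @export
thin_counts <- function(y, fraction, seed) {
  if (!inherits(y, "sinogram")) stop("`y` must be a sinogram", call. = FALSE)
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (any(abs(y$values - round(y$values)) > 1e-9)) {
    stop("`y` must contain integer counts", call. = FALSE)
  }
  if (fraction == 1) return(y)
  v <- with_seed(seed, rbinom(length(y$values), size = as.integer(round(y$values)),
                              prob = fraction))
  sinogram(matrix(as.numeric(v), nrow(y$values), ncol(y$values)),
           dose_fraction = y$dose_fraction * fraction)
}

#' Simulate a counts sinogram from an activity image
#'
#' Convenience wrapper for the full acquisition emulation: forward-project
#' the activity, rescale the expectation so the full-dose acquisition totals
#' `total_counts` expected events, and draw Poisson counts. Lower doses are
#' then obtained with [thin_counts()].
#'
#' @param activity nonnegative [image_grid].
#' @param model a [system_model].
#' @param total_counts expected total counts at full dose (default 2e6, a
#'   realistic single-slice count level for a 10-minute brain acquisition).
#' @param seed integer seed for the Poisson draw.
#' @return list with `y` (counts [sinogram]), `ybar` (scaled expectation) and
#'   `scale` (the calibration factor applied to the forward projection).
#' @export
simulate_counts <- function(activity, model, total_counts = 2e6, seed = 1) {
  ybar <- forward_project(activity, model)
  tot <- sum(ybar$values)
  if (tot <= 0) stop("activity projects to an all-zero sinogram", call. = FALSE)
  sc <- total_counts / tot
  ybar$values <- ybar$values * sc
  list(y = add_poisson_noise(ybar, seed), ybar = ybar, scale = sc)
}
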