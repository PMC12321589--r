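#' Parallel Level Sets penalty parameters
#'
#' Bundles the three tunables of the anatomically guided penalty: the
#' penalization strength `beta` (user-adjustable; controls overall
#' smoothness), the integrand smoothing parameter `alpha` (keeps the penalty
#' differentiable where the image gradient vanishes), and the edge threshold
#' `eta` (gradient magnitudes in the prior well below `eta` are treated as
#' noise rather than anatomy). `alpha` and `eta` may be left `NULL`, in which
#' case data-driven defaults are resolved at reconstruction time:
#' `eta = 0.05 * q99(|grad v|)` and `alpha = 0.01 * max(u0)` (per mm).
#'
#' `beta = 0` switches the penalty off entirely, reducing the guided
#' reconstruction exactly to OSEM.
#'
#' @param beta penalization strength, `>= 0`.
#' @param alpha smoothing parameter, `> 0`, or `NULL` for the default.
#' @param eta edge threshold, `> 0`, or `NULL` for the default.
#' @return an object of class `penalty_params`.
#' @export
penalty_params <- function(beta, alpha = NULL, eta = NULL) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0) {
    stop("`beta` must be a single nonnegative number", call. = FALSE)
  }
  if (!is.null(alpha) && (!is.finite(alpha) || alpha <= 0)) {
    stop("`alpha` must be strictly positive", call. = FALSE)
  }
  if (!is.null(eta) && (!is.finite(eta) || eta <= 0)) {
    stop("`eta` must be strictly positive", call. = FALSE)
  }
  structure(list(beta = beta, alpha = alpha, eta = eta), class = "penalty_params")
}

default_eta <- function(prior) {
  g <- grad_image(prior$values, prior$spacing_mm)
  gm <- sqrt(g$gx^2 + g$gy^2)
  e <- 0.05 * as.numeric(quantile(gm[gm > 0], 0.99))
  if (!is.finite(e) || e <= 0) e <- 1e-3
  e
}

default_alpha <- function(u0_scale) {
  a <- 0.01 * u0_scale
  if (!is.finite(a) || a <= 0) a <- 1e-6
  a
}

#' Normalized gradient field of the anatomical prior
#'
#' Computes `xi = grad(v) / sqrt(|grad v|^2 + eta^2)`, the direction field of
#' the MR prior with magnitudes rescaled so that `|xi| < 1` strictly
#' everywhere (`eta > 0`). At strong prior edges `|xi|` approaches 1; where
#' the prior is locally constant `xi = 0` and the penalty falls back to an
#' edge-agnostic smoothness prior.
#'
#' @param v prior [image_grid].
#' @param eta edge threshold, `> 0`.
#' @return object of class `ngf` with per-voxel components `xi_x`, `xi_y`
#'   and the grid metadata.
#' @export
normalized_gradient_field <- function(v, eta) {
  if (!is_image_grid(v)) stop("`v` must be an image_grid", call. = FALSE)
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0) {
    stop("`eta` must be strictly positive", call. = FALSE)
  }
  g <- grad_image(v$values, v$spacing_mm)
  denom <- sqrt(g$gx^2 + g$gy^2 + eta^2)
  structure(list(xi_x = g$gx / denom, xi_y = g$gy / denom,
                 spacing_mm = v$spacing_mm, eta = eta),
            class = "ngf")
}

# A zero guidance field on the grid of image u (reduces PLS to smoothed TV).
zero_ngf <- function(u) {
  z <- matrix(0, nrow(u$values), ncol(u$values))
  structure(list(xi_x = z, xi_y = z, spacing_mm = u$spacing_mm, eta = Inf),
            class = "ngf")
}

check_ngf_grid <- function(u, xi) {
  if (!identical(dim(u$values), dim(xi$xi_x))) {
    stop("normalized gradient field shape does not match the image", call. = FALSE)
  }
  invisible(TRUE)
}

# per-voxel integrand pieces shared by penalty value and gradient
pls_terms <- function(u, xi, alpha) {
  g <- grad_image(u$values, u$spacing_mm)
  dot <- g$gx * xi$xi_x + g$gy * xi$xi_y
  root <- sqrt(alpha^2 + g$gx^2 + g$gy^2 - dot^2)
  list(g = g, dot = dot, root = root)
}

#' Parallel Level Sets penalty value
#'
#' The anatomical smoothness penalty
#' `P(u, v) = sum_x sqrt(alpha^2 + |grad u|^2 - (grad u . xi)^2)`,
#' a voxel-wise discretization of the PLS functional: image gradients
#' parallel to the prior's normalized gradient field `xi` are (up to the
#' `|xi| < 1` ceiling) exempt from penalization, so edges shared with the MR
#' prior survive while unmatched gradients are smoothed as in (smoothed)
#' total variation. With `xi = 0` the value equals the smoothed TV penalty
#' `sum sqrt(alpha^2 + |grad u|^2)` exactly.
#'
#' @param u [image_grid] being reconstructed.
#' @param xi [normalized_gradient_field()] of the prior.
#' @param alpha smoothing parameter, `> 0`.
#' @return the scalar penalty value (always `>= n_voxels * alpha`).
#' @export
pls_penalty <- function(u, xi, alpha) {
  if (!is_image_grid(u)) stop("`u` must be an image_grid", call. = FALSE)
  if (!inherits(xi, "ngf")) stop("`xi` must be a normalized gradient field", call. = FALSE)
  check_ngf_grid(u, xi)
  if (!is.finite(alpha) || alpha <= 0) stop("`alpha` must be strictly positive", call. = FALSE)
  sum(pls_terms(u, xi, alpha)$root)
}

#' Gradient of the Parallel Level Sets penalty
#'
#' Analytic derivative of [pls_penalty()] with respect to the image:
#' `dP/du = G^T [ (grad u - xi (grad u . xi)) / sqrt(alpha^2 + |grad u|^2 - (grad u . xi)^2) ]`
#' where `G^T` is the exact transpose of the package's discrete gradient
#' operator (i.e. the negative discrete divergence), so the analytic gradient
#' is consistent with the discretized penalty to machine precision.
#'
#' @inheritParams pls_penalty
#' @return an [image_grid] holding the per-voxel derivative.
#' @export
pls_gradient <- function(u, xi, alpha) {
  if (!is_image_grid(u)) stop("`u` must be an image_grid", call. = FALSE)
  if (!inherits(xi, "ngf")) stop("`xi` must be a normalized gradient field", call. = FALSE)
  check_ngf_grid(u, xi)
  if (!is.finite(alpha) || alpha <= 0) stop("`alpha` must be strictly positive", call. = FALSE)
  tm <- pls_terms(u, xi, alpha)
  wx <- (tm$g$gx - xi$xi_x * tm$dot) / tm$root
  wy <- (tm$g$gy - xi$xi_y * tm$dot) / tm$root
  image_grid(grad_adjoint(wx, wy, u$spacing_mm), u$spacing_mm)
}
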