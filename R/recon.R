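#' Reconstruction configuration
#'
#' Iteration bookkeeping follows the clinical convention: one "iteration" is
#' a full pass over all subsets, and per-iteration snapshots can be retained
#' (routine brain protocols save every iteration of a 20-subset, 6-8
#' iteration run). Projection angles are assigned to subsets by
#' `angle index mod n_subsets` (interleaved; subsets may differ by one angle
#' when the counts do not divide), and subsets are visited in bit-reversed
#' order for balanced angular coverage.
#'
#' @param n_subsets number of ordered subsets (`1` gives MLEM).
#' @param n_iterations number of full iterations.
#' @param save_every_iteration keep a snapshot after every full iteration
#'   (otherwise only the final image is returned).
#' @param postfilter_fwhm_mm Gaussian post-filter applied to returned
#'   snapshots (OSEM convention); `0` disables it.
#' @param epsilon_floor lower clamp for the penalized update denominator,
#'   as a fraction of the subset sensitivity.
#' @return an object of class `recon_config`.
#' @export
recon_config <- function(n_subsets = 20L, n_iterations = 8L,
                         save_every_iteration = TRUE,
                         postfilter_fwhm_mm = 0, epsilon_floor = 1e-3) {
  n_subsets <- as.integer(n_subsets); n_iterations <- as.integer(n_iterations)
  if (n_subsets < 1L) stop("`n_subsets` must be >= 1", call. = FALSE)
  if (n_iterations < 1L) stop("`n_iterations` must be >= 1", call. = FALSE)
  if (postfilter_fwhm_mm < 0) stop("`postfilter_fwhm_mm` must be nonnegative", call. = FALSE)
  if (epsilon_floor <= 0 || epsilon_floor >= 1) {
    stop("`epsilon_floor` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(n_subsets = n_subsets, n_iterations = n_iterations,
                 save_every_iteration = isTRUE(save_every_iteration),
                 postfilter_fwhm_mm = postfilter_fwhm_mm,
                 epsilon_floor = epsilon_floor),
            class = "recon_config")
}

# bit-reversed visiting order of 0..(n-1), truncated to values < n
bit_reversed_order <- function(n) {
  if (n == 1L) return(1L)
  nb <- ceiling(log2(n))
  full <- 0:(2^nb - 1)
  rev_bits <- vapply(full, function(x) {
    r <- 0L
    for (b in seq_len(nb)) {
      r <- r * 2L + (x %% 2L)
      x <- x %/% 2L
    }
    r
  }, integer(1))
  ord <- full[order(rev_bits)]
  ord[ord < n] + 1L
}

# Per-subset projection structures, cached on the model keyed by n_subsets.
subset_structures <- function(model, n_subsets) {
  key <- paste0("subsets_", n_subsets)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  nb <- model$n_radial_bins
  subs <- lapply(seq_len(n_subsets), function(s) {
    ang <- which(((seq_len(model$n_angles) - 1L) %% n_subsets) == (s - 1L))
    if (length(ang) == 0L) {
      stop("more subsets than projection angles", call. = FALSE)
    }
    rows <- as.vector(vapply(ang, function(a) ((a - 1L) * nb + 1L):(a * nb), integer(nb)))
    A_sub <- model$A[rows, , drop = FALSE]
    n_sub <- model$normalization[rows]
    r_sub <- model$background[rows]
    sens <- blur_model(matrix(as.vector(Matrix::crossprod(A_sub, n_sub)),
                              model$image_shape[1], model$image_shape[2]), model)
    list(rows = rows, A = A_sub, n = n_sub, r = r_sub, sens = sens)
  })
  model$cache[[key]] <- subs
  subs
}

# Shared EM engine. beta = 0 runs plain OSEM/MLEM; beta > 0 runs the
# one-step-late penalized update with the PLS gradient evaluated at the
# current estimate and the penalty strength split evenly across subsets.
em_engine <- function(y, model, config, u0 = NULL, beta = 0, xi = NULL, alpha = NULL) {
  if (!inherits(y, "sinogram")) stop("`y` must be a sinogram", call. = FALSE)
  if (!identical(dim(y$values), c(model$n_angles, model$n_radial_bins))) {
    stop("sinogram shape does not match the system model", call. = FALSE)
  }
  nsub <- config$n_subsets
  subs <- subset_structures(model, nsub)
  fov <- model$cache$fov
  sens_full <- model$cache$sensitivity
  yv <- sino_to_vec(y$values)

  if (is.null(u0)) {
    u0val <- sum(yv) / sum(sens_full[fov])
    if (!is.finite(u0val) || u0val <= 0) u0val <- 1
    u <- matrix(0, model$image_shape[1], model$image_shape[2])
    u[fov] <- u0val
  } else {
    check_model_grid(u0, model)
    u <- u0$values
    if (any(u[fov] <= 0)) stop("`u0` must be strictly positive inside the field of view", call. = FALSE)
    u[!fov] <- 0
  }

  order_sub <- bit_reversed_order(nsub)
  out <- vector("list", if (config$save_every_iteration) config$n_iterations else 1L)
  clamp_warned <- FALSE

  for (it in seq_len(config$n_iterations)) {
    for (s in order_sub) {
      sub <- subs[[s]]
      bu <- blur_model(u, model)
      ybar <- sub$n * as.vector(sub$A %*% as.vector(bu)) + sub$r
      ys <- yv[sub$rows]
      ratio <- ifelse(ybar > 0, ys / ybar, 0)
      bp <- blur_model(matrix(as.vector(Matrix::crossprod(sub$A, sub$n * ratio)),
                              model$image_shape[1], model$image_shape[2]), model)
      denom <- sub$sens
      if (beta > 0) {
        pg <- pls_gradient(image_grid(u, model$spacing_mm), xi, alpha)$values
        denom <- denom + (beta / nsub) * pg
        floorv <- config$epsilon_floor * sub$sens
        clamped <- denom < floorv & fov
        if (!clamp_warned && sum(clamped) > 0.5 * sum(fov)) {
          warning("penalty clamp active on more than half the field of view; ",
                  "beta is likely too large for this count level", call. = FALSE)
          clamp_warned <- TRUE
        }
        denom <- pmax(denom, floorv)
      }
      un <- u
      un[fov] <- u[fov] * bp[fov] / denom[fov]
      u <- un
    }
    if (config$save_every_iteration) {
      snap <- image_grid(u, model$spacing_mm, nonnegative = TRUE)
      if (config$postfilter_fwhm_mm > 0) {
        snap <- gaussian_postfilter(snap, config$postfilter_fwhm_mm)
      }
      out[[it]] <- snap
    }
  }
  if (!config$save_every_iteration) {
    snap <- image_grid(u, model$spacing_mm, nonnegative = TRUE)
    if (config$postfilter_fwhm_mm > 0) snap <- gaussian_postfilter(snap, config$postfilter_fwhm_mm)
    out[[1]] <- snap
  }
  out
}

#' Ordered Subsets Expectation Maximization (OSEM)
#'
#' Multiplicative EM update for the Poisson emission model, cycling over
#' interleaved angle subsets:
#' `u <- (u / s_subset) * blur(A_subset^T (n y / ybar))` with
#' `ybar = n (A_subset blur(u)) + r`. With `n_subsets = 1` this is exactly
#' MLEM. Nonnegativity is preserved by construction; voxels outside the
#' field of view (zero sensitivity) are frozen at zero. If the
#' configuration's `postfilter_fwhm_mm` is positive, each returned snapshot
#' is Gaussian post-filtered (the reconstruction itself is not).
#'
#' @param y counts [sinogram].
#' @param model a [system_model].
#' @param config a [recon_config].
#' @param u0 optional initial [image_grid], strictly positive inside the
#'   field of view; default a uniform image matched to the total counts.
#' @return a list of per-iteration [image_grid] snapshots (or a length-1
#'   list when `save_every_iteration` is `FALSE`).
#' @export
osem <- function(y, model, config = recon_config(), u0 = NULL) {
  em_engine(y, model, config, u0 = u0, beta = 0)
}

#' Maximum-likelihood EM (MLEM)
#'
#' Convenience wrapper: [osem()] with a single subset.
#'
#' @inheritParams osem
#' @param n_iterations number of EM iterations.
#' @param save_every_iteration keep per-iteration snapshots.
#' @return list of [image_grid] snapshots.
#' @export
mlem <- function(y, model, n_iterations = 50L, u0 = NULL, save_every_iteration = TRUE) {
  osem(y, model,
       recon_config(n_subsets = 1L, n_iterations = n_iterations,
                    save_every_iteration = save_every_iteration),
       u0 = u0)
}

#' MR-guided penalized reconstruction (one-step-late MAP-EM)
#'
#' Minimizes the penalized Poisson objective
#' `sum_i (ybar_i - y_i log ybar_i) + beta * P(u, v)` with the Parallel
#' Level Sets penalty `P` guided by the anatomical prior `v`, using a
#' one-step-late update inside the OSEM subset loop:
#' `u <- u * blur(A_s^T (n y / ybar)) / (s_s + (beta/n_subsets) dP/du)`,
#' with the penalty gradient evaluated at the current estimate and the
#' denominator clamped below at `epsilon_floor * s_s` to keep the update
#' positive. With `beta = 0` the trajectory is identical to [osem()].
#' Guided reconstructions are returned unfiltered (no Gaussian post-filter),
#' matching routine use where only OSEM output is post-smoothed.
#'
#' @param y counts [sinogram].
#' @param model a [system_model].
#' @param prior anatomical prior [image_grid], co-registered on the model
#'   grid.
#' @param penalty a [penalty_params] (unresolved `alpha`/`eta` are filled
#'   with the data-driven defaults and reported in the result attributes).
#' @param config a [recon_config]; its post-filter setting is ignored for
#'   the guided algorithm.
#' @param u0 optional initial image.
#' @return list of per-iteration [image_grid] snapshots, with attributes
#'   `alpha` and `eta` recording the resolved penalty parameters.
#' @export
mrg_reconstruct <- function(y, model, prior, penalty, config = recon_config(), u0 = NULL) {
  if (!inherits(penalty, "penalty_params")) {
    stop("`penalty` must be a penalty_params object", call. = FALSE)
  }
  if (!is_image_grid(prior)) stop("`prior` must be an image_grid", call. = FALSE)
  check_model_grid(prior, model)
  cfg <- config
  cfg$postfilter_fwhm_mm <- 0  # guided output is never post-filtered

  if (penalty$beta == 0) {
    out <- em_engine(y, model, cfg, u0 = u0, beta = 0)
    attr(out, "alpha") <- penalty$alpha
    attr(out, "eta") <- penalty$eta
    return(out)
  }

  eta <- if (is.null(penalty$eta)) default_eta(prior) else penalty$eta
  alpha <- penalty$alpha
  if (is.null(alpha)) {
    u0scale <- if (is.null(u0)) {
      sum(y$values) / sum(model$cache$sensitivity[model$cache$fov])
    } else {
      max(u0$values)
    }
    alpha <- default_alpha(u0scale)
  }
  xi <- normalized_gradient_field(prior, eta)
  out <- em_engine(y, model, cfg, u0 = u0, beta = penalty$beta, xi = xi, alpha = alpha)
  attr(out, "alpha") <- alpha
  attr(out, "eta") <- eta
  out
}

#' Penalized-likelihood objective value
#'
#' Evaluates `sum_i (ybar_i - y_i log ybar_i) + beta * P(u, v)` for the
#' current image (the negative Poisson log-likelihood up to a constant in
#' `y`, plus the penalty). The convention `y_i log ybar_i = 0` when
#' `y_i = 0` is used; a bin with `ybar_i = 0` but `y_i > 0` makes the
#' objective infinite and is rejected.
#'
#' @param u current [image_grid].
#' @param y counts [sinogram].
#' @param model a [system_model].
#' @param xi optional [normalized_gradient_field()]; required when
#'   `penalty$beta > 0`.
#' @param penalty optional [penalty_params]; omit (or `beta = 0`) for the
#'   pure likelihood term.
#' @return the scalar objective value.
#' @export
objective_value <- function(u, y, model, xi = NULL, penalty = NULL) {
  ybar <- forward_project(u, model)
  yb <- ybar$values; yv <- y$values
  if (any(yb == 0 & yv > 0)) {
    stop("objective is infinite: expected counts are zero where data are positive",
         call. = FALSE)
  }
  loglik_term <- ifelse(yv > 0, yv * log(yb), 0)
  val <- sum(yb) - sum(loglik_term)
  if (!is.null(penalty) && penalty$beta > 0) {
    if (is.null(xi)) stop("`xi` is required when the penalty is active", call. = FALSE)
    alpha <- if (is.null(penalty$alpha)) default_alpha(max(u$values)) else penalty$alpha
    val <- val + penalty$beta * pls_penalty(u, xi, alpha)
  }
  val
}
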