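# Independent oracles used across the suite. These deliberately avoid the
# package's internal algorithms: the projector oracle clips each ray against
# every pixel box (Liang-Barsky slabs) instead of walking grid crossings; the
# smoothed-TV functions use their own stencil code; the MLEM reference uses a
# dense matrix and textbook updates.

# intersection length of the LOR (angle, offset) with every pixel, by
# per-pixel slab clipping; returns an ny x nx matrix of lengths (mm)
oracle_ray_lengths <- function(nx, ny, sx, sy, angle, offset) {
  p <- c(offset * cos(angle), offset * sin(angle))
  d <- c(-sin(angle), cos(angle))
  x0 <- -nx * sx / 2
  y0 <- -ny * sy / 2
  out <- matrix(0, ny, nx)
  for (ix in seq_len(nx)) {
    for (iy in seq_len(ny)) {
      lo <- c(x0 + (ix - 1) * sx, y0 + (iy - 1) * sy)
      hi <- c(lo[1] + sx, lo[2] + sy)
      tmin <- -Inf; tmax <- Inf; miss <- FALSE
      for (ax in 1:2) {
        if (abs(d[ax]) < 1e-12) {
          if (p[ax] <= lo[ax] || p[ax] >= hi[ax]) miss <- TRUE
        } else {
          t1 <- (lo[ax] - p[ax]) / d[ax]
          t2 <- (hi[ax] - p[ax]) / d[ax]
          tmin <- max(tmin, min(t1, t2))
          tmax <- min(tmax, max(t1, t2))
        }
      }
      if (!miss && tmax > tmin) out[iy, ix] <- tmax - tmin
    }
  }
  out
}

# forward projection of one LOR by the oracle
oracle_project_ray <- function(values, sx, sy, angle, offset) {
  L <- oracle_ray_lengths(ncol(values), nrow(values), sx, sy, angle, offset)
  sum(L * values)
}

# independent smoothed total-variation penalty and gradient,
# forward differences over spacing, Neumann boundary
oracle_tv_penalty <- function(u, spacing, alpha) {
  ny <- nrow(u); nx <- ncol(u)
  tot <- 0
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      gx <- if (j < nx) (u[i, j + 1] - u[i, j]) / spacing[2] else 0
      gy <- if (i < ny) (u[i + 1, j] - u[i, j]) / spacing[1] else 0
      tot <- tot + sqrt(alpha^2 + gx^2 + gy^2)
    }
  }
  tot
}

oracle_tv_gradient <- function(u, spacing, alpha) {
  ny <- nrow(u); nx <- ncol(u)
  # w = grad u / root, then accumulate the transpose of the difference stencil
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      gx <- if (j < nx) (u[i, j + 1] - u[i, j]) / spacing[2] else 0
      gy <- if (i < ny) (u[i + 1, j] - u[i, j]) / spacing[1] else 0
      root <- sqrt(alpha^2 + gx^2 + gy^2)
      wx <- gx / root; wy <- gy / root
      if (j < nx) {
        out[i, j] <- out[i, j] - wx / spacing[2]
        out[i, j + 1] <- out[i, j + 1] + wx / spacing[2]
      }
      if (i < ny) {
        out[i, j] <- out[i, j] - wy / spacing[1]
        out[i + 1, j] <- out[i + 1, j] + wy / spacing[1]
      }
    }
  }
  out
}

# central finite differences of a scalar functional of an image
numeric_gradient <- function(fn, u, h = 1e-5) {
  g <- matrix(0, nrow(u), ncol(u))
  for (k in seq_along(u)) {
    up <- u; up[k] <- up[k] + h
    um <- u; um[k] <- um[k] - h
    g[k] <- (fn(up) - fn(um)) / (2 * h)
  }
  g
}

# dense textbook MLEM (no subsets, no PSF) for cross-checking the engine
oracle_mlem_dense <- function(A, y, n_iter, u0) {
  A <- as.matrix(A)
  sens <- colSums(A)
  fov <- sens > 1e-9 * max(sens)
  u <- u0
  u[!fov] <- 0
  for (it in seq_len(n_iter)) {
    ybar <- as.vector(A %*% u)
    ratio <- ifelse(ybar > 0, y / ybar, 0)
    bp <- as.vector(t(A) %*% ratio)
    u[fov] <- u[fov] * bp[fov] / sens[fov]
  }
  u
}

# independent bilinear interpolation at one physical point (x, y) in mm
oracle_bilinear_point <- function(values, spacing, x, y) {
  cx <- x / spacing[2] + 1
  cy <- y / spacing[1] + 1
  j0 <- min(max(floor(cx), 1), ncol(values) - 1)
  i0 <- min(max(floor(cy), 1), nrow(values) - 1)
  fx <- cx - j0; fy <- cy - i0
  (1 - fy) * (1 - fx) * values[i0, j0] + (1 - fy) * fx * values[i0, j0 + 1] +
    fy * (1 - fx) * values[i0 + 1, j0] + fy * fx * values[i0 + 1, j0 + 1]
}

# small shared fixtures
tiny_phantom <- function(n = 64, seed = 1) generate_brain_phantom(c(n, n), 1.2, seed = seed)

tiny_model <- function(n = 64, n_angles = 60, psf = 0) {
  system_model(c(n, n), 1.2, n_angles = n_angles, psf_fwhm_mm = psf)
}
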