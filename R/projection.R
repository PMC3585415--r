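#' 2D projection image
#'
#' @param pixels square numeric matrix.
#' @param pixel_size pixel spacing in Angstrom.
#' @param euler `(phi, theta, omega)` in degrees (view orientation, if known).
#' @param shift `(x, y)` shift in pixels (if known).
#' @return Object of class `projection_image`.
#' @export
projection_image <- function(pixels, pixel_size,
                             euler = c(NA_real_, NA_real_, NA_real_),
                             shift = c(0, 0)) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels)) stop("projection image must be square")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 euler = euler, shift = shift),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat("<projection_image> ", nrow(x$pixels), " x ", ncol(x$pixels),
      " px @ ", x$pixel_size, " A/px", sep = "")
  if (!any(is.na(x$euler))) {
    cat(sprintf(" (phi %.1f, theta %.1f, omega %.1f)", x$euler[1], x$euler[2],
                x$euler[3]))
  }
  cat("\n")
  invisible(x)
}

# Trilinear interpolation of `arr` at continuous 1-based index coordinates
# (n x 3 matrix); zero outside the grid.
trilinear_interp <- function(arr, pts) {
  d <- dim(arr)
  i0 <- floor(pts)
  f <- pts - i0
  val <- numeric(nrow(pts))
  inside <- i0[, 1] >= 1 & i0[, 1] <= d[1] - 1 &
            i0[, 2] >= 1 & i0[, 2] <= d[2] - 1 &
            i0[, 3] >= 1 & i0[, 3] <= d[3] - 1
  if (!any(inside)) return(val)
  i0 <- i0[inside, , drop = FALSE]
  f <- f[inside, , drop = FALSE]
  g <- function(dx, dy, dz) {
    arr[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  v <-
    g(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
    g(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
    g(1, 1, 0) * fx       * fy       * (1 - fz) +
    g(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    g(1, 0, 1) * fx       * (1 - fy) * fz +
    g(0, 1, 1) * (1 - fx) * fy       * fz +
    g(1, 1, 1) * fx       * fy       * fz
  val[inside] <- v
  val
}

#' Project a density map along a view direction
#'
#' Actively rotates the map by `Ry(theta) %*% Rz(phi)` about the box centre
#' (trilinear interpolation) and sums along z.  Pixel values are scaled by
#' the voxel size so the image integral (`sum * pixel_size^2`) matches the
#' map integral up to interpolation error.
#'
#' @param map a `density_map`.
#' @param phi,theta Euler angles in degrees (ZY convention, in-plane omega
#'   handled separately downstream).
#' @return A `projection_image` with `euler = c(phi, theta, 0)`.
#' @export
project <- function(map, phi, theta) {
  stopifnot(inherits(map, "density_map"))
  n <- dim(map$grid)[1]
  ctr <- (n + 1) / 2
  R <- rot_y(theta) %*% rot_z(phi)
  Rinv <- t(R)
  ax <- seq_len(n) - ctr
  # all voxel index offsets of the rotated frame
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  src <- pts %*% t(Rinv)
  src <- sweep(src, 2, -ctr)   # back to 1-based indices
  vals <- trilinear_interp(map$grid, src)
  vol <- array(vals, dim = c(n, n, n))
  pix <- apply(vol, c(1, 2), sum) * map$voxel_size
  projection_image(pix, pixel_size = map$voxel_size,
                   euler = c(phi, theta, 0))
}

#' Rotate a 2D image in-plane
#'
#' Bilinear inverse-mapped rotation about the image centre, zero-filled
#' outside the frame.  Positive `omega` rotates counter-clockwise in the
#' (row, column) = (x, y) convention used throughout.
#'
#' @param pixels square numeric matrix.
#' @param omega rotation angle in degrees.
#' @return Rotated matrix of the same size.
#' @export
rotate_image <- function(pixels, omega) {
  n <- nrow(pixels)
  ctr <- (n + 1) / 2
  a <- deg2rad(omega)
  ca <- cos(a); sa <- sin(a)
  ax <- seq_len(n) - ctr
  X <- matrix(ax, n, n)        # row coordinate
  Y <- matrix(ax, n, n, byrow = TRUE)
  # inverse mapping: sample source at R(-omega) applied to output coords
  sx <- ca * X + sa * Y + ctr
  sy <- -sa * X + ca * Y + ctr
  i0 <- floor(sx); j0 <- floor(sy)
  fx <- sx - i0; fy <- sy - j0
  out <- matrix(0, n, n)
  inside <- i0 >= 1 & i0 <= n - 1 & j0 >= 1 & j0 <= n - 1
  gi <- function(di, dj) pixels[cbind(i0[inside] + di, j0[inside] + dj)]
  out[inside] <-
    gi(0, 0) * (1 - fx[inside]) * (1 - fy[inside]) +
    gi(1, 0) * fx[inside]       * (1 - fy[inside]) +
    gi(0, 1) * (1 - fx[inside]) * fy[inside] +
    gi(1, 1) * fx[inside]       * fy[inside]
  out
}

#' Integer-pixel shift of an image (zero fill)
#'
#' @param pixels numeric matrix.
#' @param shift integer `(dx, dy)`: the output at `(x + dx, y + dy)` equals
#'   the input at `(x, y)`.
#' @return Shifted matrix.
#' @export
shift_image <- function(pixels, shift) {
  shift <- round(shift)
  n <- nrow(pixels); m <- ncol(pixels)
  out <- matrix(0, n, m)
  src_r <- seq_len(n) - shift[1]
  src_c <- seq_len(m) - shift[2]
  ok_r <- src_r >= 1 & src_r <= n
  ok_c <- src_c >= 1 & src_c <= m
  out[ok_r, ok_c] <- pixels[src_r[ok_r], src_c[ok_c]]
  out
}

#' Project an atomic model directly to a 2D image
#'
#' Analytic counterpart of `project(model_to_density(...), phi, theta)`: the
#' projection of a sum of 3D Gaussians is the sum of their 2D marginals, so
#' atoms are rotated (about the model centroid) and deposited straight onto
#' the image as integrated 2D Gaussians.  This avoids the interpolation loss
#' of rotating a voxel grid and is considerably faster, which matters when
#' generating projection libraries.  Agreement with the map route (up to
#' interpolation error) is a tested property.
#'
#' @param model an `atomic_model`.
#' @param phi,theta view Euler angles in degrees (same convention as
#'   [project()]).
#' @param pixel_size pixel spacing in Angstrom.
#' @param box image side in pixels.
#' @param resolution resolution in Angstrom (Gaussian half-amplitude at
#'   `1/resolution`, as in [model_to_density()]).
#' @param center rotation centre in model coordinates (default the model
#'   centroid).
#' @param shift in-plane shift in pixels applied to the projected positions.
#' @return A `projection_image` with `euler = c(phi, theta, 0)`.
#' @export
project_model <- function(model, phi, theta, pixel_size, box, resolution,
                          center = NULL, shift = c(0, 0)) {
  xyz <- model_coords(model)
  if (is.null(center)) center <- colMeans(xyz)
  R <- rot_y(theta) %*% rot_z(phi)
  rel <- sweep(xyz, 2, center) %*% t(R)
  px <- rel[, 1] + shift[1] * pixel_size
  py <- rel[, 2] + shift[2] * pixel_size
  sigma <- resolution_sigma(resolution)
  ctr <- (box + 1) / 2
  ax <- (seq_len(box) - ctr) * pixel_size
  h <- pixel_size / 2
  cut <- 4.5 * sigma
  pix <- matrix(0, box, box)
  for (n in seq_along(px)) {
    ix <- which(abs(ax - px[n]) <= cut + h)
    iy <- which(abs(ax - py[n]) <= cut + h)
    if (length(ix) == 0L || length(iy) == 0L) next
    wx <- stats::pnorm(ax[ix] + h, px[n], sigma) - stats::pnorm(ax[ix] - h, px[n], sigma)
    wy <- stats::pnorm(ax[iy] + h, py[n], sigma) - stats::pnorm(ax[iy] - h, py[n], sigma)
    pix[ix, iy] <- pix[ix, iy] + outer(wx, wy)
  }
  projection_image(pix / pixel_size^2, pixel_size = pixel_size,
                   euler = c(phi, theta, 0))
}

#' View axis of a (phi, theta) projection and angular distance between views
#'
#' `view_axis()` returns the unit vector, in the model frame, along which
#' [project()]/[project_model()] integrate for the given Euler pair.
#' `view_angle_error()` gives the angle in degrees between two view axes --
#' the natural metric for Euler-angle recovery, since phi is degenerate at
#' the poles.
#'
#' @param phi,theta Euler angles in degrees.
#' @return `view_axis()`: unit 3-vector.
#' @export
view_axis <- function(phi, theta) {
  # R = Ry(theta) Rz(phi) rotates the model; the fixed +z viewing direction
  # corresponds to t(R) %*% c(0,0,1) in model coordinates
  as.numeric(t(rot_y(theta) %*% rot_z(phi)) %*% c(0, 0, 1))
}

#' @param euler_a,euler_b numeric length-2 `(phi, theta)` pairs in degrees.
#' @return `view_angle_error()`: angle in degrees in \[0, 180\].
#' @rdname view_axis
#' @export
view_angle_error <- function(euler_a, euler_b) {
  va <- view_axis(euler_a[1], euler_a[2])
  vb <- view_axis(euler_b[1], euler_b[2])
  acos(max(-1, min(1, sum(va * vb)))) * 180 / pi
}

# view-sphere Euler grid: theta rows at `angular_step`, phi sampled at
# approximately equal arc spacing (sin-theta weighting) unless sin_weight is
# FALSE
euler_grid <- function(angular_step, theta_range = c(0, 180),
                       sin_weight = TRUE) {
  thetas <- seq(theta_range[1], theta_range[2], by = angular_step)
  out <- list()
  for (th in thetas) {
    n_phi <- if (sin_weight) {
      max(1L, ceiling(360 * sin(deg2rad(th)) / angular_step))
    } else {
      max(1L, round(360 / angular_step))
    }
    phis <- seq(0, 360, length.out = n_phi + 1L)[seq_len(n_phi)]
    for (ph in phis) out[[length(out) + 1L]] <- c(phi = ph, theta = th)
  }
  out
}

#' Generate a projection library over the view sphere
#'
#' Theta rows at `angular_step`; within each row phi is sampled so that the
#' arc spacing on the sphere is approximately `angular_step` (the standard
#' sin-theta weighting; `sin_weight = FALSE` gives the full phi grid at every
#' row).
#'
#' @param map a `density_map`.
#' @param angular_step angular sampling in degrees (default 8).
#' @param theta_range range of theta in degrees (default the full
#'   `c(0, 180)`).
#' @param sin_weight logical; thin phi sampling near the poles (default TRUE).
#' @return List of `projection_image`s with their `euler` angles recorded.
#' @export
make_projection_library <- function(map, angular_step = 8,
                                    theta_range = c(0, 180),
                                    sin_weight = TRUE) {
  grid <- euler_grid(angular_step, theta_range, sin_weight)
  lapply(grid, function(e) project(map, e[["phi"]], e[["theta"]]))
}

#' Generate a projection library directly from an atomic model
#'
#' Like [make_projection_library()] but projects the model analytically via
#' [project_model()] instead of rotating a voxel grid.
#'
#' @param model an `atomic_model`.
#' @param angular_step angular sampling in degrees (default 8).
#' @param pixel_size,box,resolution image settings (see [project_model()]).
#' @param theta_range,sin_weight see [make_projection_library()].
#' @return List of `projection_image`s.
#' @export
make_model_projection_library <- function(model, angular_step = 8,
                                          pixel_size, box, resolution,
                                          theta_range = c(0, 180),
                                          sin_weight = TRUE) {
  grid <- euler_grid(angular_step, theta_range, sin_weight)
  center <- colMeans(model_coords(model))
  lapply(grid, function(e) {
    project_model(model, e[["phi"]], e[["theta"]], pixel_size = pixel_size,
                  box = box, resolution = resolution, center = center)
  })
}
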