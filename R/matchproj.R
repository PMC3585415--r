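circular_mask <- function(n, radius_frac = 0.45) {
  ctr <- (n + 1) / 2
  ax <- seq_len(n) - ctr
  r2 <- outer(ax^2, ax^2, `+`)
  r2 <= (radius_frac * n)^2
}

# zero-mean unit-variance within the mask, zero outside (reproducible
# replacement for the reference software's undocumented normalization)
normalize_masked <- function(pixels, mask) {
  v <- pixels[mask]
  s <- sd(v)
  if (s < .Machine$double.eps) s <- 1
  out <- matrix(0, nrow(pixels), ncol(pixels))
  out[mask] <- (v - mean(v)) / s
  out
}

# circular cross-correlation surface: entry (encoding shift s, wrapped)
# measures the overlap of `a` with `b` shifted by +s
xcorr_surface <- function(a, b) {
  Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / length(a)
}

# decode an index of the cc surface into a signed shift
cc_shift <- function(idx, n) {
  s <- idx - 1L
  ifelse(s > n / 2, s - n, s)
}

# parabolic sub-pixel refinement along one axis of the cc surface
parabolic_delta <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (abs(den) < .Machine$double.eps) return(0)
  delta <- 0.5 * (cm - cp) / den
  max(-0.5, min(0.5, delta))
}

# parabola-interpolated peak height above c0 along one axis; scoring with
# this removes the bias against alignments whose true shift is fractional
parabolic_gain <- function(cm, c0, cp) {
  a <- (cm + cp) / 2 - c0
  if (a >= 0) return(0)   # not concave: no refinement
  b <- (cp - cm) / 2
  min(b^2 / (4 * abs(a)), abs(a))
}

masked_pearson <- function(a, b, mask) {
  suppressWarnings(cor(a[mask], b[mask]))
}

#' Match a class average against a projection library
#'
#' For every library projection, searches the in-plane rotation omega (grid,
#' default 2 degrees) and translation (via the FFT cross-correlation peak,
#' with parabolic sub-pixel refinement) that maximize the normalized
#' cross-correlation with the image; returns the best library member.  Images
#' are normalized to zero mean and unit variance within a circular mask of
#' radius `0.45 * box` before correlation.  The alignment model is
#' `image ~ shift(rotate(projection, omega), shift)`; the search rotates the
#' image by `-omega` once per omega rather than every library member, which
#' is equivalent and much cheaper.  Exact score ties are broken by the lowest
#' library index.
#'
#' @param image a `projection_image` (the class average).
#' @param library list of `projection_image`s sharing the image's box and
#'   pixel size.
#' @param omega_step in-plane search step in degrees (default 2).
#' @param mask_radius mask radius as a fraction of the box (default 0.45).
#' @return List: `euler` (phi, theta of the best member), `omega`, `shift`
#'   (sub-pixel, image frame), `ccc` (Pearson r over the mask after
#'   alignment), `index` (library index).
#' @export
match_projection <- function(image, library, omega_step = 2,
                             mask_radius = 0.45) {
  if (length(library) == 0L) stop("projection library is empty")
  n <- nrow(image$pixels)
  for (p in library) {
    if (nrow(p$pixels) != n) stop("library box size differs from image")
    if (abs(p$pixel_size - image$pixel_size) > 1e-6) {
      stop("library pixel size differs from image")
    }
  }
  mask <- circular_mask(n, mask_radius)
  imgN <- normalize_masked(image$pixels, mask)

  omegas <- seq(0, 360 - omega_step, by = omega_step)
  # pre-rotate the image once per omega and cache FFTs
  f_img <- lapply(omegas, function(w) fft(rotate_image(imgN, -w)))
  f_lib <- lapply(library, function(p) {
    pN <- normalize_masked(p$pixels, mask)
    Conj(fft(pN))
  })
  npx <- sum(mask)

  best <- list(score = -Inf, index = NA_integer_, omega = NA_real_,
               cc = NULL, peak = NA_integer_)
  wrap1 <- function(i) ((i - 1L) %% n) + 1L
  for (m in seq_along(library)) {
    fl <- f_lib[[m]]
    for (wi in seq_along(omegas)) {
      cc <- matrix(Re(fft(f_img[[wi]] * fl, inverse = TRUE)) /
                     (length(fl) * npx), n, n)
      pk <- which.max(cc)
      r <- ((pk - 1L) %% n) + 1L
      cl <- ((pk - 1L) %/% n) + 1L
      score <- cc[pk] +
        parabolic_gain(cc[wrap1(r - 1L), cl], cc[pk], cc[wrap1(r + 1L), cl]) +
        parabolic_gain(cc[r, wrap1(cl - 1L)], cc[pk], cc[r, wrap1(cl + 1L)])
      if (score > best$score + 1e-12) {
        best <- list(score = score, index = m, omega = omegas[wi],
                     cc = cc, peak = pk)
      }
    }
  }

  cc <- best$cc
  pk <- arrayInd(best$peak, dim(cc))
  sx <- cc_shift(pk[1], n); sy <- cc_shift(pk[2], n)
  wrap <- function(i) ((i - 1L) %% n) + 1L
  dx <- parabolic_delta(cc[wrap(pk[1] - 1L), pk[2]], cc[pk[1], pk[2]],
                        cc[wrap(pk[1] + 1L), pk[2]])
  dy <- parabolic_delta(cc[pk[1], wrap(pk[2] - 1L)], cc[pk[1], pk[2]],
                        cc[pk[1], wrap(pk[2] + 1L)])
  # shift found in the rotated-image frame; map back to the image frame
  s_rot <- c(sx + dx, sy + dy)
  a <- deg2rad(best$omega)
  shift_img <- c(cos(a) * s_rot[1] - sin(a) * s_rot[2],
                 sin(a) * s_rot[1] + cos(a) * s_rot[2])

  bestp <- library[[best$index]]
  aligned <- shift_image(rotate_image(bestp$pixels, best$omega),
                         round(shift_img))
  ccc <- masked_pearson(image$pixels, aligned, mask)
  list(euler = bestp$euler[1:2], omega = best$omega, shift = shift_img,
       ccc = ccc, index = best$index)
}

#' Align a library projection to an image frame
#'
#' Applies the in-plane rotation and (integer-rounded) shift reported by
#' [match_projection()] to a projection.
#'
#' @param projection a `projection_image`.
#' @param omega in-plane rotation in degrees.
#' @param shift `(x, y)` shift in pixels.
#' @return A `projection_image` in the image frame.
#' @export
align_projection <- function(projection, omega, shift = c(0, 0)) {
  pix <- shift_image(rotate_image(projection$pixels, omega), round(shift))
  projection_image(pix, pixel_size = projection$pixel_size,
                   euler = c(projection$euler[1:2], omega), shift = shift)
}

#' Subtract an aligned projection from an image
#'
#' Least-squares intensity scaling (a scalar after mean subtraction within
#' the mask; negative-stain contrast is arbitrary) followed by pixelwise
#' subtraction.
#'
#' @param image a `projection_image`.
#' @param aligned_projection a `projection_image` in the image frame.
#' @param mask_radius mask radius fraction used for the scale fit.
#' @return A `projection_image` holding the difference.
#' @export
subtract_aligned <- function(image, aligned_projection, mask_radius = 0.45) {
  n <- nrow(image$pixels)
  if (nrow(aligned_projection$pixels) != n) stop("image and projection sizes differ")
  mask <- circular_mask(n, mask_radius)
  a <- image$pixels - mean(image$pixels[mask])
  p <- aligned_projection$pixels - mean(aligned_projection$pixels[mask])
  denom <- sum(p[mask]^2)
  scale <- if (denom < .Machine$double.eps) 0 else sum(a[mask] * p[mask]) / denom
  projection_image(a - scale * p, pixel_size = image$pixel_size)
}

#' Sequential two-body projection fit
#'
#' Reproduces the two-stage fitting used for receptor/Fab class averages:
#' the first body (e.g. the ectodomain without the ligand-binding domain) is
#' matched into the image, its aligned projection is subtracted, and the
#' second body (e.g. the domain/Fab moiety) is matched into the difference
#' image.  The composite cross-correlation is the Pearson r between the
#' image and the joint least-squares combination of both aligned
#' projections, over the same circular mask used for the single-body score,
#' so the two numbers are directly comparable.
#'
#' @param image a `projection_image` (class average).
#' @param body1_model,body2_model `atomic_model`s for the two bodies.
#' @param angular_step projection library sampling in degrees (default 8).
#' @param resolution density simulation resolution in Angstrom (default 18).
#' @param omega_step in-plane search step in degrees (default 2).
#' @param body2_ccc_min minimum body-2 ccc against the difference image for
#'   body 2 to be reported present (default 0.3).
#' @param mask_radius mask radius fraction (default 0.45).
#' @return Object of class `sequential_fit_result`: per-body Euler angles
#'   and in-plane parameters, `ccc_body1`, `ccc_body2` (vs difference),
#'   `ccc_composite`, `body2_present`.
#' @export
sequential_fit <- function(image, body1_model, body2_model,
                           angular_step = 8, resolution = 18,
                           omega_step = 2, body2_ccc_min = 0.3,
                           mask_radius = 0.45) {
  n <- nrow(image$pixels)
  apix <- image$pixel_size
  lib1 <- make_model_projection_library(body1_model,
                                        angular_step = angular_step,
                                        pixel_size = apix, box = n,
                                        resolution = resolution)
  m1 <- match_projection(image, lib1, omega_step = omega_step,
                         mask_radius = mask_radius)
  aligned1 <- align_projection(lib1[[m1$index]], m1$omega, m1$shift)
  diff <- subtract_aligned(image, aligned1, mask_radius = mask_radius)

  lib2 <- make_model_projection_library(body2_model,
                                        angular_step = angular_step,
                                        pixel_size = apix, box = n,
                                        resolution = resolution)
  m2 <- match_projection(diff, lib2, omega_step = omega_step,
                         mask_radius = mask_radius)
  aligned2 <- align_projection(lib2[[m2$index]], m2$omega, m2$shift)

  mask <- circular_mask(n, mask_radius)
  df <- data.frame(y = image$pixels[mask],
                   p1 = aligned1$pixels[mask],
                   p2 = aligned2$pixels[mask])
  fit <- lm(y ~ p1 + p2, data = df)
  ccc_comp <- suppressWarnings(cor(fitted(fit), df$y))

  structure(list(
    integrin_euler = m1$euler, integrin_inplane = list(omega = m1$omega,
                                                       shift = m1$shift),
    fab_euler = m2$euler, fab_inplane = list(omega = m2$omega,
                                             shift = m2$shift),
    ccc_body1 = m1$ccc, ccc_body2 = m2$ccc, ccc_composite = ccc_comp,
    body2_present = is.finite(m2$ccc) && m2$ccc >= body2_ccc_min
  ), class = "sequential_fit_result")
}

#' @export
print.sequential_fit_result <- function(x, ...) {
  cat(sprintf(
    "<sequential_fit_result> body1 (phi %.1f, theta %.1f) ccc %.3f; body2 (phi %.1f, theta %.1f) ccc %.3f%s; composite ccc %.3f\n",
    x$integrin_euler[1], x$integrin_euler[2], x$ccc_body1,
    x$fab_euler[1], x$fab_euler[2], x$ccc_body2,
    if (x$body2_present) "" else " [below presence threshold]",
    x$ccc_composite))
  invisible(x)
}
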