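#' 3D density map
#'
#' A cubic voxel grid with physical sampling.  Voxel centre `(i, j, k)`
#' (1-based) is at `origin + (c(i,j,k) - 1) * voxel_size`.
#'
#' @param grid 3D numeric array (cubic).
#' @param voxel_size voxel spacing in Angstrom (> 0).
#' @param origin physical position of voxel (1,1,1), Angstrom.
#' @param resolution nominal low-pass resolution in Angstrom (NA if unset).
#' @return Object of class `density_map`.
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0), resolution = NA_real_) {
  d <- dim(grid)
  if (length(d) != 3L || length(unique(d)) != 1L) stop("grid must be a cubic 3D array")
  if (!all(is.finite(grid))) stop("density must be finite everywhere")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  structure(list(grid = grid, voxel_size = voxel_size, origin = origin,
                 resolution = resolution),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("<density_map> ", paste(dim(x$grid), collapse = " x "),
      " voxels @ ", x$voxel_size, " A/voxel",
      if (!is.na(x$resolution)) paste0(", ", x$resolution, " A resolution"),
      "\n", sep = "")
  invisible(x)
}

# Real-space sigma of a Gaussian whose Fourier amplitude falls to 0.5 at
# spatial frequency 1/resolution: exp(-2 pi^2 sigma^2 k^2) = 1/2.
resolution_sigma <- function(resolution) resolution * sqrt(log(2) / 2) / pi

#' Simulate low-resolution density from an atomic model
#'
#' Each atom is deposited as a unit-weight 3D Gaussian whose Fourier
#' amplitude falls to 0.5 at `1/resolution` (all atoms weighted equally; at
#' the 18-26 Angstrom resolutions this models, elemental scattering
#' differences are negligible).  Deposition uses per-axis integrated
#' Gaussians (normal CDF differences across each voxel), so the integral of
#' the map equals the atom count essentially exactly regardless of sampling.
#' The box is centred on the model centroid.
#'
#' @param model an `atomic_model`.
#' @param voxel_size voxel spacing in Angstrom.
#' @param box box side length in voxels.
#' @param resolution target resolution in Angstrom.
#' @param origin physical position of voxel (1,1,1); by default the box is
#'   centred on the model centroid.
#' @return A `density_map`; `sum(grid) * voxel_size^3` equals the number of
#'   atoms (up to Gaussian tail truncation).
#' @export
model_to_density <- function(model, voxel_size, box, resolution,
                             origin = NULL) {
  xyz <- model_coords(model)
  box <- as.integer(box)
  if (box < 4L) stop("box must be at least 4 voxels")
  if (is.null(origin)) {
    origin <- colMeans(xyz) - (box - 1) / 2 * voxel_size
  }
  box_center <- origin + (box - 1) / 2 * voxel_size
  # require >= 10% padding: all atoms inside the central 80% of the box
  half <- box * voxel_size / 2
  rel <- sweep(xyz, 2, box_center)
  if (max(abs(rel)) > 0.8 * half) {
    stop("model does not fit in the box with 10% padding; ",
         "increase box or voxel_size")
  }
  sigma <- resolution_sigma(resolution)
  grid <- array(0, dim = c(box, box, box))
  centers <- origin[1] + (seq_len(box) - 1) * voxel_size  # same offsets per axis
  h <- voxel_size / 2
  cut <- 4.5 * sigma
  axis_centers <- lapply(1:3, function(a) origin[a] + (seq_len(box) - 1) * voxel_size)
  for (n in seq_len(nrow(xyz))) {
    w <- vector("list", 3L)
    idx <- vector("list", 3L)
    ok <- TRUE
    for (a in 1:3) {
      cs <- axis_centers[[a]]
      sel <- which(abs(cs - xyz[n, a]) <= cut + h)
      if (length(sel) == 0L) { ok <- FALSE; break }
      idx[[a]] <- sel
      w[[a]] <- stats::pnorm(cs[sel] + h, xyz[n, a], sigma) -
                stats::pnorm(cs[sel] - h, xyz[n, a], sigma)
    }
    if (!ok) next
    blob <- outer(outer(w[[1]], w[[2]]), w[[3]])
    grid[idx[[1]], idx[[2]], idx[[3]]] <-
      grid[idx[[1]], idx[[2]], idx[[3]]] + blob
  }
  grid <- grid / voxel_size^3   # integral (sum * voxel^3) = n_atoms
  density_map(grid, voxel_size = voxel_size, origin = origin,
              resolution = resolution)
}

# centred integer frequency index along one axis of an n-point DFT
fft_freq_index <- function(n) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  k[seq_len(n)]
}

#' Sharp low-pass filter of a density map
#'
#' Zeroes all Fourier coefficients beyond `1/resolution`.  The cutoff is
#' sharp by design: band-limited copies then correlate perfectly below the
#' cutoff and not at all above it, which is what makes the FSC 0.5 crossing
#' land at the cutoff frequency.
#'
#' @param map a `density_map`.
#' @param resolution cutoff resolution in Angstrom.
#' @return Filtered `density_map` with `resolution` recorded.
#' @export
lowpass_map <- function(map, resolution) {
  stopifnot(inherits(map, "density_map"))
  n <- dim(map$grid)[1]
  k <- fft_freq_index(n) / (n * map$voxel_size)
  k2 <- outer(outer(k^2, k^2, `+`), k^2, `+`)
  mask <- k2 <= (1 / resolution)^2
  f <- fft(map$grid) * mask
  out <- Re(fft(f, inverse = TRUE)) / length(f)
  density_map(out, voxel_size = map$voxel_size, origin = map$origin,
              resolution = resolution)
}
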