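#' Fourier shell correlation between two maps
#'
#' Correlation of the two maps' Fourier coefficients within concentric
#' spherical shells:
#' `FSC(k) = Re(sum F1 conj(F2)) / sqrt(sum |F1|^2 * sum |F2|^2)`.
#' Shells where either map has no power are reported as correlation 0 (a
#' band-limited map carries no signal there).
#'
#' @param map_a,map_b `density_map`s on the same grid and voxel size.
#' @return Object of class `fsc_curve`: `shell_centers` (1/Angstrom,
#'   increasing) and `correlations` in \[-1, 1\].
#' @export
fsc <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "density_map"), inherits(map_b, "density_map"))
  if (!all(dim(map_a$grid) == dim(map_b$grid))) stop("map grids differ in size")
  if (abs(map_a$voxel_size - map_b$voxel_size) > 1e-9) {
    stop("map voxel sizes differ")
  }
  n <- dim(map_a$grid)[1]
  f1 <- fft(map_a$grid)
  f2 <- fft(map_b$grid)
  k <- fft_freq_index(n)
  shell <- round(sqrt(outer(outer(k^2, k^2, `+`), k^2, `+`)))
  n_shell <- floor(n / 2)
  sel <- shell >= 1 & shell <= n_shell
  sh <- shell[sel]
  num <- as.numeric(tapply(Re(f1[sel] * Conj(f2[sel])), sh, sum))
  p1 <- as.numeric(tapply(abs(f1[sel])^2, sh, sum))
  p2 <- as.numeric(tapply(abs(f2[sel])^2, sh, sum))
  den <- sqrt(p1 * p2)
  corr <- ifelse(den < .Machine$double.eps, 0, num / den)
  structure(list(shell_centers = seq_len(n_shell) / (n * map_a$voxel_size),
                 correlations = corr),
            class = "fsc_curve")
}

#' Resolution at an FSC threshold
#'
#' Finds the first crossing of the curve below `threshold` and linearly
#' interpolates the crossing frequency between the bracketing shells; the
#' resolution is its reciprocal in Angstrom.
#'
#' @param curve an `fsc_curve`.
#' @param threshold correlation threshold (default 0.5).
#' @return Resolution in Angstrom.
#' @export
resolution_at <- function(curve, threshold = 0.5) {
  stopifnot(inherits(curve, "fsc_curve"))
  cc <- curve$correlations
  fr <- curve$shell_centers
  if (cc[1] < threshold) {
    stop("FSC is already below the threshold in the first shell")
  }
  below <- which(cc < threshold)
  if (length(below) == 0L) {
    stop("FSC never crosses ", threshold, "; resolution is beyond Nyquist")
  }
  i <- below[1]
  f_cross <- fr[i - 1] + (fr[i] - fr[i - 1]) *
    (cc[i - 1] - threshold) / (cc[i - 1] - cc[i])
  1 / f_cross
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat("<fsc_curve> ", length(x$correlations), " shells, ",
      sprintf("%.4f", x$shell_centers[1]), " to ",
      sprintf("%.4f", x$shell_centers[length(x$shell_centers)]),
      " 1/A\n", sep = "")
  invisible(x)
}
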