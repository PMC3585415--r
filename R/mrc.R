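# Minimal MRC2014 mode-2 (float32) I/O.  Only the fields the package needs:
# dimensions, mode, cell size (voxel spacing = cella / mx) and the data block.
# Written because no installed R package reads MRC volumes.

#' Write a density map or projection image to an MRC file
#'
#' Mode 2 (float32, little-endian), MRC2014 header.  A `projection_image` is
#' written as an nx x ny x 1 volume.
#'
#' @param x a `density_map` or `projection_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path) {
  if (inherits(x, "density_map")) {
    arr <- x$grid
    spacing <- x$voxel_size
  } else if (inherits(x, "projection_image")) {
    arr <- array(x$pixels, dim = c(dim(x$pixels), 1L))
    spacing <- x$pixel_size
  } else {
    stop("x must be a density_map or projection_image")
  }
  d <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(d)                                  # nx ny nz
  wi(2L)                                 # mode 2 = float32
  wi(c(0L, 0L, 0L))                      # nxstart nystart nzstart
  wi(d)                                  # mx my mz
  wf(d * spacing)                        # cella (Angstrom)
  wf(c(90, 90, 90))                      # cellb
  wi(c(1L, 2L, 3L))                      # mapc mapr maps
  wf(c(min(arr), max(arr), mean(arr)))   # dmin dmax dmean
  wi(c(1L, 0L))                          # ispg, nsymbt
  wi(rep(0L, 25L))                       # extra
  wf(c(0, 0, 0))                         # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(as.numeric(arr)))                # rms
  wi(0L)                                 # nlabl
  writeBin(raw(800L), con)               # labels
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC file
#'
#' Supports mode 2 (float32) volumes.  Returns a `density_map` when nz > 1
#' and a `projection_image` when nz == 1.
#'
#' @param path MRC file path.
#' @return A `density_map` or `projection_image`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("unsupported MRC mode ", mode, " (only mode 2 is read)")
  ri(3)               # nxstart..
  m <- ri(3)          # mx my mz
  cella <- rf(3)
  seek(con, 1024L)
  n_vox <- prod(d)
  vals <- rf(n_vox)
  if (length(vals) != n_vox) stop("truncated MRC data block in ", path)
  spacing <- if (m[1] > 0) cella[1] / m[1] else 1
  arr <- array(vals, dim = d)
  if (d[3] == 1L) {
    projection_image(arr[, , 1L], pixel_size = spacing)
  } else {
    density_map(arr, voxel_size = spacing)
  }
}
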