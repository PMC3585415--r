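#' Circular mean and standard deviation in degrees
#'
#' Mean direction from the resultant vector; circular SD as
#' `sqrt(-2 log Rbar)` converted to degrees.  For tightly clustered angles
#' both reduce to the ordinary statistics.
#'
#' @param deg numeric vector of angles in degrees.
#' @return List with `mean` (in \[0, 360)) and `sd` (degrees).
#' @export
circular_stats <- function(deg) {
  if (length(deg) == 0L) stop("no angles supplied")
  a <- deg2rad(deg)
  s <- mean(sin(a)); c <- mean(cos(a))
  mu <- (atan2(s, c) * 180 / pi) %% 360
  if (mu > 360 - 1e-9) mu <- 0
  rbar <- sqrt(s^2 + c^2)
  sd <- if (rbar < 1e-12) Inf else sqrt(-2 * log(min(rbar, 1))) * 180 / pi
  list(mean = mu, sd = sd)
}

#' Tilt and tilt-direction statistics of orientation samples
#'
#' Tilt angles (degrees from the membrane plane) are summarized with
#' arithmetic mean and sample SD; the tilt direction phi is periodic and is
#' summarized with circular statistics.
#'
#' @param samples data.frame with columns `tilt` and `phi` (degrees), e.g. a
#'   subset of the `samples` table of an [orientation_scan()] result.
#' @return List `tilt_mean`, `tilt_sd`, `phi_mean`, `phi_sd` (degrees).
#' @export
angle_statistics <- function(samples) {
  if (NROW(samples) == 0L) stop("no samples supplied")
  cs <- circular_stats(samples$phi)
  list(tilt_mean = mean(samples$tilt),
       tilt_sd = if (NROW(samples) > 1L) sd(samples$tilt) else NA_real_,
       phi_mean = cs$mean,
       phi_sd = if (NROW(samples) > 1L) cs$sd else NA_real_)
}

#' Systematic membrane-orientation scan
#'
#' Rotates the framed model over the full grid of tilt directions
#' (`phi` in \[0, 360), excluding the periodic endpoint) and tilt rotations
#' (`rho` in \[0, 180\], both endpoints included: vertical legs through flush
#' to buried).  Each grid point records whether any atom dips below the
#' membrane plane (clash) and the perpendicular distance from the Fab
#' lysine-CA centroid to the plane.  With the default 5 degree step the grid
#' holds 72 x 37 = 2,664 samples.  Tilt is reported as `90 - rho` (90 =
#' perpendicular to the membrane, 0 = flush, negative = buried).
#'
#' Only the atom z-coordinates after rotation are needed, so the scan is
#' evaluated in closed form per grid point rather than by transforming the
#' full model.
#'
#' @param framed a `framed_model`.
#' @param plane a [membrane_plane()].
#' @param step grid step in degrees; must divide both ranges evenly.
#' @param phi_range,rho_range numeric length-2 ranges in degrees.
#' @param fab_roles role tags selecting the Fab chains for the centroid.
#' @return Object of class `orientation_scan_result`: list with `samples`
#'   (data.frame: phi, rho, tilt, clash, centroid_distance, allowed,
#'   flim_consistent), counts, statistics over the allowed set, and the scan
#'   parameters.  The `flim_consistent` column is all-FALSE until
#'   [apply_flim_constraint()] is applied.
#' @export
orientation_scan <- function(framed, plane, step = 5,
                             phi_range = c(0, 360), rho_range = c(0, 180),
                             fab_roles = c("fab_heavy", "fab_light")) {
  stopifnot(inherits(framed, "framed_model"), inherits(plane, "membrane_plane"))
  if (step <= 0) stop("step must be positive")
  if (abs((diff(phi_range) / step) %% 1) > 1e-9 ||
      abs((diff(rho_range) / step) %% 1) > 1e-9) {
    stop("step must divide the phi and rho ranges evenly")
  }
  phis <- seq(phi_range[1], phi_range[2] - step, by = step)
  rhos <- seq(rho_range[1], rho_range[2], by = step)

  xyz <- model_coords(framed$model)
  cen <- lysine_centroid(framed$model, role_filter = fab_roles)
  z0 <- plane$z_level

  nphi <- length(phis); nrho <- length(rhos)
  clash <- matrix(FALSE, nrho, nphi)
  dist <- matrix(NA_real_, nrho, nphi)
  for (i in seq_along(phis)) {
    a <- deg2rad(phis[i])
    # x after Rz(phi); y not needed (Ry only mixes x and z)
    x1 <- cos(a) * xyz[, 1] - sin(a) * xyz[, 2]
    cx1 <- cos(a) * cen[1] - sin(a) * cen[2]
    for (j in seq_along(rhos)) {
      b <- deg2rad(rhos[j])
      z2 <- -sin(b) * x1 + cos(b) * xyz[, 3]
      clash[j, i] <- any(z2 < z0)
      dist[j, i] <- abs((-sin(b) * cx1 + cos(b) * cen[3]) - z0)
    }
  }

  samples <- data.frame(
    phi = rep(phis, each = nrho),
    rho = rep(rhos, times = nphi),
    tilt = 90 - rep(rhos, times = nphi),
    clash = as.vector(clash),
    centroid_distance = as.vector(dist)
  )
  samples$allowed <- !samples$clash
  samples$flim_consistent <- FALSE

  res <- structure(
    list(samples = samples, step = step, plane = plane,
         fab_roles = fab_roles, target = NULL, tolerance = NULL),
    class = "orientation_scan_result"
  )
  update_scan_summary(res)
}

# recompute counts and statistics; the statistics describe the most
# constrained non-empty subset (flim-consistent if applied, else allowed)
update_scan_summary <- function(res) {
  s <- res$samples
  res$n_samples <- nrow(s)
  res$n_allowed <- sum(s$allowed)
  res$n_flim_consistent <- sum(s$flim_consistent)
  subset <- if (!is.null(res$target)) s[s$flim_consistent, , drop = FALSE]
            else s[s$allowed, , drop = FALSE]
  if (nrow(subset) == 0L) {
    res$statistics <- list(tilt_mean = NA_real_, tilt_sd = NA_real_,
                           phi_mean = NA_real_, phi_sd = NA_real_)
    res$statistics_defined <- FALSE
  } else {
    res$statistics <- angle_statistics(subset)
    res$statistics_defined <- TRUE
  }
  res
}

#' Apply the FLIM distance constraint to a scan result
#'
#' Keeps the allowed (non-clashing) orientations whose Fab-centroid distance
#' lies within `tolerance` of the FLIM-derived target distance, and
#' recomputes the tilt/direction statistics on that subset.
#'
#' @param result an `orientation_scan_result`.
#' @param target target centroid-to-membrane distance in Angstrom (> 0).
#' @param tolerance half-width of the acceptance window in Angstrom
#'   (default 2.5, half the typical per-grid-step distance change).
#' @return Updated `orientation_scan_result`.
#' @export
apply_flim_constraint <- function(result, target, tolerance = 2.5) {
  stopifnot(inherits(result, "orientation_scan_result"))
  if (target <= 0) stop("target distance must be positive")
  if (tolerance < 0) stop("tolerance must be non-negative")
  s <- result$samples
  s$flim_consistent <- s$allowed &
    abs(s$centroid_distance - target) <= tolerance
  result$samples <- s
  result$target <- target
  result$tolerance <- tolerance
  update_scan_summary(result)
}

#' @export
print.orientation_scan_result <- function(x, ...) {
  cat("<orientation_scan_result> step ", x$step, " deg, ",
      x$n_samples, " samples; allowed ", x$n_allowed, sep = "")
  if (!is.null(x$target)) {
    cat("; FLIM-consistent ", x$n_flim_consistent,
        " (target ", x$target, " +/- ", x$tolerance, " A)", sep = "")
  }
  cat("\n")
  if (isTRUE(x$statistics_defined)) {
    st <- x$statistics
    cat(sprintf("  tilt %.1f (SD %.1f) deg; phi %.1f (SD %.1f) deg\n",
                st$tilt_mean, st$tilt_sd, st$phi_mean, st$phi_sd))
  } else {
    cat("  statistics undefined (empty subset)\n")
  }
  invisible(x)
}

#' Write a scan result to CSV
#'
#' One row per grid sample plus a commented summary block (counts and
#' statistics) at the top.
#'
#' @param result an `orientation_scan_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(result, path) {
  stopifnot(inherits(result, "orientation_scan_result"))
  st <- result$statistics
  hdr <- c(
    sprintf("# n_samples,%d", result$n_samples),
    sprintf("# n_allowed,%d", result$n_allowed),
    sprintf("# n_flim_consistent,%d", result$n_flim_consistent),
    sprintf("# target,%s", if (is.null(result$target)) "NA" else result$target),
    sprintf("# tolerance,%s", if (is.null(result$tolerance)) "NA" else result$tolerance),
    sprintf("# tilt_mean,%s", format(st$tilt_mean)),
    sprintf("# tilt_sd,%s", format(st$tilt_sd)),
    sprintf("# phi_mean,%s", format(st$phi_mean)),
    sprintf("# phi_sd,%s", format(st$phi_sd))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(result$samples, con, row.names = FALSE)
  invisible(path)
}
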