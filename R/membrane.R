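#' Model membrane plane
#'
#' The membrane is the half-space `z < z_level` with outward normal +z; no
#' thickness, headgroups or atom radii are modelled.  In the canonical frame
#' the plane sits below the alpha-chain terminal residue by the linker offset
#' (the unresolved stretch between the last modelled ectodomain residue and
#' the start of the transmembrane helix), i.e. `z_level = -linker_offset`.
#'
#' @param z_level plane height in Angstrom.
#' @return Object of class `membrane_plane`.
#' @export
membrane_plane <- function(z_level) {
  stopifnot(is.numeric(z_level), length(z_level) == 1L, is.finite(z_level))
  structure(list(z_level = z_level), class = "membrane_plane")
}

deg2rad <- function(x) x * pi / 180

rot_z <- function(phi) {
  a <- deg2rad(phi)
  matrix(c(cos(a), -sin(a), 0,
           sin(a),  cos(a), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

rot_y <- function(rho) {
  a <- deg2rad(rho)
  matrix(c( cos(a), 0, sin(a),
            0,      1, 0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

#' Rotate a framed model to an orientation sample
#'
#' Applies the extrinsic active rotation `Ry(rho) %*% Rz(phi)` to every atom:
#' first the tilt direction is selected by spinning about z (angle phi), then
#' the model is tilted down about y (angle rho).
#'
#' @param framed a `framed_model` (see [canonicalize()]).
#' @param phi rotation about z in degrees (wrapped into \[0, 360)).
#' @param rho subsequent rotation about y in degrees.
#' @return Rotated `atomic_model`.
#' @export
rotate_model <- function(framed, phi, rho) {
  stopifnot(inherits(framed, "framed_model"))
  transform_model(framed$model, rotation = rot_y(rho %% 360) %*% rot_z(phi %% 360))
}

#' Does a model clash with the membrane plane?
#'
#' TRUE iff any atom centre lies strictly below the plane.  No van der Waals
#' radii are applied: the membrane is a mathematical plane.
#'
#' @param model an `atomic_model`.
#' @param plane a [membrane_plane()].
#' @return Logical scalar.
#' @export
clashes_membrane <- function(model, plane) {
  stopifnot(inherits(plane, "membrane_plane"))
  any(model$atoms$z < plane$z_level)
}

#' Perpendicular distance from the Fab fluorophore centroid to the membrane
#'
#' @param model an `atomic_model`.
#' @param plane a [membrane_plane()].
#' @param fab_roles role tags selecting the Fab chains.
#' @return Distance in Angstrom (non-negative).
#' @export
centroid_distance <- function(model, plane,
                              fab_roles = c("fab_heavy", "fab_light")) {
  stopifnot(inherits(plane, "membrane_plane"))
  cen <- lysine_centroid(model, role_filter = fab_roles)
  abs(cen[[3]] - plane$z_level)
}
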