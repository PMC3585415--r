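#' Atomic model container
#'
#' An `atomic_model` holds labelled atoms (chain, residue number, residue
#' name, atom name, element, xyz in Angstrom) together with a role map that
#' assigns each chain one of the tags `"alpha"`, `"beta"`, `"fab_heavy"`,
#' `"fab_light"` or `"other"`.  Roles are explicit user configuration: they
#' are never inferred from sequence, because chain identities are specific to
#' each deposited structure.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `elesy`, `x`, `y`, `z`.
#' @param roles named character vector mapping chain id to role tag; chains
#'   not named default to `"other"`.
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, roles = NULL) {
  required <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("atomic model contains no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("atomic model contains non-finite coordinates")
  atoms <- as.data.frame(atoms[, required], stringsAsFactors = FALSE)
  atoms$chain <- as.character(atoms$chain)
  chains <- unique(atoms$chain)
  role_map <- stats::setNames(rep("other", length(chains)), chains)
  if (!is.null(roles)) {
    roles <- unlist(roles)
    bad <- setdiff(roles, c("alpha", "beta", "fab_heavy", "fab_light", "other"))
    if (length(bad) > 0L) stop("unknown role tag(s): ", paste(bad, collapse = ", "))
    unknown <- setdiff(names(roles), chains)
    if (length(unknown) > 0L) {
      stop("role assigned to chain(s) absent from model: ",
           paste(unknown, collapse = ", "))
    }
    role_map[names(roles)] <- roles
  }
  structure(list(atoms = atoms, roles = role_map), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat("<atomic_model> ", nrow(x$atoms), " atoms, ",
      length(x$roles), " chain(s)\n", sep = "")
  for (ch in names(x$roles)) {
    n <- sum(x$atoms$chain == ch)
    cat("  chain ", ch, " [", x$roles[[ch]], "]: ", n, " atoms\n", sep = "")
  }
  invisible(x)
}

#' Coordinate matrix of an atomic model
#'
#' @param model an `atomic_model`.
#' @return n x 3 numeric matrix of positions in Angstrom.
#' @export
model_coords <- function(model) {
  stopifnot(inherits(model, "atomic_model"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Assign chain roles
#'
#' @param model an `atomic_model`.
#' @param roles named character vector, chain id -> role tag.
#' @return The model with roles updated.
#' @export
set_roles <- function(model, roles) {
  atomic_model(model$atoms, roles = replace(as.list(model$roles),
                                            names(roles), roles))
}

#' Apply a rigid transform to a model
#'
#' Positions become `R %*% x + t` (active convention).
#'
#' @param model an `atomic_model`.
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation length-3 vector in Angstrom (default zero).
#' @return Transformed `atomic_model`.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- model_coords(model)
  new_xyz <- sweep(xyz %*% t(rotation), 2, -translation)
  atoms <- model$atoms
  atoms$x <- new_xyz[, 1]
  atoms$y <- new_xyz[, 2]
  atoms$z <- new_xyz[, 3]
  atomic_model(atoms, roles = model$roles)
}

#' Read an atomic model from a PDB file
#'
#' Parses ATOM and HETATM records via bio3d.  Alternate locations other than
#' blank/'A' are dropped; insertion codes are rejected with an error (toy and
#' canonical inputs never carry them, and silently reinterpreting them would
#' corrupt residue numbering).
#'
#' @param path PDB file path.
#' @param roles optional named character vector, chain id -> role tag.
#' @return An `atomic_model`.
#' @export
read_model <- function(path, roles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no ATOM/HETATM records in ", path)
  if (any(!is.na(at$insert) & nzchar(at$insert))) {
    stop("insertion codes present in ", path, "; not supported")
  }
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms left after alternate-location filtering in ", path)
  elesy <- at$elesy
  elesy[is.na(elesy)] <- ""
  atomic_model(
    data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
               elety = at$elety, elesy = elesy,
               x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE),
    roles = roles
  )
}

#' Write an atomic model to a PDB file
#'
#' Fixed-column ATOM records, coordinates in Angstrom.  Output is
#' deterministic: writing the same model twice yields byte-identical files.
#'
#' @param model an `atomic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  at <- model$atoms
  n <- nrow(at)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(model_coords(model))),
    type = rep("ATOM", n),
    resno = at$resno, resid = at$resid,
    eleno = seq_len(n), elety = at$elety,
    chain = at$chain, elesy = at$elesy,
    o = rep(1, n), b = rep(0, n)
  )
  invisible(path)
}

chains_with_role <- function(model, role_filter) {
  names(model$roles)[model$roles %in% role_filter]
}

#' Centroid of lysine alpha-carbons
#'
#' Mean position of the CA atoms of all LYS residues in chains whose role is
#' in `role_filter`.  Used as the single-point stand-in for the randomly
#' amine-labelled fluorophores on a Fab: with many labelled molecules the
#' measured FRET distance reports on the fluorophore centroid.
#'
#' @param model an `atomic_model`.
#' @param role_filter character vector of role tags (default the Fab roles).
#' @return Length-3 numeric vector in Angstrom.
#' @export
lysine_centroid <- function(model, role_filter = c("fab_heavy", "fab_light")) {
  chains <- chains_with_role(model, role_filter)
  if (length(chains) == 0L) {
    stop("no chains carry role(s): ", paste(role_filter, collapse = ", "))
  }
  at <- model$atoms
  sel <- at$chain %in% chains & at$resid == "LYS" & at$elety == "CA"
  if (!any(sel)) {
    stop("no lysine CA atoms found in chains ", paste(chains, collapse = ", "),
         " (check the chain-role assignment)")
  }
  unname(colMeans(as.matrix(at[sel, c("x", "y", "z")])))
}
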