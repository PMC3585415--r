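#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' matched coordinate pairs.  `P` (mobile) is mapped onto `Q` (reference) as
#' `x -> R x + t`.
#'
#' @param P,Q n x 3 coordinate matrices of matched points, n >= 3 and
#'   non-collinear.
#' @return An object of class `superposition`: list with `rotation` (3x3,
#'   det +1), `translation` (3-vector), `rmsd` (Angstrom).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L) {
    stop("P and Q must be matched n x 3 matrices")
  }
  if (nrow(P) < 3L) stop("at least 3 matched pairs are required")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  # collinear sets leave the rotation about the common axis undetermined
  if (sum(svd(P0)$d > 1e-8 * max(1, max(abs(P0)))) < 2L) {
    stop("matched points are collinear; superposition is underdetermined")
  }
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cq - as.numeric(R %*% cp)
  aligned <- sweep(P %*% t(R), 2, -t_vec)
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "superposition")
}

#' Superpose one model onto another over matched CA atoms
#'
#' @param mobile,reference `atomic_model`s.
#' @param pairing data.frame with columns `mobile_chain`, `mobile_resno`,
#'   `ref_chain`, `ref_resno`; each row matches one CA atom in `mobile` to
#'   one in `reference`.
#' @return A `superposition` (see [kabsch()]).
#' @export
superpose <- function(mobile, reference, pairing) {
  required <- c("mobile_chain", "mobile_resno", "ref_chain", "ref_resno")
  if (!all(required %in% names(pairing))) {
    stop("pairing must have columns ", paste(required, collapse = ", "))
  }
  if (nrow(pairing) < 3L) stop("at least 3 matched pairs are required")
  get_ca <- function(model, chain, resno, label) {
    at <- model$atoms
    hit <- at[at$chain == chain & at$resno == resno & at$elety == "CA", ,
              drop = FALSE]
    if (nrow(hit) == 0L) {
      stop("no CA atom for ", label, " chain ", chain, " residue ", resno)
    }
    as.numeric(hit[1L, c("x", "y", "z")])
  }
  P <- t(mapply(function(ch, rn) get_ca(mobile, ch, rn, "mobile"),
                pairing$mobile_chain, pairing$mobile_resno))
  Q <- t(mapply(function(ch, rn) get_ca(reference, ch, rn, "reference"),
                pairing$ref_chain, pairing$ref_resno))
  kabsch(P, Q)
}

#' Apply a superposition to a model
#'
#' @param model an `atomic_model`.
#' @param sp a `superposition`.
#' @return Transformed `atomic_model`.
#' @export
apply_superposition <- function(model, sp) {
  stopifnot(inherits(sp, "superposition"))
  transform_model(model, rotation = sp$rotation, translation = sp$translation)
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd =", format(x$rmsd, digits = 4), "Angstrom\n")
  invisible(x)
}
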