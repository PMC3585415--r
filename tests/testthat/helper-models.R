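# Fixture builders shared across test files.  Everything is generated in
# code; no binary fixtures.

make_atoms <- function(chain, resno, resid, elety, elesy, xyz) {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             elesy = elesy, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# minimal alpha rod: CA trace up z with SG-bearing cysteines at the top,
# terminal residue 1 at the origin; canonical by construction
tiny_alpha_rod <- function(n = 6, spacing = 5) {
  zs <- (seq_len(n) - 1) * spacing
  resid <- c(rep("GLY", n - 2), "CYS", "CYS")
  df <- make_atoms("A", seq_len(n), resid, "CA", "C",
                   cbind(0, 0, zs))
  top <- zs[n]
  df <- rbind(df,
              make_atoms("A", n - 1, "CYS", "SG", "S", cbind(2, 0, top)),
              make_atoms("A", n, "CYS", "SG", "S", cbind(-2, 0, top)))
  atomic_model(df, roles = c(A = "alpha"))
}

tiny_calf_spec <- function(n = 6) {
  calf_vector_spec(cys_pair = c(n - 1, n), terminal_residue = 1)
}

# pseudo-Fab: n lysine CA atoms with centred jitter so the centroid is exact
pseudo_fab <- function(centroid, n = 10, seed = 42, chain = "F") {
  set.seed(seed)
  jit <- matrix(runif(n * 3, -4, 4), ncol = 3)
  jit <- sweep(jit, 2, colMeans(jit))
  atomic_model(
    make_atoms(chain, seq_len(n), "LYS", "CA", "C",
               sweep(jit, 2, -centroid)),
    roles = stats::setNames("fab_heavy", chain)
  )
}

merge_models <- function(a, b) {
  atomic_model(rbind(a$atoms, b$atoms), roles = c(a$roles, b$roles))
}

# asymmetric chiral tripod: its projections determine the view uniquely
make_tripod <- function(chain = "A", role = "alpha") {
  pts <- rbind(
    t(sapply(seq(0, 50, 5), function(s) c(s, 0, 0))),
    t(sapply(seq(5, 30, 5), function(s) c(0, s, 0))),
    t(sapply(seq(5, 40, 5), function(s) c(0, 0, s))),
    c(15, 15, 10)
  )
  atomic_model(
    make_atoms(chain, seq_len(nrow(pts)), "GLY", "CA", "C", pts),
    roles = stats::setNames(role, chain)
  )
}

# smaller bent L with an out-of-plane knob (stand-in for a Fab moiety)
make_lshape <- function(chain = "F", role = "fab_heavy") {
  pts <- rbind(
    t(sapply(seq(0, 28, 4), function(s) c(s, 0, 0))),
    t(sapply(seq(4, 16, 4), function(s) c(0, s, 0))),
    c(8, 4, 8)
  )
  atomic_model(
    make_atoms(chain, seq_len(nrow(pts)), "LYS", "CA", "C", pts),
    roles = stats::setNames(role, chain)
  )
}

# random proper rotation (QR of a Gaussian matrix, det forced to +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# naive per-sample scan oracle: rebuilds the rotation matrix and transforms
# every atom at every grid point (the implementation under test uses a
# closed-form z row instead)
naive_scan_oracle <- function(framed, plane, step = 5,
                              fab_roles = c("fab_heavy", "fab_light")) {
  phis <- seq(0, 360 - step, by = step)
  rhos <- seq(0, 180, by = step)
  out <- list()
  for (ph in phis) {
    for (rh in rhos) {
      m <- rotate_model(framed, ph, rh)
      out[[length(out) + 1L]] <- data.frame(
        phi = ph, rho = rh,
        clash = clashes_membrane(m, plane),
        centroid_distance = centroid_distance(m, plane, fab_roles = fab_roles)
      )
    }
  }
  do.call(rbind, out)
}
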