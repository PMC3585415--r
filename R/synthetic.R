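# run `expr` under a private RNG seed, restoring the caller's RNG state
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Toy receptor/Fab model specification
#'
#' Geometry of a minimal stand-in for a membrane receptor with a labelled
#' Fab: an alpha-chain rod of pseudo-residues (the "leg"), a short beta-chain
#' stub, and a pseudo-Fab blob of lysines whose CA centroid lands at an
#' analytically known offset.  Defaults give a 100 Angstrom leg (the scale of
#' a bent integrin ectodomain) with the Fab centroid 71 Angstrom above the
#' leg terminus -- the distance the FLIM analysis reports for the motivating
#' receptor -- and 25 Angstrom off-axis so the scan geometry is non-trivial.
#'
#' @param leg_length leg rod length in Angstrom (> 0).
#' @param head_offset 3-vector, Angstrom: position of the Fab lysine
#'   centroid relative to the leg terminus.
#' @param n_fab_lysines number of pseudo-Fab lysines (>= 1).
#' @param seed integer seed controlling the (centred) lysine jitter.
#' @return Object of class `toy_integrin_spec`.
#' @export
toy_integrin_spec <- function(leg_length = 100, head_offset = c(25, 0, 71),
                              n_fab_lysines = 10, seed = 1) {
  if (leg_length <= 0) stop("leg_length must be positive")
  if (n_fab_lysines < 1) stop("n_fab_lysines must be >= 1")
  stopifnot(length(head_offset) == 3L)
  structure(list(leg_length = leg_length, head_offset = as.numeric(head_offset),
                 n_fab_lysines = as.integer(n_fab_lysines),
                 seed = as.integer(seed)),
            class = "toy_integrin_spec")
}

#' Build a toy receptor/Fab atomic model
#'
#' Chain A (role `alpha`) is a CA rod from the origin up the z axis, spaced
#' 5 Angstrom, terminating at residue 1 at (0,0,0); its two topmost residues
#' are cysteines carrying SG atoms placed symmetrically about the rod axis,
#' so the disulfide-centre anchor lies exactly on the axis and the model is
#' canonical by construction.  Chain B (role `beta`) is a short parallel
#' stub.  Chain F (role `fab_heavy`) holds `n_fab_lysines` LYS CA atoms with
#' centred jitter, so their centroid equals `head_offset` exactly.
#' Deterministic given the spec seed.
#'
#' @param spec a [toy_integrin_spec()].
#' @param path optional PDB output path.
#' @return An `atomic_model` with the matching [calf_vector_spec()] in
#'   attribute `"calf_spec"` and the generating spec in `"toy_spec"`.
#' @export
make_toy_integrin <- function(spec = toy_integrin_spec(), path = NULL) {
  stopifnot(inherits(spec, "toy_integrin_spec"))
  spacing <- 5
  n_leg <- max(3L, as.integer(round(spec$leg_length / spacing)) + 1L)
  z_leg <- seq(0, spec$leg_length, length.out = n_leg)
  resid_a <- c(rep("GLY", n_leg - 2L), "CYS", "CYS")

  rows <- list()
  add <- function(chain, resno, resid, elety, elesy, pos) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, resid = resid, elety = elety,
      elesy = elesy, x = pos[1], y = pos[2], z = pos[3],
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_leg)) {
    add("A", i, resid_a[i], "CA", "C", c(0, 0, z_leg[i]))
  }
  top <- spec$leg_length
  add("A", n_leg - 1L, "CYS", "SG", "S", c(1.5, 0, top))
  add("A", n_leg, "CYS", "SG", "S", c(-1.5, 0, top))

  for (i in seq_len(5L)) {
    add("B", i, "GLY", "CA", "C", c(8, 0, (i - 1) * spacing))
  }

  jitter <- with_private_seed(spec$seed, {
    m <- matrix(runif(spec$n_fab_lysines * 3L, -5, 5),
                ncol = 3L)
    sweep(m, 2, colMeans(m))   # centred: centroid lands exactly on target
  })
  for (i in seq_len(spec$n_fab_lysines)) {
    add("F", i, "LYS", "CA", "C", spec$head_offset + jitter[i, ])
  }

  model <- atomic_model(do.call(rbind, rows),
                        roles = c(A = "alpha", B = "beta", F = "fab_heavy"))
  attr(model, "calf_spec") <- calf_vector_spec(cys_pair = c(n_leg - 1L, n_leg),
                                               terminal_residue = 1L)
  attr(model, "toy_spec") <- spec
  if (!is.null(path)) write_model(model, path)
  model
}

#' Lifetime simulation specification
#'
#' Defaults are the study conditions of the motivating experiment: per-cell
#' mean lifetimes drawn from a Gaussian, 176 cells per condition (back-solved
#' so that a 95% CI of +/-13 ps on the fitted mean corresponds to sigma = 88
#' ps).  A non-zero `outlier_fraction` replaces that fraction of cells with
#' uniform draws over mu +/- 6 sigma, mimicking the minor off-distribution
#' cell populations seen in real data.
#'
#' @param n_cells number of cells (>= 1).
#' @param mu,sigma Gaussian mean and SD of per-cell lifetimes, ps.
#' @param outlier_fraction fraction in \[0, 1\] of uniform outliers.
#' @param seed integer seed.
#' @return Object of class `lifetime_sim_spec`.
#' @export
lifetime_sim_spec <- function(n_cells = 176, mu = 2234, sigma = 88,
                              outlier_fraction = 0, seed = 1) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (sigma <= 0) stop("sigma must be positive")
  if (outlier_fraction < 0 || outlier_fraction > 1) {
    stop("outlier_fraction must be in [0, 1]")
  }
  structure(list(n_cells = as.integer(n_cells), mu = mu, sigma = sigma,
                 outlier_fraction = outlier_fraction, seed = as.integer(seed)),
            class = "lifetime_sim_spec")
}

simulate_one_condition <- function(spec) {
  with_private_seed(spec$seed, {
    x <- rnorm(spec$n_cells, spec$mu, spec$sigma)
    n_out <- round(spec$outlier_fraction * spec$n_cells)
    if (n_out > 0) {
      idx <- sample.int(spec$n_cells, n_out)
      x[idx] <- runif(n_out, spec$mu - 6 * spec$sigma, spec$mu + 6 * spec$sigma)
    }
    pmax(x, 1)  # lifetimes are physically positive
  })
}

#' Simulate per-cell lifetime datasets for both FLIM conditions
#'
#' Independent Gaussian draws per cell for the donor-only and donor+acceptor
#' conditions; deterministic per seed.  Defaults reproduce the statistical
#' texture of the motivating experiment (donor 2,234 +/- 88 ps; quenched
#' 1,529 +/- 115 ps; 176 cells each).
#'
#' @param spec_donor [lifetime_sim_spec()] for the donor-only condition.
#' @param spec_da [lifetime_sim_spec()] for the donor+acceptor condition.
#' @param path optional CSV output path (columns cell_id, condition,
#'   lifetime_ps).
#' @return List with `donor_only` and `donor_acceptor`
#'   ([lifetime_dataset()]s) and `table` (the combined data.frame).
#' @export
simulate_lifetimes <- function(spec_donor = lifetime_sim_spec(),
                               spec_da = lifetime_sim_spec(mu = 1529,
                                                           sigma = 115,
                                                           seed = 2),
                               path = NULL) {
  stopifnot(inherits(spec_donor, "lifetime_sim_spec"),
            inherits(spec_da, "lifetime_sim_spec"))
  d <- simulate_one_condition(spec_donor)
  da <- simulate_one_condition(spec_da)
  tab <- data.frame(
    cell_id = c(sprintf("d%03d", seq_along(d)), sprintf("a%03d", seq_along(da))),
    condition = c(rep("donor_only", length(d)),
                  rep("donor_acceptor", length(da))),
    lifetime_ps = c(d, da),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) write.csv(tab, path, row.names = FALSE)
  list(donor_only = lifetime_dataset(d, "donor_only"),
       donor_acceptor = lifetime_dataset(da, "donor_acceptor"),
       table = tab)
}

#' Build a synthetic class average with known ground truth
#'
#' Projects one or two atomic models at specified view orientations, applies
#' a common in-plane rotation and shift, and adds averaged Gaussian noise
#' with SD `noise_sd * peak / sqrt(n_averaged)` (a class average of
#' `n_averaged` particles suppresses per-image noise by the square root of
#' the count).  The full ground truth is attached as attribute
#' `"ground_truth"` and optionally written to a JSON side-car.
#'
#' @param model_a an `atomic_model` (first body).
#' @param model_b optional second body (`NULL` to omit, e.g. for negative
#'   controls).
#' @param euler_a,euler_b `(phi, theta)` view angles, degrees.
#' @param shift_a,shift_b per-body in-plane shifts in pixels (the projected
#'   displacement of each body within the particle).
#' @param inplane list with `omega` (degrees) and `shift` (pixels) applied
#'   to the composite.
#' @param noise_sd per-image noise SD as a fraction of the signal peak.
#' @param n_averaged number of particles notionally averaged.
#' @param seed integer seed for the noise.
#' @param voxel_size,box,resolution density-simulation settings (Angstrom,
#'   voxels, Angstrom).
#' @param path optional MRC output path; a `.json` side-car with the ground
#'   truth is written alongside it.
#' @return A `projection_image`.
#' @export
make_synthetic_class_average <- function(model_a, model_b = NULL,
                                         euler_a = c(0, 90),
                                         euler_b = c(0, 90),
                                         shift_a = c(0, 0),
                                         shift_b = c(0, 0),
                                         inplane = list(omega = 0,
                                                        shift = c(0, 0)),
                                         noise_sd = 0, n_averaged = 1,
                                         seed = 1,
                                         voxel_size = 6, box = 32,
                                         resolution = 18, path = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  comp <- project_model(model_a, euler_a[1], euler_a[2],
                        pixel_size = voxel_size, box = box,
                        resolution = resolution, shift = shift_a)$pixels
  if (!is.null(model_b)) {
    comp <- comp + project_model(model_b, euler_b[1], euler_b[2],
                                 pixel_size = voxel_size, box = box,
                                 resolution = resolution,
                                 shift = shift_b)$pixels
  }
  if (inplane$omega != 0) comp <- rotate_image(comp, inplane$omega)
  if (any(inplane$shift != 0)) comp <- shift_image(comp, inplane$shift)
  peak <- max(abs(comp))
  if (noise_sd > 0 && peak > 0) {
    noise <- with_private_seed(seed, {
      matrix(rnorm(box * box, 0, noise_sd * peak / sqrt(n_averaged)), box, box)
    })
    comp <- comp + noise
  }
  img <- projection_image(comp, pixel_size = voxel_size)
  truth <- list(euler_a = euler_a,
                euler_b = if (is.null(model_b)) NULL else euler_b,
                shift_a = shift_a,
                shift_b = if (is.null(model_b)) NULL else shift_b,
                inplane = inplane, noise_sd = noise_sd,
                n_averaged = n_averaged, seed = seed,
                voxel_size = voxel_size, box = box, resolution = resolution)
  attr(img, "ground_truth") <- truth
  if (!is.null(path)) {
    write_mrc(img, path)
    jsonlite::write_json(truth, paste0(sub("\\.mrc$", "", path), ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  img
}
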