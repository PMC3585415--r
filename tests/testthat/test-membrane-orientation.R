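framed_toy <- function(leg = 100, head = c(25, 0, 71)) {
  toy <- make_toy_integrin(toy_integrin_spec(leg_length = leg,
                                             head_offset = head))
  canonicalize(toy, attr(toy, "calf_spec"))
}

test_that("rotate_model applies Ry(rho) Rz(phi) rigidly", {
  fr <- framed_toy()
  xyz0 <- model_coords(fr$model)

  # identity at (0, 0)
  expect_lt(max(abs(model_coords(rotate_model(fr, 0, 0)) - xyz0)), 1e-9)

  # rho = 0 leaves every z unchanged for any phi
  for (ph in c(30, 137, 290)) {
    expect_equal(model_coords(rotate_model(fr, ph, 0))[, 3], xyz0[, 3],
                 tolerance = 1e-9)
  }

  # hand-rotation: the leg-top atom at (0,0,100) goes to (100,0,0) at (90,90)
  rot <- model_coords(rotate_model(fr, 90, 90))
  i <- which(abs(xyz0[, 3] - 100) < 1e-9 & abs(xyz0[, 1]) < 1e-9 &
               abs(xyz0[, 2]) < 1e-9)[1]
  expect_equal(rot[i, ], c(100, 0, 0), tolerance = 1e-6,
               ignore_attr = TRUE)

  # rigidity under arbitrary angles
  before <- dist(xyz0)
  after <- dist(model_coords(rotate_model(fr, 123, 47)))
  expect_equal(as.vector(after), as.vector(before), tolerance = 1e-6)
})

test_that("membrane clash flags any atom strictly below the plane", {
  pts <- make_atoms("A", 1:3, "GLY", "CA", "C",
                    rbind(c(0, 0, 0), c(1, 1, 5), c(-2, 3, 10)))
  m <- atomic_model(pts, roles = c(A = "alpha"))
  expect_false(clashes_membrane(m, membrane_plane(0)))
  expect_false(clashes_membrane(m, membrane_plane(-0.01)))
  pts2 <- pts; pts2$z[1] <- -0.01
  expect_true(clashes_membrane(atomic_model(pts2, roles = c(A = "alpha")),
                               membrane_plane(0)))

  # brute-force oracle on random models and planes
  set.seed(5)
  for (k in 1:10) {
    xyz <- matrix(rnorm(300, 0, 20), ncol = 3)
    mm <- atomic_model(make_atoms("A", 1:100, "GLY", "CA", "C", xyz),
                       roles = c(A = "alpha"))
    z0 <- runif(1, -30, 30)
    oracle <- any(sapply(seq_len(100), function(i) xyz[i, 3] < z0))
    expect_identical(clashes_membrane(mm, membrane_plane(z0)), oracle)
  }
})

test_that("centroid distance is the perpendicular distance to the plane", {
  fab <- pseudo_fab(c(12, -8, 66))
  expect_equal(centroid_distance(fab, membrane_plane(-5)), 71)

  # direct arithmetic oracle
  at <- fab$atoms
  direct <- abs(mean(at$z[at$resid == "LYS" & at$elety == "CA"]) + 5)
  expect_equal(centroid_distance(fab, membrane_plane(-5)), direct)

  # invariant across phi at rho = 0
  fr <- framed_toy()
  pl <- membrane_plane(-5)
  d0 <- centroid_distance(rotate_model(fr, 0, 0), pl)
  for (ph in seq(0, 315, 45)) {
    expect_equal(centroid_distance(rotate_model(fr, ph, 0), pl), d0,
                 tolerance = 1e-9)
  }
})

test_that("orientation scan matches the naive per-sample oracle exactly", {
  fr <- framed_toy(leg = 60, head = c(20, 0, 45))
  pl <- membrane_plane(-5)
  res <- orientation_scan(fr, pl, step = 15)
  oracle <- naive_scan_oracle(fr, pl, step = 15)
  s <- res$samples[order(res$samples$phi, res$samples$rho), ]
  o <- oracle[order(oracle$phi, oracle$rho), ]
  expect_identical(s$clash, o$clash)
  expect_equal(s$centroid_distance, o$centroid_distance, tolerance = 1e-9)
  expect_equal(res$n_allowed, sum(!oracle$clash))
})

test_that("scan grid has the documented shape and degenerate cases behave", {
  fr <- framed_toy()
  # 5 degree grid: 72 x 37 = 2664 samples
  res <- orientation_scan(fr, membrane_plane(-5), step = 5)
  expect_equal(res$n_samples, 2664L)
  expect_equal(sort(unique(res$samples$phi)), seq(0, 355, 5))
  expect_equal(sort(unique(res$samples$rho)), seq(0, 180, 5))

  # tiny model far above the plane, rho restricted: everything allowed
  high <- atomic_model(
    make_atoms("A", 1:3, c("GLY", "CYS", "CYS"), "CA", "C",
               rbind(c(0, 0, 100), c(0, 0, 103), c(0, 0, 106))),
    roles = c(A = "alpha"))
  high <- merge_models(high, pseudo_fab(c(0, 0, 110), n = 3))
  frh <- structure(list(model = high, calf_vector = c(0, 0, 1)),
                   class = "framed_model")
  resh <- orientation_scan(frh, membrane_plane(-1000), step = 15,
                           rho_range = c(0, 90))
  expect_equal(resh$n_allowed, resh$n_samples)

  # plane above all atoms: the (0, 0) sample clashes
  res0 <- orientation_scan(framed_toy(), membrane_plane(200), step = 45)
  s00 <- res0$samples[res0$samples$phi == 0 & res0$samples$rho == 0, ]
  expect_true(s00$clash)

  # empty allowed set is flagged, not an error
  expect_false(res0$statistics_defined)
  expect_true(is.na(res0$statistics$tilt_mean))

  expect_error(orientation_scan(fr, membrane_plane(0), step = 7), "evenly")
})

test_that("FLIM constraint selects engineered orientations and is monotone", {
  fr <- framed_toy(head = c(25, 0, 71))
  pl <- membrane_plane(0)           # linker offset 0
  res <- orientation_scan(fr, pl, step = 5)

  # by construction the (0, 0) sample has centroid distance exactly 71
  s00 <- res$samples[res$samples$phi == 0 & res$samples$rho == 0, ]
  expect_equal(s00$centroid_distance, 71, tolerance = 1e-9)

  con <- apply_flim_constraint(res, target = 71, tolerance = 0.5)
  sel <- con$samples[con$samples$flim_consistent, ]
  expect_true(any(sel$phi == 0 & sel$rho == 0))
  # oracle recomputation of every selected sample
  oracle <- naive_scan_oracle(fr, pl, step = 5)
  key <- paste(oracle$phi, oracle$rho)
  od <- stats::setNames(oracle$centroid_distance, key)
  oc <- stats::setNames(oracle$clash, key)
  for (k in seq_len(nrow(sel))) {
    kk <- paste(sel$phi[k], sel$rho[k])
    expect_false(oc[[kk]])
    expect_lte(abs(od[[kk]] - 71), 0.5)
  }

  # tolerance = Inf keeps the whole allowed set
  all_in <- apply_flim_constraint(res, target = 71, tolerance = Inf)
  expect_equal(all_in$n_flim_consistent, all_in$n_allowed)

  # tolerance 0 with an incommensurate target selects nothing
  none <- apply_flim_constraint(res, target = 71.0001, tolerance = 0)
  expect_equal(none$n_flim_consistent, 0L)

  # monotone in tolerance
  counts <- sapply(c(0.5, 1, 2.5, 5, 10),
                   function(tol) apply_flim_constraint(res, 71, tol)$n_flim_consistent)
  expect_true(all(diff(counts) >= 0))
})

test_that("subset chain holds across random scans", {
  set.seed(9)
  for (k in 1:4) {
    fr <- framed_toy(leg = runif(1, 40, 120),
                     head = c(runif(1, -40, 40), runif(1, -40, 40),
                              runif(1, 20, 90)))
    res <- orientation_scan(fr, membrane_plane(-runif(1, 0, 10)), step = 15)
    res <- apply_flim_constraint(res, target = runif(1, 30, 90),
                                 tolerance = runif(1, 0, 5))
    expect_lte(res$n_flim_consistent, res$n_allowed)
    expect_lte(res$n_allowed, res$n_samples)
    # raising the model off the plane never creates new clashes
    lifted <- fr
    lifted$model <- transform_model(fr$model, translation = c(0, 0, 25))
    res_l <- orientation_scan(lifted, res$plane, step = 15)
    expect_true(all(res_l$samples$allowed >= res$samples$allowed))
  }
})

test_that("angle statistics: arithmetic tilt, circular phi", {
  st <- angle_statistics(data.frame(tilt = c(50, 55, 60), phi = c(10, 20, 30)))
  expect_equal(st$tilt_mean, 55)
  expect_equal(st$tilt_sd, 5)

  # wrap-around: 350 and 10 average to 0
  cs <- circular_stats(c(350, 10))
  expect_equal(cs$mean, 0, tolerance = 1e-9)

  # simulation recovery of a wrapped normal near the wrap point
  set.seed(77)
  draws <- (rnorm(1000, 323.6, 14.6)) %% 360
  cs2 <- circular_stats(draws)
  expect_lt(abs(cs2$mean - 323.6), 1.5)
  expect_lt(abs(cs2$sd - 14.6), 1.5)

  expect_error(angle_statistics(data.frame(tilt = numeric(0),
                                           phi = numeric(0))), "samples")
})

test_that("scan CSV export round-trips the sample table", {
  fr <- framed_toy()
  res <- apply_flim_constraint(orientation_scan(fr, membrane_plane(-5),
                                                step = 30), 71, 2.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_scan_csv(res, f)
  back <- read.csv(f, comment.char = "#")
  expect_equal(nrow(back), res$n_samples)
  expect_equal(sum(back$flim_consistent), res$n_flim_consistent)
})
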