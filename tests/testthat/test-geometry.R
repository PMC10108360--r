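test_that("make_whole applies the minimum image across the boundary", {
  fr <- make_frame(rbind(c(0.1, 0, 0), c(9.9, 0, 0)))
  out <- make_whole(fr, 1:2, rbind(c(1L, 2L)))
  expect_equal(unname(out[2, ]), c(-0.1, 0, 0))
  expect_equal(unname(out[1, ]), c(0.1, 0, 0))  # root unchanged

  # already-whole molecule is returned unchanged
  fr2 <- make_frame(rbind(c(1, 1, 1), c(1.2, 1, 1)))
  expect_equal(make_whole(fr2, 1:2, rbind(c(1L, 2L))),
               fr2$coords, ignore_attr = TRUE)
})

test_that("a scattered chain unwraps to its original geometry", {
  set.seed(5)
  for (rep in 1:5) {
    steps <- matrix(runif(19 * 3, -0.4, 0.4), 19)
    whole <- apply(rbind(c(5, 5, 5), steps), 2, cumsum)
    box <- c(10, 10, 10)
    wrapped <- whole %% matrix(box, 20, 3, byrow = TRUE)
    fr <- make_frame(wrapped, box = box)
    bonds <- cbind(1:19, 2:20)
    out <- make_whole(fr, 1:20, bonds)
    # translationally consistent with the original chain
    shift <- out[1, ] - whole[1, ]
    expect_equal(unname(out), unname(whole + matrix(shift, 20, 3,
                                                    byrow = TRUE)),
                 tolerance = 1e-12)
    dists <- sqrt(rowSums((out[1:19, ] - out[2:20, ])^2))
    expect_true(all(dists < 5))
  }
})

test_that("a disconnected bond graph is reported with its components", {
  fr <- make_frame(rbind(c(1, 1, 1), c(2, 1, 1), c(5, 5, 5)))
  expect_error(make_whole(fr, 1:3, rbind(c(1L, 2L))), "disconnected")
})

test_that("center_of_mass matches the direct mass-weighted sum", {
  expect_equal(center_of_mass(rbind(c(0, 0, 0), c(0, 0, 2)), c(1, 1)),
               c(0, 0, 1))
  expect_equal(center_of_mass(rbind(c(3, 2, 1)), 7), c(3, 2, 1))
  set.seed(8)
  xyz <- matrix(rnorm(300), 100)
  m <- runif(100, 0.5, 40)
  expect_equal(center_of_mass(xyz, m),
               c(sum(xyz[, 1] * m), sum(xyz[, 2] * m), sum(xyz[, 3] * m)) /
                 sum(m))
  expect_error(center_of_mass(rbind(c(0, 0, 0)), 0), "zero total mass")
})

test_that("membrane_frame recovers the bilayer center and is equivariant", {
  coords <- rbind(c(1, 1, 3), c(2, 2, 7))
  fr <- make_frame(coords)
  masses <- c(10, 10)
  expect_equal(membrane_frame(fr, 1:2, masses)$z_center, 5)
  fr_shift <- make_frame(coords + matrix(c(0, 0, 1), 2, 3, byrow = TRUE))
  expect_equal(membrane_frame(fr_shift, 1:2, masses)$z_center, 6)
  expect_error(membrane_frame(fr, integer(0), masses), "empty lipid group")

  scen <- cached_scenario("geom40", scenario_config(n_frames = 40, seed = 9))
  zc <- vapply(scen$trajectory$frames, function(f) {
    membrane_frame(f, scen$groups$lipids, scen$trajectory$atoms$mass)$z_center
  }, numeric(1))
  expect_true(all(abs(zc - scen$config$box[3] / 2) < 0.05))
})

test_that("aligned and mirrored ligands give theta = 0 at the same depth", {
  sys <- manual_ligand_system(axis_dir = c(0, 0, 1), oh_target = c(5, 5, 6.6))
  mem <- membrane_frame(sys$frame, sys$lipid_idx, sys$atoms$mass)
  s <- ligand_orientation(sys$frame, sys$spec, 1L, mem, sys$atoms)
  expect_equal(s$theta, 0, tolerance = 1e-8)
  expect_equal(s$depth, 1.6, tolerance = 1e-8)
  expect_equal(s$leaflet, "upper")

  # mirror through the bilayer midplane: lower leaflet, same (theta, depth)
  mirrored <- sys$frame
  mirrored$coords[, 3] <- (2 * mem$z_center - mirrored$coords[, 3]) %%
    sys$frame$box[3]
  mem2 <- membrane_frame(mirrored, sys$lipid_idx, sys$atoms$mass)
  s2 <- ligand_orientation(mirrored, sys$spec, 1L, mem2, sys$atoms)
  expect_equal(s2$theta, s$theta, tolerance = 1e-8)
  expect_equal(s2$depth, s$depth, tolerance = 1e-8)
  expect_equal(s2$leaflet, "lower")
})

test_that("a 45-degree tilt matches the arccos oracle", {
  sys <- manual_ligand_system(axis_dir = c(1, 0, 1) / sqrt(2),
                              oh_target = c(5, 5, 6.6))
  mem <- membrane_frame(sys$frame, sys$lipid_idx, sys$atoms$mass)
  s <- ligand_orientation(sys$frame, sys$spec, 1L, mem, sys$atoms)
  expect_equal(s$theta, acos(1 / sqrt(2)) * 180 / pi, tolerance = 1e-6)
})

test_that("leaflet mirroring and box translation leave all samples unchanged", {
  scen <- cached_scenario("geom30", scenario_config(n_frames = 30, seed = 12))
  traj <- scen$trajectory
  ref <- orientation_samples(traj, scen$spec, scen$groups$lipids)

  zmid <- scen$config$box[3] / 2
  mirrored <- traj
  for (i in seq_along(mirrored$frames)) {
    mirrored$frames[[i]]$coords[, 3] <-
      (2 * zmid - mirrored$frames[[i]]$coords[, 3]) %%
      mirrored$frames[[i]]$box[3]
  }
  sm <- orientation_samples(mirrored, scen$spec, scen$groups$lipids)
  expect_equal(sm$theta, ref$theta, tolerance = 1e-9)
  expect_equal(sm$depth, ref$depth, tolerance = 1e-9)

  shifted <- traj
  delta <- c(1.3, -0.7, 2.9)
  for (i in seq_along(shifted$frames)) {
    box <- shifted$frames[[i]]$box
    shifted$frames[[i]]$coords <-
      (shifted$frames[[i]]$coords +
         matrix(delta, nrow(shifted$frames[[i]]$coords), 3, byrow = TRUE)) %%
      matrix(box, nrow(shifted$frames[[i]]$coords), 3, byrow = TRUE)
  }
  st <- orientation_samples(shifted, scen$spec, scen$groups$lipids)
  expect_equal(st$theta, ref$theta, tolerance = 1e-9)
  expect_equal(st$depth, ref$depth, tolerance = 1e-9)
})

test_that("theta and depth stay in their physical ranges across seeds", {
  for (seed in c(21, 22, 23)) {
    scen <- generate_scenario(scenario_config(
      n_frames = 15, n_waters = 30, n_ions = 2, seed = seed,
      tilt_mean = sample(c(20, 90, 160), 1), tilt_sd = 25,
      depth_mean = runif(1, 0.3, 2.2), depth_sd = 0.5))
    s <- orientation_samples(scen$trajectory, scen$spec, scen$groups$lipids)
    expect_true(all(s$theta >= 0 & s$theta <= 180))
    expect_true(all(s$depth >= 0 & s$depth <= scen$config$box[3] / 2))
  }
})
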