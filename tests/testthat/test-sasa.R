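test_that("an isolated sphere reproduces its analytic area", {
  fr <- make_frame(c(5, 5, 5))
  st <- sasa_settings()
  a <- shrake_rupley(fr, 1L, integer(0), radii = 0.152, st)
  analytic <- 4 * pi * (0.152 + 0.14)^2
  expect_lte(abs(a[[1]] - analytic), analytic / st$n_dots)

  # fully buried atom: surrounded by a tight shell of occluders
  shell <- fibonacci_sphere(60) * 0.1
  fr2 <- make_frame(rbind(c(5, 5, 5),
                          sweep(shell, 2, c(5, 5, 5), "+")))
  a2 <- shrake_rupley(fr2, 1L, 1:61, radii = rep(0.152, 61), st)
  expect_equal(a2[[1]], 0)
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  st <- sasa_settings()
  r <- 0.152
  R <- r + st$probe_radius
  tol <- 4 * pi * R^2 / sqrt(st$n_dots)  # boundary-dot resolution
  for (d in seq(0.05, 2 * R - 0.02, length.out = 12)) {
    fr <- make_frame(rbind(c(10, 10, 10), c(10, 10, 10 + d)),
                     box = c(20, 20, 20))
    a <- shrake_rupley(fr, 1:2, 1:2, radii = c(r, r), st)
    expect_lte(abs(a[[1]] - two_sphere_exposed_area(R, d)), tol)
    expect_lte(abs(a[[2]] - two_sphere_exposed_area(R, d)), tol)
  }
})

test_that("doubling the dot count converges and occlusion is monotone", {
  fr <- make_frame(rbind(c(5, 5, 5), c(5, 5, 5.3), c(5.2, 5, 5)))
  r <- rep(0.152, 3)
  a1 <- shrake_rupley(fr, 1L, 1:2, r, sasa_settings(n_dots = 480))
  a2 <- shrake_rupley(fr, 1L, 1:2, r, sasa_settings(n_dots = 960))
  expect_lt(abs(a1[[1]] - a2[[1]]), 4 * pi * 0.292^2 / sqrt(480))
  # adding an occluder never increases the area
  a3 <- shrake_rupley(fr, 1L, 1:3, r, sasa_settings(n_dots = 960))
  expect_lte(a3[[1]], a2[[1]])
  expect_true(all(a3 >= 0))
})

test_that("rigid rotation leaves areas unchanged within dot tolerance", {
  set.seed(53)
  pts <- matrix(rnorm(15, 0, 0.25), 5)
  ang <- 0.7
  rotz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
  center <- c(10, 10, 10)
  fr1 <- make_frame(sweep(pts, 2, center, "+"), box = c(20, 20, 20))
  fr2 <- make_frame(sweep(pts %*% t(rotz), 2, center, "+"),
                    box = c(20, 20, 20))
  r <- rep(0.16, 5)
  st <- sasa_settings()
  a1 <- shrake_rupley(fr1, 1:5, 1:5, r, st)
  a2 <- shrake_rupley(fr2, 1:5, 1:5, r, st)
  tol <- 4 * pi * (0.16 + 0.14)^2 / sqrt(st$n_dots)
  expect_true(all(abs(a1 - a2) < 2 * tol))
})

test_that("missing radii are reported by atom", {
  fr <- make_frame(rbind(c(5, 5, 5), c(5, 5, 5.2)))
  expect_error(shrake_rupley(fr, 1L, 1:2, radii = c(0.15, NA)),
               "missing vdW radius")
})

test_that("group SASA: vacuum copies are constant, burial reduces exposure", {
  # an unchanging pose with no occluders beyond the molecule itself gives
  # the same area every frame: sd exactly 0
  one <- generate_scenario(scenario_config(n_frames = 1, n_waters = 0,
                                           n_ions = 0, seed = 61))
  fr <- one$trajectory$frames[[1]]
  frames <- lapply(0:5, function(t) list(time = t * 10, box = fr$box,
                                         coords = fr$coords))
  still <- trajectory(one$trajectory$atoms, frames)
  lig_idx <- unlist(lapply(1:4, function(k) {
    resolve_ligand_atoms(still$atoms, one$spec, k, "all")
  }))
  ba <- group_sasa_block_stats(still, one$spec, "oh",
                               sasa_settings(n_dots = 240), n_blocks = 3,
                               occluders = lig_idx)
  expect_equal(ba$sd, 0)

  # hydroxy pinned above the phosphate plane (toward water) vs buried at
  # the bilayer center, membrane + ligand as occluders: exposure ordering
  exposed <- generate_scenario(scenario_config(n_frames = 15, seed = 62,
                                               depth_mean = 2.4,
                                               depth_sd = 0.02))
  buried <- generate_scenario(scenario_config(n_frames = 15, seed = 62,
                                              depth_mean = 0.3,
                                              depth_sd = 0.02))
  st <- sasa_settings(n_dots = 240)
  occ <- function(s) c(s$groups$lipids, unlist(lapply(1:4, function(k) {
    resolve_ligand_atoms(s$trajectory$atoms, s$spec, k, "all")
  })))
  ba_s <- group_sasa_block_stats(exposed$trajectory, exposed$spec, "oh", st,
                                 n_blocks = 3, occluders = occ(exposed))
  ba_b <- group_sasa_block_stats(buried$trajectory, buried$spec, "oh", st,
                                 n_blocks = 3, occluders = occ(buried))
  expect_gt(ba_s$grand_mean, ba_b$grand_mean)
})

test_that("block scheme for SASA follows the 5 x 300-unit layout", {
  scen <- cached_scenario("tiny", scenario_config(n_frames = 2, n_waters = 20,
                                                  n_ions = 2, seed = 42))
  expect_error(group_sasa_block_stats(scen$trajectory, scen$spec, "oh",
                                      n_blocks = 5), "fewer frames")
  ba <- block_average(rep(0.06, 200), n_blocks = 5, frame_dt = 7.5)
  expect_equal(ba$block_length, 300)
})
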