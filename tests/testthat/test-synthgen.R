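test_that("paper-scale composition is honored exactly", {
  cfg <- scenario_config(paper_scale = TRUE, n_frames = 1, seed = 1)
  scen <- generate_scenario(cfg)
  atoms <- scen$trajectory$atoms
  expect_equal(length(unique(atoms$resid[atoms$resname == "LIP"])), 128L)
  expect_equal(length(unique(atoms$resid[atoms$resname == "SOL"])), 6400L)
  expect_equal(sum(atoms$resname == "K"), 128L)
  expect_equal(length(unique(atoms$resid[atoms$resname == "LIG"])), 4L)
})

test_that("generation is byte-identical for a fixed seed", {
  cfg <- scenario_config(n_frames = 3, n_waters = 40, n_ions = 4, seed = 99)
  f1 <- tempfile(fileext = ".gro")
  f2 <- tempfile(fileext = ".gro")
  write_gro(generate_scenario(cfg)$trajectory, f1)
  write_gro(generate_scenario(cfg)$trajectory, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("drawn tilt and depth distributions match their configuration", {
  scen <- cached_scenario("big", scenario_config(n_frames = 1500,
                                                 n_waters = 0, n_ions = 0,
                                                 seed = 101))
  th <- as.vector(scen$truth$theta)
  dp <- as.vector(scen$truth$depth)
  n <- length(th)
  expect_gte(n, 5000)
  expect_lt(abs(mean(th) - 30), 3 * 8 / sqrt(n))
  expect_lt(abs(mean(dp) - 1.65), 3 * 0.08 / sqrt(n))
  expect_lt(abs(sd(th) - 8), 3 * 8 / sqrt(2 * n))
  expect_lt(abs(sd(dp) - 0.08), 3 * 0.08 / sqrt(2 * n))
})

test_that("every injected ideal-geometry H-bond event is detected", {
  scen <- cached_scenario("hb08", scenario_config(n_frames = 120,
                                                  hbond_rate = 0.8,
                                                  seed = 47))
  traj <- scen$trajectory
  atoms <- traj$atoms
  crit <- hbond_criterion()
  pp <- membscreen:::partner_participants(atoms, "water",
                                          scen$groups$water,
                                          scen$groups$lipids)
  detected <- matrix(FALSE, length(traj$frames), scen$spec$n_copies)
  for (f in seq_along(traj$frames)) {
    for (k in seq_len(scen$spec$n_copies)) {
      p <- membscreen:::hbond_participants(traj, scen$spec, k, "oh", "water")
      n1 <- nrow(detect_hbonds(traj$frames[[f]], p$lig_donors, pp$acceptors,
                               crit, method = "brute"))
      detected[f, k] <- n1 > 0
    }
  }
  expect_identical(detected, scen$truth$hbond)
})

test_that("flipped poses read as 180 - theta", {
  scen <- generate_scenario(scenario_config(n_frames = 40, n_waters = 0,
                                            n_ions = 0, flip_probability = 1,
                                            seed = 103))
  expect_true(all(scen$truth$flipped))
  expect_true(all(scen$truth$theta > 90))
  s <- orientation_samples(scen$trajectory, scen$spec, scen$groups$lipids)
  expect_equal(s$theta, as.vector(t(scen$truth$theta)), tolerance = 1e-9)
})

test_that("the full pipeline recovers the configured mode within one bin", {
  scen <- cached_scenario("big", scenario_config(n_frames = 1500,
                                                 n_waters = 0, n_ions = 0,
                                                 seed = 101))
  s <- orientation_samples(scen$trajectory, scen$spec, scen$groups$lipids)
  mode <- find_mode(accumulate_heatmap(s, 5, 0.05, depth_max = 5))
  expect_lte(abs(mode[["theta"]] - 30), 5)
  expect_lte(abs(mode[["depth"]] - 1.65), 0.05)
})

test_that("reference scenarios cover the decision space", {
  refs <- reference_scenarios(n_frames = 5)
  expect_setequal(names(refs),
                  c("hmi_like", "pyr_like", "ambiguous", "no_hydroxymethyl"))
  expect_equal(refs$hmi_like$tilt_mean, 30)
  expect_equal(refs$hmi_like$depth_mean, 1.65)
  expect_equal(refs$pyr_like$tilt_mean, 150)
  expect_equal(refs$pyr_like$depth_mean, 1.0)
  expect_null(refs$no_hydroxymethyl$template$spec$oh_group)

  # the no-hydroxymethyl analog errors cleanly in orientation but the
  # density and cluster stages still run
  scen <- generate_scenario(refs$no_hydroxymethyl)
  expect_error(orientation_samples(scen$trajectory, scen$spec,
                                   scen$groups$lipids), "no 'oh' group")
  p <- partial_density(scen$trajectory, scen$groups$lipids, 0.2,
                       scen$groups$lipids)
  expect_gt(max(p$density), 0)
  ts <- cluster_timeseries(scen$trajectory, scen$spec)
  expect_equal(nrow(ts$timeseries), 5L)
})

test_that("scenario artifacts round-trip through GRO/NDX/JSON", {
  scen <- cached_scenario("tiny", scenario_config(n_frames = 2, n_waters = 20,
                                                  n_ions = 2, seed = 42))
  dir <- tempfile()
  paths <- write_scenario(scen, dir)
  expect_true(all(file.exists(paths)))
  back <- read_gro(paths[["gro"]])
  expect_equal(length(back$frames), 2L)
  expect_equal(nrow(back$atoms), nrow(scen$trajectory$atoms))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$seed, 42)
})
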