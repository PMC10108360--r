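test_that("ideal geometry is detected and the cutoff is respected", {
  # D at origin, H on the D->A segment, A at 0.30 nm
  fr <- make_frame(rbind(c(5, 5, 5), c(5.1, 5, 5), c(5.3, 5, 5)))
  crit <- hbond_criterion()
  hits <- detect_hbonds(fr, cbind(1L, 2L), 3L, crit)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$acceptor, 3L)

  fr2 <- make_frame(rbind(c(5, 5, 5), c(5.1, 5, 5), c(5.36, 5, 5)))
  expect_equal(nrow(detect_hbonds(fr2, cbind(1L, 2L), 3L, crit)), 0L)

  # angle beyond the cutoff fails even at short range
  fr3 <- make_frame(rbind(c(5, 5, 5), c(5, 5.1, 5), c(5.3, 5, 5)))
  expect_equal(nrow(detect_hbonds(fr3, cbind(1L, 2L), 3L, crit)), 0L)

  # a donor's own atoms are never its acceptor
  expect_equal(nrow(detect_hbonds(fr, cbind(1L, 2L), c(1L, 2L), crit)), 0L)
})

test_that("grid-accelerated detection equals the exhaustive search", {
  set.seed(41)
  crit <- hbond_criterion()
  for (rep in 1:8) {
    box <- c(3, 3, 3)
    nd <- 80
    na <- 120
    dpos <- matrix(runif(nd * 3, 0, 3), nd)
    hpos <- dpos + matrix(rnorm(nd * 3, 0, 0.06), nd)
    apos <- matrix(runif(na * 3, 0, 3), na)
    coords <- rbind(dpos, hpos, apos)
    fr <- make_frame(coords, box = box)
    donors <- cbind(seq_len(nd), nd + seq_len(nd))
    acceptors <- 2L * nd + seq_len(na)
    g <- detect_hbonds(fr, donors, acceptors, crit, method = "grid")
    b <- detect_hbonds(fr, donors, acceptors, crit, method = "brute")
    expect_identical(g, b)
  }
})

test_that("enlarging the criterion never loses bonds", {
  set.seed(43)
  fr <- make_frame(matrix(runif(300, 0, 4), 100), box = c(4, 4, 4))
  donors <- cbind(1:30, 31:60)
  acceptors <- 61:100
  n_base <- nrow(detect_hbonds(fr, donors, acceptors,
                               hbond_criterion(0.35, 30)))
  n_r <- nrow(detect_hbonds(fr, donors, acceptors, hbond_criterion(0.5, 30)))
  n_a <- nrow(detect_hbonds(fr, donors, acceptors, hbond_criterion(0.35, 60)))
  expect_gte(n_r, n_base)
  expect_gte(n_a, n_base)
})

test_that("block scheme: a 1500-unit span in 5 blocks gives 300-unit blocks", {
  ba <- block_average(rep(2, 200), n_blocks = 5, frame_dt = 7.5)
  expect_equal(ba$block_length, 300)
  expect_equal(ba$grand_mean, 2)
  expect_equal(ba$sd, 0)
  expect_error(block_average(1:3, n_blocks = 5), "fewer frames")
  # remainder frames are dropped from the end
  ba2 <- block_average(c(rep(1, 10), 99), n_blocks = 5)
  expect_equal(ba2$n_frames_dropped, 1L)
  expect_equal(ba2$grand_mean, 1)
})

test_that("injected Bernoulli H-bond events are recovered per molecule", {
  scen <- cached_scenario("hb08", scenario_config(n_frames = 120,
                                                  hbond_rate = 0.8,
                                                  seed = 47))
  ba <- hbond_block_stats(scen$trajectory, scen$spec, "oh", "water",
                          water_group = scen$groups$water,
                          lipid_group = scen$groups$lipids)
  # every injected event is ideal geometry: detection is exact
  expect_equal(ba$grand_mean, mean(scen$truth$hbond))
  n <- length(scen$truth$hbond)
  se <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(ba$grand_mean - 0.8), 3 * se)
  expect_equal(ba$block_length, 24 * 7500)
})

test_that("OH and OO/NO statistics do not cross-contaminate", {
  scen <- cached_scenario("hb08", scenario_config(n_frames = 120,
                                                  hbond_rate = 0.8,
                                                  seed = 47))
  # events are injected against the hydroxy group only; the ester/amide
  # acceptors sit > 0.35 nm from every water by construction
  ba_oono <- hbond_block_stats(scen$trajectory, scen$spec, "oono", "water",
                               water_group = scen$groups$water,
                               lipid_group = scen$groups$lipids)
  expect_equal(ba_oono$grand_mean, 0)
})

test_that("a donor hydrogen must be bonded to its donor in the spec", {
  tmpl <- default_ligand_template()
  expect_error(
    ligand_spec(resname = "LIG", n_copies = 1,
                all_atoms = tmpl$spec$all_atoms,
                axis_tail = tmpl$spec$axis_tail, axis_head = "O1",
                oh_group = c("O1", "HO1"),
                donors = list(c("O1", "C1")),
                acceptors = "O1", bonds = tmpl$spec$bonds),
    "not bonded")
})
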