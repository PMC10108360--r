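#' Configuration of a synthetic bilayer + ligand scenario
#'
#' The generator emulates the assay-mimicking simulation system — an anionic
#' lipid bilayer with water, K+ counterions and four ligand copies placed in
#' the membrane with lateral separation — at reduced scale, with known
#' ground truth. Frames are independent draws from the configured
#' distributions, not dynamics: every downstream statistic is a
#' time-average of configurational observables, so an emulator suffices.
#'
#' Defaults are a reduced-scale system (16 three-bead pseudo-lipids, 400
#' waters, 16 K+ ions, 4 ligand copies, 200 frames of 7.5 ns giving the
#' 1500 ns analyzed span of the study conditions); `paper_scale = TRUE`
#' switches to the full 128-lipid / 6400-water / 128-ion composition.
#'
#' @param n_lipids,n_waters,n_ions,n_ligand_copies Particle counts.
#' @param box Orthorhombic box edges, nm.
#' @param phosphate_plane Distance of the lipid head-bead planes from the
#'   bilayer center, nm (default 2.0).
#' @param tilt_mean,tilt_sd Ligand tilt-angle distribution vs the outward
#'   leaflet normal, degrees (defaults 30 / 8: HMI-like).
#' @param depth_mean,depth_sd Hydroxy-group depth distribution (distance
#'   from bilayer center), nm (defaults 1.65 / 0.08: HMI-like).
#' @param flip_probability Probability per copy per frame of inverting the
#'   drawn tilt (theta -> 180 - theta), emulating a flipped, PYR-like pose.
#' @param hbond_rate Per-copy per-frame probability of injecting one
#'   ideal-geometry water H-bond (r(D,A) = 0.30 nm, H-D-A angle 0) against
#'   the hydroxy group.
#' @param cluster_fraction Fraction of frames in which copies 1 and 2 are
#'   brought to a minimum inter-atomic distance of 0.3 nm (0 disables
#'   cluster episodes).
#' @param n_frames Number of frames.
#' @param frame_dt Time per frame, ps (default 7500, i.e. 7.5 ns).
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @param template Ligand template from [default_ligand_template()].
#' @param paper_scale If `TRUE`, override counts/box with the full-scale
#'   composition (128 lipids, 6400 waters, 128 K+, 4 copies).
#' @return Object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(n_lipids = 16L, n_waters = 400L, n_ions = 16L,
                            n_ligand_copies = 4L, box = c(4, 4, 10),
                            phosphate_plane = 2.0,
                            tilt_mean = 30, tilt_sd = 8,
                            depth_mean = 1.65, depth_sd = 0.08,
                            flip_probability = 0, hbond_rate = 0,
                            cluster_fraction = 0, n_frames = 200L,
                            frame_dt = 7500, seed = 1L,
                            template = default_ligand_template(
                              n_copies = n_ligand_copies),
                            paper_scale = FALSE) {
  if (paper_scale) {
    n_lipids <- 128L; n_waters <- 6400L; n_ions <- 128L
    n_ligand_copies <- 4L; box <- c(6.4, 6.4, 12)
  }
  cfg <- list(n_lipids = as.integer(n_lipids),
              n_waters = as.integer(n_waters),
              n_ions = as.integer(n_ions),
              n_ligand_copies = as.integer(n_ligand_copies),
              box = box, phosphate_plane = phosphate_plane,
              tilt_mean = tilt_mean, tilt_sd = tilt_sd,
              depth_mean = depth_mean, depth_sd = depth_sd,
              flip_probability = flip_probability, hbond_rate = hbond_rate,
              cluster_fraction = cluster_fraction,
              n_frames = as.integer(n_frames), frame_dt = frame_dt,
              seed = as.integer(seed), template = template)
  stopifnot(cfg$n_lipids >= 2L, cfg$n_lipids %% 2L == 0L, cfg$n_waters >= 0L,
            cfg$n_ions >= 0L, cfg$n_ligand_copies >= 1L,
            length(box) == 3L, all(box > 0),
            phosphate_plane > 0, phosphate_plane < box[3L] / 2,
            tilt_sd > 0, depth_sd > 0,
            flip_probability >= 0, flip_probability <= 1,
            hbond_rate >= 0, hbond_rate <= 1,
            cluster_fraction >= 0, cluster_fraction <= 1,
            cfg$n_frames >= 1L, frame_dt > 0)
  if (hbond_rate > 0 && cfg$n_waters < cfg$n_ligand_copies) {
    stop("hbond_rate > 0 needs at least one water per ligand copy",
         call. = FALSE)
  }
  if (template$spec$n_copies != cfg$n_ligand_copies) {
    stop("template spec declares ", template$spec$n_copies,
         " copies but the scenario requests ", cfg$n_ligand_copies,
         call. = FALSE)
  }
  class(cfg) <- "scenario_config"
  cfg
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# Rotation matrix mapping unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  c_ <- sum(a * b)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any axis perpendicular to a for the 180-degree flip
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(a[2] * p[3] - a[3] * p[2], a[3] * p[1] - a[1] * p[3],
           a[1] * p[2] - a[2] * p[1])
    v <- v / sqrt(sum(v^2))
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    return(diag(3) + 2 * vx %*% vx)
  }
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# Minimum inter-atomic distance between two coordinate blocks (minimum image).
min_block_distance <- function(a, b, box) {
  m <- Inf
  for (r in seq_len(nrow(a))) {
    d <- minimum_image(b - matrix(a[r, ], nrow(b), 3L, byrow = TRUE), box)
    m <- min(m, min(rowSums(d^2)))
  }
  sqrt(m)
}

#' Generate a synthetic bilayer + ligand trajectory with ground truth
#'
#' Pseudo-lipids are three-bead chains (head bead at +/- the phosphate
#' plane with lateral jitter, two tail beads toward z = 0); waters and ions
#' are placed uniformly outside the membrane slab; each ligand copy is the
#' rigid template rotated to a per-frame drawn tilt and translated to a
#' drawn hydroxy depth in a randomly chosen leaflet, at laterally separated
#' grid positions. Waters falling inside the ligand excluded volume
#' (< 0.45 nm from any ligand atom) are displaced to the outer water shell,
#' so injected H-bond events are the only ligand-water hydrogen bonds. When
#' `hbond_rate` fires, a reserved water is teleported to ideal H-bond
#' geometry against the hydroxy group; during cluster episodes copies 1 and
#' 2 are brought to a minimum inter-atomic distance of 0.3 nm in the same
#' leaflet. All coordinates are wrapped into the box. The ground-truth
#' record stores every drawn angle, depth, leaflet and event.
#'
#' @param cfg A [scenario_config()].
#' @return Object of class `membscreen_scenario`: list with `trajectory`,
#'   `groups` (named index lists: lipids, water, ions, LIG1..), `spec`
#'   (the [ligand_spec()]), `truth` (matrices `theta`, `depth`, `leaflet`,
#'   `flipped`, `hbond`; vector `cluster`), and `config`.
#' @export
generate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_preserved_seed(cfg$seed, generate_scenario_impl(cfg))
}

generate_scenario_impl <- function(cfg) {
  box <- cfg$box
  zc <- box[3L] / 2
  plane <- cfg$phosphate_plane
  tmpl <- cfg$template
  tmpl_names <- rownames(tmpl$coords)
  nlig_atoms <- nrow(tmpl$coords)
  has_oh <- !is.null(tmpl$spec$oh_group)

  # ---- atom table -------------------------------------------------------
  lipid_names <- rep(c("P", "C1", "C2"), cfg$n_lipids)
  water_names <- rep(c("OW", "HW1", "HW2"), cfg$n_waters)
  ion_names <- rep("K", cfg$n_ions)
  atoms <- data.frame(
    name = c(lipid_names, water_names, ion_names,
             rep(tmpl_names, cfg$n_ligand_copies)),
    resname = c(rep("LIP", 3L * cfg$n_lipids),
                rep("SOL", 3L * cfg$n_waters),
                rep("K", cfg$n_ions),
                rep(tmpl$spec$resname, nlig_atoms * cfg$n_ligand_copies)),
    resid = c(rep(seq_len(cfg$n_lipids), each = 3L),
              cfg$n_lipids + rep(seq_len(cfg$n_waters), each = 3L),
              cfg$n_lipids + cfg$n_waters + seq_len(cfg$n_ions),
              cfg$n_lipids + cfg$n_waters + cfg$n_ions +
                rep(seq_len(cfg$n_ligand_copies), each = nlig_atoms)),
    stringsAsFactors = FALSE
  )
  atoms$index <- seq_len(nrow(atoms))
  # head bead stands for the whole phosphate/glycerol moiety: give it a
  # heavier mass than a bare P so the bilayer COM is head-weighted
  atoms <- assign_atom_properties(
    atoms, overrides = data.frame(name = "P", mass = 94.97,
                                  vdw_radius = 0.19))
  n_atoms <- nrow(atoms)
  lipid_idx <- which(atoms$resname == "LIP")
  water_idx <- which(atoms$resname == "SOL")
  ion_idx <- which(atoms$resname == "K")
  ow_idx <- water_idx[atoms$name[water_idx] == "OW"]
  groups <- c(list(lipids = lipid_idx, water = water_idx, ions = ion_idx),
              stats::setNames(
                lapply(seq_len(cfg$n_ligand_copies), function(k) {
                  resolve_ligand_atoms(atoms, tmpl$spec, k, "all")
                }),
                paste0(tmpl$spec$resname, seq_len(cfg$n_ligand_copies))))

  # lateral grid anchors for the ligand copies
  ngrid <- ceiling(sqrt(cfg$n_ligand_copies))
  gx <- (rep(seq_len(ngrid), times = ngrid) - 0.5) / ngrid * box[1L]
  gy <- (rep(seq_len(ngrid), each = ngrid) - 0.5) / ngrid * box[2L]
  anchors <- cbind(gx, gy)[seq_len(cfg$n_ligand_copies), , drop = FALSE]

  nl2 <- cfg$n_lipids %/% 2L
  lip_side <- rep(c(1, -1), c(nl2, cfg$n_lipids - nl2))
  wat_margin <- plane + 0.15

  truth_theta <- matrix(NA_real_, cfg$n_frames, cfg$n_ligand_copies)
  truth_depth <- truth_theta
  truth_leaf <- matrix(NA_character_, cfg$n_frames, cfg$n_ligand_copies)
  truth_flip <- matrix(FALSE, cfg$n_frames, cfg$n_ligand_copies)
  truth_hb <- matrix(FALSE, cfg$n_frames, cfg$n_ligand_copies)
  truth_clu <- logical(cfg$n_frames)

  copy1_idx <- groups[[paste0(tmpl$spec$resname, "1")]]
  com_of <- function(names_) {
    i <- match(names_, tmpl_names)
    m <- atoms$mass[copy1_idx[i]]
    colSums(tmpl$coords[i, , drop = FALSE] * m) / sum(m)
  }
  axis_template <- com_of(tmpl$spec$axis_head) - com_of(tmpl$spec$axis_tail)
  axis_template <- axis_template / sqrt(sum(axis_template^2))

  oh_com_template <- if (has_oh) {
    oidx <- match(tmpl$spec$oh_group, tmpl_names)
    m <- atoms$mass[groups[[paste0(tmpl$spec$resname, "1")]][oidx]]
    colSums(tmpl$coords[oidx, , drop = FALSE] * m) / sum(m)
  } else {
    ridx <- match(tmpl$spec$axis_tail, tmpl_names)
    colMeans(tmpl$coords[ridx, , drop = FALSE])
  }

  frames <- vector("list", cfg$n_frames)
  for (f in seq_len(cfg$n_frames)) {
    coords <- matrix(NA_real_, n_atoms, 3L)

    # lipids: 3-bead chains, heads on the phosphate planes
    hx <- stats::runif(cfg$n_lipids, 0, box[1L])
    hy <- stats::runif(cfg$n_lipids, 0, box[2L])
    hz <- zc + lip_side * (plane + stats::rnorm(cfg$n_lipids, 0, 0.03))
    t1z <- zc + lip_side * (0.62 * plane + stats::rnorm(cfg$n_lipids, 0, 0.05))
    t2z <- zc + lip_side * (0.25 * plane + stats::rnorm(cfg$n_lipids, 0, 0.05))
    jit <- function(n) stats::rnorm(n, 0, 0.05)
    li <- matrix(lipid_idx, nrow = 3L)
    coords[li[1L, ], ] <- cbind(hx, hy, hz)
    coords[li[2L, ], ] <- cbind(hx + jit(cfg$n_lipids),
                                hy + jit(cfg$n_lipids), t1z)
    coords[li[3L, ], ] <- cbind(hx + jit(cfg$n_lipids),
                                hy + jit(cfg$n_lipids), t2z)

    # waters: uniform in the two slabs outside the membrane
    if (cfg$n_waters > 0L) {
      ws <- sample(c(1, -1), cfg$n_waters, replace = TRUE)
      wu <- stats::runif(cfg$n_waters, wat_margin, box[3L] / 2 - 0.1)
      owp <- cbind(stats::runif(cfg$n_waters, 0, box[1L]),
                   stats::runif(cfg$n_waters, 0, box[2L]),
                   zc + ws * wu)
      runit <- function(n) {
        v <- matrix(stats::rnorm(3L * n), n, 3L)
        v / sqrt(rowSums(v^2))
      }
      u1 <- runit(cfg$n_waters)
      # second O-H direction roughly tetrahedral to the first
      u2raw <- runit(cfg$n_waters)
      u2raw <- u2raw - u1 * rowSums(u2raw * u1)
      u2len <- sqrt(rowSums(u2raw^2))
      u2raw <- u2raw / ifelse(u2len < 1e-8, 1, u2len)
      u2 <- u1 * cos(104.5 * pi / 180) + u2raw * sin(104.5 * pi / 180)
      wi <- matrix(water_idx, nrow = 3L)
      coords[wi[1L, ], ] <- owp
      coords[wi[2L, ], ] <- owp + 0.0957 * u1
      coords[wi[3L, ], ] <- owp + 0.0957 * u2
    }

    # ions among the waters
    if (cfg$n_ions > 0L) {
      is_ <- sample(c(1, -1), cfg$n_ions, replace = TRUE)
      iu <- stats::runif(cfg$n_ions, wat_margin, box[3L] / 2 - 0.1)
      coords[ion_idx, ] <- cbind(stats::runif(cfg$n_ions, 0, box[1L]),
                                 stats::runif(cfg$n_ions, 0, box[2L]),
                                 zc + is_ * iu)
    }

    # ligand copies: drawn tilt/depth/leaflet, rigid template placement
    clustered <- cfg$cluster_fraction > 0 && cfg$n_ligand_copies >= 2L &&
      stats::runif(1) < cfg$cluster_fraction
    truth_clu[f] <- clustered
    place_copy <- function(k, side, theta_deg, depth, phi, lateral) {
      u <- c(sin(theta_deg * pi / 180) * cos(phi),
             sin(theta_deg * pi / 180) * sin(phi),
             side * cos(theta_deg * pi / 180))
      rot <- rotation_between(axis_template, u)
      xyz <- tmpl$coords %*% t(rot)
      ref <- as.vector(oh_com_template %*% t(rot))
      target <- c(lateral[1L], lateral[2L], zc + side * depth)
      xyz + matrix(target - ref, nlig_atoms, 3L, byrow = TRUE)
    }
    copy_coords <- vector("list", cfg$n_ligand_copies)
    for (k in seq_len(cfg$n_ligand_copies)) {
      side <- sample(c(1, -1), 1L)
      theta <- min(180, max(0, stats::rnorm(1, cfg$tilt_mean, cfg$tilt_sd)))
      flip <- stats::runif(1) < cfg$flip_probability
      if (flip) theta <- 180 - theta
      depth <- min(box[3L] / 2 - 0.05,
                   max(0.05, stats::rnorm(1, cfg$depth_mean, cfg$depth_sd)))
      phi <- stats::runif(1, 0, 2 * pi)
      lateral <- anchors[k, ] + stats::rnorm(2L, 0, 0.05)
      if (clustered && k == 2L) {
        side <- truth_side1
        depth <- truth_depth[f, 1L]
      }
      copy_coords[[k]] <- place_copy(k, side, theta, depth, phi, lateral)
      if (k == 1L) truth_side1 <- side
      truth_theta[f, k] <- theta
      truth_depth[f, k] <- depth
      truth_leaf[f, k] <- if (side > 0) "upper" else "lower"
      truth_flip[f, k] <- flip
    }
    if (clustered) {
      c1 <- copy_coords[[1L]]
      base <- copy_coords[[2L]]
      base_xy <- colMeans(base)[1:2]
      target_xy <- colMeans(c1)[1:2]
      shift_to <- function(t) {
        sweep(base, 2L, c(target_xy[1L] + t - base_xy[1L],
                          target_xy[2L] - base_xy[2L], 0), "+")
      }
      fdist <- function(t) min_block_distance(c1, shift_to(t), box) - 0.3
      tstar <- tryCatch(
        stats::uniroot(fdist, c(0.05, 2.0), tol = 1e-4)$root,
        error = function(e) 0.9)
      copy_coords[[2L]] <- shift_to(tstar)
    }
    for (k in seq_len(cfg$n_ligand_copies)) {
      coords[groups[[paste0(tmpl$spec$resname, k)]], ] <- copy_coords[[k]]
    }
    lig_all_idx <- unlist(groups[paste0(tmpl$spec$resname,
                                        seq_len(cfg$n_ligand_copies))],
                          use.names = FALSE)

    # solvent excluded volume: displace waters overlapping any ligand atom
    if (cfg$n_waters > 0L) {
      mind2 <- rep(Inf, cfg$n_waters)
      for (a in lig_all_idx) {
        d <- minimum_image(coords[ow_idx, , drop = FALSE] -
                             matrix(coords[a, ], cfg$n_waters, 3L,
                                    byrow = TRUE), box)
        mind2 <- pmin(mind2, rowSums(d^2))
      }
      bad <- which(mind2 < 0.45^2)
      if (length(bad)) {
        side <- sample(c(1, -1), length(bad), replace = TRUE)
        newz <- zc + side * (box[3L] / 2 - 0.15 -
                               stats::runif(length(bad), 0, 0.4))
        dz <- newz - coords[ow_idx[bad], 3L]
        for (b in seq_along(bad)) {
          rows <- water_idx[(3L * (bad[b] - 1L) + 1L):(3L * bad[b])]
          coords[rows, 3L] <- coords[rows, 3L] + dz[b]
        }
      }
    }

    # injected ideal-geometry H-bond events against the hydroxy group
    if (cfg$hbond_rate > 0 && has_oh) {
      for (k in seq_len(cfg$n_ligand_copies)) {
        if (stats::runif(1) >= cfg$hbond_rate) next
        truth_hb[f, k] <- TRUE
        lig <- groups[[paste0(tmpl$spec$resname, k)]]
        nm <- atoms$name[lig]
        o1 <- coords[lig[match(tmpl$spec$donors[[1L]][1L], nm)], ]
        h1 <- coords[lig[match(tmpl$spec$donors[[1L]][2L], nm)], ]
        u <- (h1 - o1) / sqrt(sum((h1 - o1)^2))
        w <- cfg$n_waters - k + 1L  # reserved water
        rows <- water_idx[(3L * (w - 1L) + 1L):(3L * w)]
        owp <- o1 + 0.30 * u
        perp <- c(-u[2L], u[1L], 0)
        if (sum(perp^2) < 1e-8) perp <- c(1, 0, 0)
        perp <- perp / sqrt(sum(perp^2))
        coords[rows[1L], ] <- owp
        coords[rows[2L], ] <- owp + 0.0957 * u       # H pointing away
        coords[rows[3L], ] <- owp + 0.0957 * perp    # ~90 deg off the O..O axis
      }
    }

    coords <- coords %% matrix(box, n_atoms, 3L, byrow = TRUE)
    frames[[f]] <- list(time = (f - 1L) * cfg$frame_dt, box = box,
                        coords = coords)
  }

  structure(list(
    trajectory = trajectory(atoms, frames),
    groups = groups,
    spec = tmpl$spec,
    truth = list(theta = truth_theta, depth = truth_depth,
                 leaflet = truth_leaf, flipped = truth_flip,
                 hbond = truth_hb, cluster = truth_clu),
    config = cfg
  ), class = "membscreen_scenario")
}

#' Built-in reference scenarios
#'
#' Named scenario configurations spanning the screening decision space:
#' `hmi_like` (the correct-orientation positive reference: mean tilt 30
#' degrees, hydroxy depth 1.65 nm), `pyr_like` (the flipped, buried negative
#' reference: mean tilt 150 degrees, depth 1.0 nm), `ambiguous` (tilt near
#' 90 degrees at intermediate depth) and `no_hydroxymethyl` (a control
#' analog lacking the hydroxy group, exercising the missing-group error
#' path).
#'
#' @param n_frames Frames per scenario (default 200).
#' @param seed Seed recorded in each configuration.
#' @param ... Further overrides passed to every [scenario_config()] call.
#' @return Named list of `scenario_config` objects.
#' @export
reference_scenarios <- function(n_frames = 200L, seed = 1L, ...) {
  list(
    hmi_like = scenario_config(tilt_mean = 30, depth_mean = 1.65,
                               n_frames = n_frames, seed = seed, ...),
    pyr_like = scenario_config(tilt_mean = 150, depth_mean = 1.0,
                               n_frames = n_frames, seed = seed, ...),
    ambiguous = scenario_config(tilt_mean = 90, tilt_sd = 10,
                                depth_mean = 1.3, n_frames = n_frames,
                                seed = seed, ...),
    no_hydroxymethyl = scenario_config(
      template = default_ligand_template(with_oh = FALSE),
      tilt_mean = 30, depth_mean = 1.65, n_frames = n_frames, seed = seed,
      ...)
  )
}

#' Write a scenario's trajectory, groups and ground truth to disk
#'
#' @param scen A `membscreen_scenario`.
#' @param dir Output directory (created if needed).
#' @param basename File stem (default "scenario").
#' @return Named character vector of the written paths (`gro`, `ndx`,
#'   `truth`).
#' @export
write_scenario <- function(scen, dir, basename = "scenario") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gro <- file.path(dir, paste0(basename, ".gro"))
  ndx <- file.path(dir, paste0(basename, ".ndx"))
  truth <- file.path(dir, paste0(basename, "_truth.json"))
  write_gro(scen$trajectory, gro)
  write_index_groups(scen$groups, ndx)
  tr <- scen$truth
  jsonlite::write_json(
    list(theta = tr$theta, depth = tr$depth, leaflet = tr$leaflet,
         flipped = tr$flipped, hbond = tr$hbond, cluster = tr$cluster,
         seed = scen$config$seed),
    truth, digits = NA)
  c(gro = gro, ndx = ndx, truth = truth)
}
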